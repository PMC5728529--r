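#' Parameters for the sliding-window PTS scan
#'
#' A PTS region (the proline/threonine/serine-rich, O-glycosylated segment of
#' gel-forming mucins) is defined compositionally: a window qualifies when its
#' combined serine+threonine fraction is strictly greater than `st_min_frac`
#' and its proline fraction is at least `pro_min_frac`. The defaults encode
#' the standard definition at window size 100: > 40% S or T and >= 5% P.
#'
#' @param window Window size in residues (default 100).
#' @param st_min_frac Minimum combined S+T fraction, exclusive bound
#'   (default 0.40).
#' @param pro_min_frac Minimum proline fraction, inclusive bound
#'   (default 0.05).
#' @param step Stride of the scan in residues (default 1, maximal
#'   sensitivity).
#' @return An object of class `pts_params`.
#' @export
pts_params <- function(window = 100L, st_min_frac = 0.40,
                       pro_min_frac = 0.05, step = 1L) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || window < 1L) .stop("window must be >= 1")
  if (is.na(step) || step < 1L) .stop("step must be >= 1")
  for (f in c(st_min_frac, pro_min_frac)) {
    if (!is.finite(f) || f < 0 || f > 1) .stop("fractions must lie in [0, 1]")
  }
  structure(list(window = window, st_min_frac = st_min_frac,
                 pro_min_frac = pro_min_frac, step = step),
            class = "pts_params")
}

#' Does a single window satisfy the PTS composition criterion?
#'
#' `X` residues count toward window length but toward no composition class.
#'
#' @param window_seq Amino-acid string of length exactly `params$window`.
#' @param params A [pts_params()] object.
#' @return Logical scalar.
#' @export
window_qualifies <- function(window_seq, params = pts_params()) {
  if (nchar(window_seq) != params$window) {
    .stop("window sequence has length %d, expected %d",
          nchar(window_seq), params$window)
  }
  ch <- strsplit(toupper(window_seq), "")[[1]]
  st <- sum(ch == "S" | ch == "T") / params$window
  pro <- sum(ch == "P") / params$window
  st > params$st_min_frac && pro >= params$pro_min_frac
}

#' Sliding-window PTS scan over protein sequences
#'
#' Slides a window of `params$window` residues with stride `params$step`
#' along each sequence; all qualifying windows whose spans overlap or abut
#' are merged into maximal regions. Sequences shorter than the window yield
#' no regions.
#'
#' @param x Either a character vector of sequences (optionally named by
#'   protein id) or a tibble of protein records as from [read_fasta()].
#' @param params A [pts_params()] object.
#' @return Tibble with columns `protein_id`, `start`, `end`, `st_frac_max`,
#'   `pro_frac_max` (maxima over the region's qualifying windows), sorted by
#'   protein then start.
#' @export
scan_pts <- function(x, params = pts_params()) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$sequence, x$id)
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  out <- lapply(names(seqs), function(id) {
    r <- .scan_pts_one(seqs[[id]], params)
    if (nrow(r)) r$protein_id <- id
    r
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(protein_id = character(), start = integer(), end = integer(),
                  st_frac_max = numeric(), pro_frac_max = numeric()))
  }
  as_tibble(res[, c("protein_id", "start", "end", "st_frac_max", "pro_frac_max")])
}

.scan_pts_one <- function(sequence, params) {
  w <- params$window
  empty <- tibble(start = integer(), end = integer(),
                  st_frac_max = numeric(), pro_frac_max = numeric())
  L <- nchar(sequence)
  if (L < w) return(empty)
  ch <- strsplit(toupper(sequence), "")[[1]]
  cst <- cumsum(ch == "S" | ch == "T")
  cp <- cumsum(ch == "P")
  starts <- seq.int(1L, L - w + 1L, by = params$step)
  stc <- cst[starts + w - 1L] - c(0, cst)[starts]
  pc <- cp[starts + w - 1L] - c(0, cp)[starts]
  st_frac <- stc / w
  pro_frac <- pc / w
  qual <- st_frac > params$st_min_frac & pro_frac >= params$pro_min_frac
  qs <- starts[qual]
  if (length(qs) == 0) return(empty)
  # windows [i, i+w-1] and [j, j+w-1] (i < j) overlap or abut iff j <= i + w
  brk <- which(diff(qs) > w)
  grp <- rep(seq_len(length(brk) + 1L), diff(c(0L, brk, length(qs))))
  sf <- st_frac[qual]; pf <- pro_frac[qual]
  tibble(
    start = as.integer(tapply(qs, grp, min)),
    end = as.integer(tapply(qs, grp, max)) + w - 1L,
    st_frac_max = as.numeric(tapply(sf, grp, max)),
    pro_frac_max = as.numeric(tapply(pf, grp, max))
  )
}
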