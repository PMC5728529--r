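#' Filter domain hits by independent E-value
#'
#' @param hits Tibble of domain hits.
#' @param evalue_max Keep hits with `i_evalue <= evalue_max` (default 1e-3,
#'   common Pfam practice).
#' @return Filtered tibble.
#' @export
filter_hits <- function(hits, evalue_max = 1e-3) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) .stop("evalue_max must be > 0")
  hits[hits$i_evalue <= evalue_max, , drop = FALSE]
}

# overlap extent between [s1,e1] and [s2,e2]; two hits conflict when this
# exceeds overlap_tol (min(end)-max(start), so tol=10 tolerates an 11-residue
# shared flank)
.overlap_extent <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2)

#' Resolve overlapping domain hits on one protein
#'
#' Greedy selection in ascending E-value order (ties broken by higher score,
#' then smaller start): a hit is kept iff its overlap extent with every
#' already-kept hit is at most `overlap_tol`. Result is sorted by start.
#'
#' @param hits Tibble of domain hits, all on one protein.
#' @param overlap_tol Overlap tolerance in residues (default 10).
#' @return Tibble of retained hits sorted by start coordinate.
#' @export
resolve_overlaps <- function(hits, overlap_tol = 10L) {
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$protein_id)) > 1) {
    .stop("resolve_overlaps expects hits on a single protein")
  }
  ord <- order(hits$i_evalue, -hits$score, hits$start)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    k <- which(keep)
    ok <- length(k) == 0 ||
      all(.overlap_extent(h$start[i], h$end[i], h$start[k], h$end[k]) <= overlap_tol)
    keep[i] <- ok
  }
  out <- h[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Build an ordered domain architecture
#'
#' Interleaves resolved domain hits and PTS regions by start coordinate. A
#' PTS region that overlaps a kept domain by more than `overlap_tol` is
#' truncated to its largest domain-free sub-interval (dropped if none of at
#' least one residue remains).
#'
#' @param resolved_hits Tibble of non-conflicting domain hits on one protein
#'   (as from [resolve_overlaps()]).
#' @param pts_regions Tibble of PTS regions on the same protein (columns
#'   `start`, `end`); may be empty.
#' @param protein_id Protein identifier; inferred from the inputs when
#'   omitted.
#' @param overlap_tol Overlap tolerance in residues (default 10).
#' @return An object of class `architecture`: list with `protein_id` and an
#'   `elements` tibble (`element`, `start`, `end`) sorted by start.
#' @export
build_architecture <- function(resolved_hits, pts_regions = NULL,
                               protein_id = NULL, overlap_tol = 10L) {
  if (is.null(protein_id)) {
    protein_id <- unique(c(
      if (nrow(resolved_hits)) resolved_hits$protein_id,
      if (!is.null(pts_regions) && nrow(pts_regions) &&
          "protein_id" %in% names(pts_regions)) pts_regions$protein_id
    ))
    if (length(protein_id) != 1) .stop("cannot infer a unique protein_id")
  }
  el <- tibble(element = character(), start = integer(), end = integer())
  if (nrow(resolved_hits)) {
    el <- tibble(element = resolved_hits$family,
                 start = as.integer(resolved_hits$start),
                 end = as.integer(resolved_hits$end))
  }
  if (!is.null(pts_regions) && nrow(pts_regions)) {
    for (i in seq_len(nrow(pts_regions))) {
      iv <- .free_interval(pts_regions$start[i], pts_regions$end[i],
                           el$start, el$end, overlap_tol)
      if (!is.null(iv)) {
        el <- rbind(el, tibble(element = "PTS", start = iv[1], end = iv[2]))
      }
    }
  }
  el <- el[order(el$start, el$end), , drop = FALSE]
  structure(list(protein_id = protein_id, elements = el), class = "architecture")
}

# largest sub-interval of [s,e] free of the domain spans, applied only when
# some domain overlaps [s,e] by more than tol; NULL if nothing remains
.free_interval <- function(s, e, dstart, dend, tol) {
  if (length(dstart) == 0) return(c(as.integer(s), as.integer(e)))
  ov <- .overlap_extent(s, e, dstart, dend)
  if (all(ov <= tol)) return(c(as.integer(s), as.integer(e)))
  # subtract all domain spans, keep longest remaining piece
  cover <- cbind(pmax(dstart, s), pmin(dend, e))
  cover <- cover[cover[, 1] <= cover[, 2], , drop = FALSE]
  cover <- cover[order(cover[, 1]), , drop = FALSE]
  free <- list(); cur <- s
  for (i in seq_len(nrow(cover))) {
    if (cover[i, 1] > cur) free[[length(free) + 1]] <- c(cur, cover[i, 1] - 1L)
    cur <- max(cur, cover[i, 2] + 1L)
  }
  if (cur <= e) free[[length(free) + 1]] <- c(cur, e)
  if (length(free) == 0) return(NULL)
  lens <- vapply(free, function(v) v[2] - v[1] + 1, 0)
  iv <- free[[which.max(lens)]]
  c(as.integer(iv[1]), as.integer(iv[2]))
}

#' Render an architecture as a string
#'
#' Elements are joined with `-`. With `group = TRUE`, each VWD-led cassette
#' (VWD followed immediately by C8, TIL and optionally VWC) is wrapped in
#' parentheses; with `compress = TRUE`, runs of identical consecutive groups
#' are abbreviated `nX(...)`. Grouping is presentation-only: equality of
#' architectures is defined on the flat element sequence.
#'
#' @param arch An `architecture` object, or a character vector of element
#'   names.
#' @param group Wrap VWD-C8-TIL(-VWC) cassettes in parentheses.
#' @param compress Abbreviate repeated identical groups as `nX(...)`.
#' @return A single string, `""` for an empty architecture.
#' @export
architecture_string <- function(arch, group = FALSE, compress = FALSE) {
  el <- if (inherits(arch, "architecture")) arch$elements$element else as.character(arch)
  if (length(el) == 0) return("")
  if (!group) return(paste(el, collapse = "-"))
  toks <- character(0); i <- 1
  while (i <= length(el)) {
    if (el[i] == "VWD" && i + 2 <= length(el) &&
        el[i + 1] == "C8" && el[i + 2] == "TIL") {
      j <- i + 2
      if (j + 1 <= length(el) && el[j + 1] == "VWC") j <- j + 1
      toks <- c(toks, paste0("(", paste(el[i:j], collapse = "-"), ")"))
      i <- j + 1
    } else {
      toks <- c(toks, el[i])
      i <- i + 1
    }
  }
  if (compress) {
    r <- rle(toks)
    toks <- ifelse(r$lengths > 1 & startsWith(r$values, "("),
                   paste0(r$lengths, "X", r$values),
                   ifelse(r$lengths > 1,
                          vapply(seq_along(r$values), function(k)
                            paste(rep(r$values[k], r$lengths[k]), collapse = "-"), ""),
                          r$values))
  }
  paste(toks, collapse = "-")
}

#' @export
print.architecture <- function(x, ...) {
  cat(x$protein_id, ": ", architecture_string(x), "\n", sep = "")
  invisible(x)
}

#' Test for the minimum gel-forming mucin motif (VWD-C8-TIL)
#'
#' TRUE iff the element sequence contains VWD, C8, TIL consecutively in that
#' N-to-C order. PTS elements are transparent (skipped); any other domain
#' element blocks the cassette.
#'
#' @param arch An `architecture` object or character vector of element names.
#' @return Logical scalar.
#' @export
has_min_mucin_motif <- function(arch) {
  el <- if (inherits(arch, "architecture")) arch$elements$element else as.character(arch)
  el <- el[el != "PTS"]
  n <- length(el)
  if (n < 3) return(FALSE)
  any(el[seq_len(n - 2)] == "VWD" &
        el[seq_len(n - 2) + 1] == "C8" &
        el[seq_len(n - 2) + 2] == "TIL")
}

#' Extract positionally labelled VWD domains
#'
#' One entry per VWD element, labelled `D1`, `D2`, ... by start order from
#' the N-terminus, with the corresponding subsequence.
#'
#' @param arch An `architecture` object.
#' @param protein A single protein record (one-row tibble or list with
#'   `id`/`sequence`) whose sequence covers all element coordinates.
#' @return Tibble with columns `protein_id`, `label`, `start`, `end`,
#'   `sequence`; empty when the architecture has no VWD element.
#' @export
extract_vwd <- function(arch, protein) {
  seqs <- if (is.data.frame(protein)) protein$sequence[1] else protein$sequence
  el <- arch$elements
  v <- el[el$element == "VWD", , drop = FALSE]
  if (nrow(v) == 0) {
    return(tibble(protein_id = character(), label = character(),
                  start = integer(), end = integer(), sequence = character()))
  }
  if (max(el$end) > nchar(seqs)) {
    .stop("architecture coordinates for %s exceed sequence length (%d > %d)",
          arch$protein_id, max(el$end), nchar(seqs))
  }
  v <- v[order(v$start), , drop = FALSE]
  tibble(
    protein_id = arch$protein_id,
    label = paste0("D", seq_len(nrow(v))),
    start = v$start,
    end = v$end,
    sequence = substring(seqs, v$start, v$end)
  )
}

#' Build architectures for a whole protein collection
#'
#' Convenience wrapper: filters hits by E-value, resolves overlaps per
#' protein, scans for PTS regions and assembles one architecture per protein
#' record.
#'
#' @param records Protein records tibble.
#' @param hits Domain hits tibble (all proteins).
#' @param params [pts_params()] for the PTS scan.
#' @param evalue_max E-value threshold (default 1e-3).
#' @param overlap_tol Overlap tolerance in residues (default 10).
#' @return Named list of `architecture` objects (one per record, in input
#'   order).
#' @export
build_architectures <- function(records, hits, params = pts_params(),
                                evalue_max = 1e-3, overlap_tol = 10L) {
  hits <- filter_hits(hits, evalue_max)
  pts <- scan_pts(records, params)
  out <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    h <- resolve_overlaps(hits[hits$protein_id == id, , drop = FALSE], overlap_tol)
    p <- pts[pts$protein_id == id, , drop = FALSE]
    build_architecture(h, p, protein_id = id, overlap_tol = overlap_tol)
  })
  names(out) <- records$id
  out
}
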