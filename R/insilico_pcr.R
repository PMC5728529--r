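#' Define a qPCR primer pair
#'
#' @param name Assay name.
#' @param forward Forward primer, 5'→3', A/C/G/T only, >= 10 nt.
#' @param reverse Reverse primer, 5'→3' on the opposite strand, same rules.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!grepl("^[ACGT]+$", p)) .stop("primers must contain only A/C/G/T: %s", p)
    if (nchar(p) < 10) .stop("primers must be >= 10 nt: %s", p)
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Predict amplicons for a primer pair on a nucleotide template
#'
#' The forward primer is matched exactly on the given strand; the reverse
#' primer is matched as its reverse complement strictly downstream of the
#' forward site (no 3' overlap of the two sites). Matching is exact --
#' ambiguous template bases are mismatches. All products are reported,
#' shortest first, up to `max_products`.
#'
#' @param template Nucleotide sequence string (or one-row records tibble).
#' @param pair A [primer_pair()].
#' @param max_products Maximum number of products to report (default 10).
#' @param template_id Identifier for the output; taken from the tibble when
#'   given.
#' @return Tibble (`template_id`, `assay`, `start`, `end`, `length`);
#'   zero rows when there is no product.
#' @export
find_amplicon <- function(template, pair, max_products = 10L,
                          template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.data.frame(template)) {
    template_id <- template$id[1]
    template <- template$sequence[1]
  }
  template <- toupper(template)
  fwd <- pair$forward
  rc <- .revcomp(pair$reverse)
  f_pos <- .all_matches(template, fwd)
  r_pos <- .all_matches(template, rc)
  empty <- tibble(template_id = character(), assay = character(),
                  start = integer(), end = integer(), length = integer())
  if (length(f_pos) == 0 || length(r_pos) == 0) return(empty)
  lf <- nchar(fwd); lr <- nchar(rc)
  prods <- list()
  for (s in f_pos) {
    for (r in r_pos) {
      if (r >= s + lf) {
        e <- r + lr - 1L
        prods[[length(prods) + 1]] <- c(s, e)
      }
    }
  }
  if (length(prods) == 0) return(empty)
  pm <- do.call(rbind, prods)
  len <- pm[, 2] - pm[, 1] + 1L
  ord <- order(len, pm[, 1])
  pm <- pm[ord, , drop = FALSE]; len <- len[ord]
  k <- min(nrow(pm), as.integer(max_products))
  tibble(template_id = template_id, assay = pair$name,
         start = as.integer(pm[seq_len(k), 1]),
         end = as.integer(pm[seq_len(k), 2]),
         length = as.integer(len[seq_len(k)]))
}

.all_matches <- function(subject, pattern) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}
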