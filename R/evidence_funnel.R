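#' Configuration of the three-layer evidence funnel
#'
#' @param annotation_keyword Case-insensitive substring that marks an
#'   annotated candidate (default `"mucin"`); the empty string matches every
#'   record.
#' @param fpkm_threshold A gene is transcribed iff its FPKM exceeds this
#'   value (strictly) in at least one tissue; default 1, the direct
#'   complement of the "FPKM <= 1" not-transcribed bound.
#' @param require_motif Require the minimum VWD-C8-TIL cassette
#'   (default TRUE).
#' @return An object of class `funnel_config`.
#' @export
funnel_config <- function(annotation_keyword = "mucin", fpkm_threshold = 1,
                          require_motif = TRUE) {
  if (!is.numeric(fpkm_threshold) || fpkm_threshold < 0) {
    .stop("fpkm_threshold must be >= 0")
  }
  structure(list(annotation_keyword = annotation_keyword,
                 fpkm_threshold = fpkm_threshold,
                 require_motif = isTRUE(require_motif)),
            class = "funnel_config")
}

#' Annotation filter: ids whose description contains a keyword
#'
#' @param records Protein records tibble (`id`, `description`).
#' @param keyword Case-insensitive substring; `""` matches everything.
#' @return Character vector of ids.
#' @export
annotation_filter <- function(records, keyword = "mucin") {
  hit <- grepl(tolower(keyword), tolower(records$description), fixed = TRUE)
  records$id[hit]
}

#' Transcription filter: genes with FPKM above threshold in >= 1 tissue
#'
#' @param matrix Genes x tissues FPKM matrix.
#' @param threshold Strict lower bound on the per-gene maximum FPKM
#'   (default 1).
#' @return Character vector of gene ids.
#' @export
transcription_filter <- function(matrix, threshold = 1) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0) return(character(0))
  rownames(matrix)[apply(matrix, 1, max) > threshold]
}

#' Run the three-layer candidate-mucin funnel
#'
#' Applies the annotation, transcription and domain-architecture filters and
#' intersects them. Stage counts follow the nested convention: the
#' transcription and motif counts are reported within the annotated set, and
#' the candidates are the genes passing all three layers.
#'
#' @param records Protein records tibble.
#' @param matrix Genes x tissues FPKM matrix. Records absent from the matrix
#'   are treated as not transcribed (with a message).
#' @param architectures Named list of `architecture` objects (names are
#'   protein ids), e.g. from [build_architectures()].
#' @param config A [funnel_config()].
#' @return An object of class `funnel_report`: list with `counts` (named:
#'   `n_annotated`, `n_transcribed`, `n_motif`, `n_candidates`), `flags`
#'   (per-gene tibble of the three evidence flags), and `candidates`.
#' @export
run_funnel <- function(records, matrix, architectures, config = funnel_config()) {
  ids <- records$id
  annotated <- ids %in% annotation_filter(records, config$annotation_keyword)
  missing <- setdiff(ids, rownames(matrix))
  if (length(missing)) {
    message(sprintf("%d record(s) absent from expression matrix; treated as not transcribed",
                    length(missing)))
  }
  transcribed_ids <- transcription_filter(matrix, config$fpkm_threshold)
  transcribed <- ids %in% transcribed_ids
  has_motif <- vapply(ids, function(id) {
    a <- architectures[[id]]
    !is.null(a) && has_min_mucin_motif(a)
  }, logical(1))
  candidate <- annotated & transcribed & (has_motif | !config$require_motif)
  flags <- tibble(id = ids, annotated = annotated, transcribed = transcribed,
                  has_motif = unname(has_motif), candidate = candidate)
  counts <- c(
    n_annotated = sum(annotated),
    n_transcribed = sum(annotated & transcribed),
    n_motif = sum(annotated & has_motif),
    n_candidates = sum(candidate)
  )
  structure(list(counts = counts, flags = flags,
                 candidates = ids[candidate], config = config),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  c_ <- x$counts
  cat("Evidence funnel (counts within the annotated set):\n")
  cat(sprintf("  annotated:    %d\n", c_["n_annotated"]))
  cat(sprintf("  transcribed:  %d\n", c_["n_transcribed"]))
  cat(sprintf("  VWD-C8-TIL:   %d\n", c_["n_motif"]))
  cat(sprintf("  candidates:   %d\n", c_["n_candidates"]))
  if (length(x$candidates)) {
    cat("  ->", paste(x$candidates, collapse = ", "), "\n")
  }
  invisible(x)
}
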