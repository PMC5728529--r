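#' Read a protein (or nucleotide) FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] / [Biostrings::readDNAStringSet()]
#' and applies strict validation: identifiers (the first whitespace-delimited
#' token of each header) must be unique, sequences must be non-empty and, for
#' proteins, contain only the 20 canonical residues plus `X`. Sequences are
#' upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .stop("FASTA file not found: %s", path)
  set <- if (alphabet == "protein") {
    Biostrings::readBStringSet(path)  # permissive read; we validate ourselves
  } else {
    Biostrings::readBStringSet(path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (anyDuplicated(ids)) {
    .stop("duplicate FASTA identifier(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    .stop("empty sequence for record(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  legal <- if (alphabet == "protein") "^[ACDEFGHIKLMNPQRSTVWYX]+$" else "^[ACGTN]+$"
  bad <- !grepl(legal, seqs)
  if (any(bad)) {
    .stop("illegal %s residue(s) in record(s): %s",
          alphabet, paste(ids[bad], collapse = ", "))
  }
  tibble(id = ids, description = desc, sequence = seqs)
}

#' Write protein records to FASTA
#'
#' @param records Tibble with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()] or [simulate_proteome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Default Pfam-to-internal domain name map
#'
#' Maps Pfam family names onto the internal mucin domain vocabulary;
#' anything unmapped becomes `"other"`.
#' @return Named character vector.
#' @export
default_name_map <- function() {
  setNames(.MUCIN_DOMAINS, .MUCIN_DOMAINS)
}

#' Parse an hmmscan per-domain table (domtblout dialect)
#'
#' Reads the whitespace-delimited per-domain hit table emitted by
#' `hmmscan --domtblout`. Comment lines (`#`) are skipped. One hit is
#' returned per data row; coordinates are taken from the envelope columns
#' (1-based inclusive, the Pfam reporting convention).
#'
#' @param path Path to a domtblout file.
#' @param name_map Named character vector mapping family names as they appear
#'   in the file onto the internal vocabulary; unmapped families become
#'   `"other"`. Defaults to [default_name_map()].
#' @return Tibble with columns `protein_id`, `family`, `start`, `end`,
#'   `i_evalue`, `score`.
#' @export
parse_domtblout <- function(path, name_map = default_name_map()) {
  if (!file.exists(path)) .stop("domtblout file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(seq_along(idx), function(k) {
    f <- strsplit(trimws(lines[idx[k]]), "\\s+")[[1]]
    if (length(f) < 22) {
      .stop("malformed domtblout row at line %d: expected >= 22 fields, got %d",
            idx[k], length(f))
    }
    iev <- suppressWarnings(as.numeric(f[13]))
    sc <- suppressWarnings(as.numeric(f[14]))
    s <- suppressWarnings(as.integer(f[20]))
    e <- suppressWarnings(as.integer(f[21]))
    if (anyNA(c(iev, sc, s, e))) {
      .stop("malformed domtblout row at line %d: non-numeric coordinate/score field",
            idx[k])
    }
    list(family = f[1], protein_id = f[4], start = s, end = e,
         i_evalue = iev, score = sc)
  })
  if (length(rows) == 0) {
    return(tibble(protein_id = character(), family = character(),
                  start = integer(), end = integer(),
                  i_evalue = numeric(), score = numeric()))
  }
  fam_raw <- vapply(rows, `[[`, "", "family")
  fam <- unname(ifelse(fam_raw %in% names(name_map), name_map[fam_raw], "other"))
  tibble(
    protein_id = vapply(rows, `[[`, "", "protein_id"),
    family = fam,
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    i_evalue = vapply(rows, `[[`, 0, "i_evalue"),
    score = vapply(rows, `[[`, 0, "score")
  )
}

#' Write domain hits in hmmscan domtblout column layout
#'
#' Emits the 23-column per-domain layout that [parse_domtblout()] consumes
#' (family in column 1, protein id in column 4, independent E-value in column
#' 13, domain score in column 14, envelope coordinates in columns 20-21).
#'
#' @param hits Tibble of domain hits (`protein_id`, `family`, `start`, `end`,
#'   `i_evalue`, `score`).
#' @param path Output path.
#' @param protein_lengths Optional named integer vector of protein lengths
#'   used for the query-length column; defaults to the per-protein maximum
#'   hit end.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path, protein_lengths = NULL) {
  if (is.null(protein_lengths)) {
    protein_lengths <- tapply(hits$end, hits$protein_id, max)
  }
  qlen <- as.integer(protein_lengths[hits$protein_id])
  qlen[is.na(qlen)] <- as.integer(hits$end[is.na(qlen)])
  n <- nrow(hits)
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  )
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  dlen <- hits$end - hits$start + 1L
  # E-value and score printed at full double precision so that parsing the
  # table back yields identical hits
  rows <- sprintf(
    "%-20s %-11s %5d %-20s %-11s %6d %9.2g %6.1f %5.1f %3d %3d %.17g %.17g %.17g %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    hits$family, "-", dlen, hits$protein_id, "-", qlen,
    hits$i_evalue, hits$score, 0.0, 1L, 1L, hits$i_evalue, hits$i_evalue,
    hits$score, 0.0, 1L, dlen, hits$start, hits$end, hits$start, hits$end,
    0.99, "-"
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a genes x tissues FPKM matrix from TSV
#'
#' First column holds gene identifiers (genes in rows, the canonical
#' orientation); remaining columns are tissues. All cells must be
#' non-negative numbers; missing or negative values are rejected.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) .stop("expression file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stop("expression table needs a gene column plus >= 1 tissue")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (anyDuplicated(colnames(mat))) .stop("duplicate tissue names in expression table")
  if (anyNA(mat)) .stop("missing FPKM cell(s) in expression table")
  if (any(mat < 0)) {
    bad <- genes[apply(mat < 0, 1, any)]
    .stop("negative FPKM for gene(s): %s", paste(bad, collapse = ", "))
  }
  mat
}

#' Write an FPKM matrix as TSV (genes in rows)
#' @param mat Numeric matrix with gene rownames and tissue colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format qPCR Ct table from TSV
#'
#' Expected columns: `sample_id`, `fish_id`, `tissue`, `group`, `gene`,
#' `replicate`, `ct`. Absent wells are simply absent rows; a non-numeric or
#' non-positive Ct, or a replicate index outside 1..2, is a format error.
#'
#' @param path Path to a TSV file.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) .stop("Ct table not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "fish_id", "tissue", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stop("Ct table missing column(s): %s", paste(miss, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))
  if (anyNA(ct)) .stop("non-numeric Ct value(s) in rows: %s",
                       paste(which(is.na(ct)), collapse = ", "))
  if (any(ct <= 0)) .stop("non-positive Ct value(s) in rows: %s",
                          paste(which(ct <= 0), collapse = ", "))
  rep <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep) || !all(rep %in% c(1L, 2L))) {
    .stop("replicate index must be 1 or 2")
  }
  tibble(sample_id = as.character(df$sample_id),
         fish_id = as.character(df$fish_id),
         tissue = as.character(df$tissue),
         group = as.character(df$group),
         gene = as.character(df$gene),
         replicate = rep, ct = ct)
}

#' Write a Ct table as TSV
#' @param ct Tibble of Ct records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA file into an alignment matrix
#'
#' @param path Aligned FASTA (gaps as `-`).
#' @return Character matrix, one row per taxon, one column per alignment
#'   column, with taxa as rownames.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta_aligned(path)
  alignment_from_strings(setNames(recs$sequence, recs$id))
}

# permissive FASTA read used for alignments (gap characters allowed)
read_fasta_aligned <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) .stop("duplicate alignment taxa: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tibble(id = ids, sequence = toupper(as.character(set)))
}

#' Build an alignment matrix from named aligned strings
#' @param x Named character vector of equal-length aligned sequences.
#' @return Character matrix (taxa x columns).
#' @export
alignment_from_strings <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) .stop("aligned sequences must be named")
  w <- unique(nchar(x))
  if (length(w) != 1) .stop("aligned sequences differ in length: %s",
                            paste(w, collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(unname(x)), ""))
  rownames(m) <- names(x)
  m
}

#' Write an alignment matrix as aligned FASTA
#' @param aln Character matrix as from [alignment_from_strings()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  recs <- tibble(id = rownames(aln), description = "",
                 sequence = apply(aln, 1, paste, collapse = ""))
  set <- Biostrings::BStringSet(setNames(recs$sequence, recs$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}
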