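#' Collapse technical qPCR duplicates with quality control
#'
#' Wells are keyed by (`sample_id`, `gene`). Pairs whose absolute Ct
#' difference is below `qc_limit` are retained and averaged; pairs at or
#' above the limit are discarded (the conventional reading of the duplicate
#' rule). `mode = "literal"` applies the rule as sometimes printed --
#' removing pairs with a difference *below* the limit -- and is provided for
#' comparison only. Singleton wells pass with a warning.
#'
#' @param records Long Ct tibble (`sample_id`, `fish_id`, `tissue`, `group`,
#'   `gene`, `replicate`, `ct`).
#' @param qc_limit Ct-difference limit in cycles (default 0.5).
#' @param mode `"conventional"` (default) or `"literal"`.
#' @return Tibble with one row per retained well (`sample_id`, `fish_id`,
#'   `tissue`, `group`, `gene`, `ct` = duplicate mean, `n_rep`, `ct_diff`),
#'   with the discarded wells in attribute `"qc_log"`.
#' @export
collapse_duplicates <- function(records, qc_limit = 0.5,
                                mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  key <- paste(records$sample_id, records$gene, sep = "\r")
  n_per <- table(key)
  if (any(n_per > 2)) {
    .stop("more than 2 replicates for well(s): %s",
          paste(gsub("\r", " / ", names(n_per)[n_per > 2]), collapse = ", "))
  }
  ord <- order(match(key, unique(key)))
  r <- records[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  idx1 <- which(first)
  idx2 <- match(key[first], key[!first])  # row in the "second replicate" set
  second_rows <- which(!first)
  ct1 <- r$ct[idx1]
  ct2 <- rep(NA_real_, length(idx1))
  ct2[!is.na(idx2)] <- r$ct[second_rows[idx2[!is.na(idx2)]]]
  out <- tibble(
    sample_id = r$sample_id[idx1], fish_id = r$fish_id[idx1],
    tissue = r$tissue[idx1], group = r$group[idx1], gene = r$gene[idx1],
    ct = ifelse(is.na(ct2), ct1, (ct1 + ct2) / 2),
    n_rep = ifelse(is.na(ct2), 1L, 2L),
    ct_diff = ifelse(is.na(ct2), NA_real_, abs(ct1 - ct2))
  )
  if (any(out$n_rep == 1L)) {
    warning(sprintf("%d singleton well(s) retained without duplicate QC",
                    sum(out$n_rep == 1L)), call. = FALSE)
  }
  pair <- out$n_rep == 2L
  fail <- if (mode == "conventional") pair & out$ct_diff >= qc_limit
          else pair & out$ct_diff < qc_limit
  qc_log <- out[fail, c("sample_id", "gene", "ct_diff")]
  qc_log$reason <- if (mode == "conventional") "ct_diff >= qc_limit" else "ct_diff < qc_limit"
  res <- out[!fail, , drop = FALSE]
  attr(res, "qc_log") <- qc_log
  res
}

#' Primer efficiency from a dilution series
#'
#' Least-squares fit of `Ct = a + b * log10(conc)`; the amplification factor
#' is `E = 10^(-1/b)`. A perfect assay doubles product every cycle
#' (`E = 2`), i.e. Ct drops exactly one cycle per 2x concentration.
#'
#' @param series Data frame with columns `conc` (relative concentration,
#'   positive) and `ct`; at least 3 points.
#' @return List with `efficiency`, `slope`, `intercept`, `r_squared`.
#' @export
efficiency_from_dilution <- function(series) {
  if (nrow(series) < 3) .stop("dilution series needs >= 3 points")
  if (any(series$conc <= 0)) .stop("concentrations must be positive")
  fit <- lm(ct ~ log10(conc), data = series)
  b <- unname(coef(fit)[2])
  if (!is.finite(b) || b >= 0) {
    .stop("invalid dilution series: Ct does not decrease with concentration (slope %.3g)", b)
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless series fit exactly
  list(efficiency = 10^(-1 / b), slope = b,
       intercept = unname(coef(fit)[1]), r_squared = r2)
}

#' Reference-gene stability ranking
#'
#' Computes four standard stability measures over candidate reference genes
#' and aggregates their ranks by geometric mean (the RefFinder-style
#' summary). Lower is more stable throughout. With samples `i` and genes
#' `j` on collapsed Ct values:
#' * geNorm M: mean over other genes `k` of `sd_i(Ct_j - Ct_k)`;
#' * BestKeeper: `sd_i(Ct_j)`;
#' * comparative delta-Ct: mean over `k != j` of `sd_i(Ct_j - Ct_k)`
#'   (identical to geNorm M under this pairwise definition);
#' * NormFinder-style: `sd_i` of the doubly centred residual
#'   `Ct_ji - rowmean_i - colmean_j + grandmean`.
#'
#' @param ct Either a collapsed Ct tibble restricted to the candidate genes
#'   (columns `sample_id`, `gene`, `ct`) or a samples x genes numeric
#'   matrix.
#' @return Tibble with the four measures, their ranks, and `aggregate_rank`;
#'   attribute `"most_stable"` holds the top-ranked gene.
#' @export
stability_ranking <- function(ct) {
  if (is.data.frame(ct)) {
    genes <- unique(ct$gene)
    samples <- unique(ct$sample_id)
    m <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
    m[cbind(match(ct$sample_id, samples), match(ct$gene, genes))] <- ct$ct
  } else {
    m <- as.matrix(ct)
  }
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
  }
  if (ncol(m) < 2) .stop("stability ranking needs >= 2 candidate genes")
  if (nrow(m) < 3) .stop("stability ranking needs >= 3 complete samples")
  genes <- colnames(m)
  p <- ncol(m)
  pair_sd <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    if (j != k) pair_sd[j, k] <- sd(m[, j] - m[, k])
  }
  genorm_m <- rowSums(pair_sd) / (p - 1)
  bestkeeper_sd <- apply(m, 2, sd)
  comparative_dct <- genorm_m
  resid <- m - rowMeans(m) - matrix(colMeans(m), nrow(m), p, byrow = TRUE) + mean(m)
  normfinder <- apply(resid, 2, sd)
  meas <- cbind(genorm_m, bestkeeper_sd, comparative_dct, normfinder)
  if (all(meas == 0)) {
    message("zero variance across all candidate genes; ranks tied by gene order")
    ranks <- matrix(rep(seq_len(p), 4), p, 4)
  } else {
    ranks <- apply(meas, 2, rank, ties.method = "first")
  }
  aggregate_rank <- apply(ranks, 1, function(r) exp(mean(log(r))))
  out <- tibble(gene = genes,
                genorm_m = unname(genorm_m),
                bestkeeper_sd = unname(bestkeeper_sd),
                comparative_dct = unname(comparative_dct),
                normfinder = unname(normfinder),
                rank_genorm = ranks[, 1], rank_bestkeeper = ranks[, 2],
                rank_comparative = ranks[, 3], rank_normfinder = ranks[, 4],
                aggregate_rank = aggregate_rank)
  attr(out, "most_stable") <- genes[which.min(aggregate_rank)]
  out
}

#' Delta-Ct normalisation against a reference gene
#'
#' `delta_ct = Ct(gene) - Ct(reference)` within each sample. Samples in
#' which the reference was not measured are dropped with a message.
#'
#' @param collapsed Collapsed Ct tibble from [collapse_duplicates()].
#' @param reference_gene Name of the reference gene.
#' @return Tibble (`sample_id`, `fish_id`, `tissue`, `group`, `gene`,
#'   `delta_ct`); the reference gene itself appears with `delta_ct = 0`.
#' @export
delta_ct <- function(collapsed, reference_gene) {
  refs <- collapsed[collapsed$gene == reference_gene, , drop = FALSE]
  if (nrow(refs) == 0) .stop("reference gene '%s' absent from Ct data", reference_gene)
  ref_ct <- setNames(refs$ct, refs$sample_id)
  have <- collapsed$sample_id %in% names(ref_ct)
  n_drop <- length(unique(collapsed$sample_id[!have]))
  if (n_drop > 0) {
    message(sprintf("%d sample(s) dropped: reference gene not measured", n_drop))
  }
  d <- collapsed[have, , drop = FALSE]
  tibble(sample_id = d$sample_id, fish_id = d$fish_id, tissue = d$tissue,
         group = d$group, gene = d$gene,
         delta_ct = d$ct - unname(ref_ct[d$sample_id]))
}

#' Tissue transcription profile matrix (inverted mean delta-Ct)
#'
#' Cell value is `-mean(delta_ct)` over fish for each gene x tissue, so that
#' higher transcription (lower delta-Ct) gives a larger value. Gene/tissue
#' combinations with no measurement are `NA` (absent, not zero).
#'
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @return Numeric genes x tissues matrix.
#' @export
tissue_profile_matrix <- function(dct) {
  genes <- unique(dct$gene); tissues <- unique(dct$tissue)
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  agg <- tapply(dct$delta_ct, list(dct$gene, dct$tissue), mean)
  m[rownames(agg), colnames(agg)] <- -agg
  m
}

#' Group log2 fold changes vs control with linear-model testing
#'
#' For each gene x tissue, fits a one-way linear model of delta-Ct on group
#' and tests each group against the control with the pooled residual
#' variance (two-sided). The displayed effect is
#' `log2fc = -(mean delta-Ct of group - mean delta-Ct of control)`, so the
#' control group is exactly 0.
#'
#' @param dct Delta-Ct tibble from [delta_ct()].
#' @param control Label of the control/baseline group (e.g. `"control"`, or
#'   `"day0"` for a time-course baseline).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return Tibble (`gene`, `tissue`, `group`, `n`, `log2fc`, `p_value`,
#'   `significant`); the control rows carry `log2fc = 0` and `p_value = NA`.
#'   Singleton non-control groups are reported without a p-value.
#' @export
log2fc_vs_control <- function(dct, control = "control", alpha = 0.05) {
  out <- list()
  for (gene in unique(dct$gene)) {
    for (tissue in unique(dct$tissue[dct$gene == gene])) {
      d <- dct[dct$gene == gene & dct$tissue == tissue, , drop = FALSE]
      groups <- unique(d$group)
      if (length(groups) < 2) {
        .stop("gene %s / tissue %s has fewer than 2 groups", gene, tissue)
      }
      if (!control %in% groups) {
        .stop("control group '%s' absent for gene %s / tissue %s",
              control, gene, tissue)
      }
      n_ctrl <- sum(d$group == control)
      if (n_ctrl < 2) {
        .stop("control group needs >= 2 fish (gene %s / tissue %s)", gene, tissue)
      }
      d$group <- stats::relevel(factor(d$group), ref = control)
      fit <- lm(delta_ct ~ group, data = d)
      sfit <- suppressWarnings(summary(fit))  # noiseless data fit exactly
      sm <- sfit$coefficients
      # residual sd indistinguishable from zero: the model is degenerate and
      # the t statistic undefined; handled explicitly below
      degenerate <- sfit$sigma < 1e-10 * max(1, mean(abs(d$delta_ct)))
      mu <- tapply(d$delta_ct, d$group, mean)
      ns <- tapply(d$delta_ct, d$group, length)
      for (g in levels(d$group)) {
        if (g == control) {
          out[[length(out) + 1]] <- tibble(
            gene = gene, tissue = tissue, group = g, n = unname(ns[g]),
            log2fc = 0, p_value = NA_real_, significant = FALSE)
        } else {
          est <- unname(mu[g] - mu[control])
          cf <- paste0("group", g)
          p <- if (cf %in% rownames(sm)) sm[cf, "Pr(>|t|)"] else NA_real_
          if (degenerate) {
            # noiseless data: identical values give p = 1, an exact nonzero
            # shift the smallest representable positive p
            p <- if (abs(est) < 1e-12) 1 else .Machine$double.xmin
          }
          if (ns[g] < 2) {
            message(sprintf("group %s (gene %s / tissue %s) has one fish; p omitted",
                            g, gene, tissue))
            p <- NA_real_
          }
          out[[length(out) + 1]] <- tibble(
            gene = gene, tissue = tissue, group = g, n = unname(ns[g]),
            log2fc = -est, p_value = unname(p),
            significant = !is.na(p) && p < alpha)
        }
      }
    }
  }
  do.call(rbind, out)
}
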