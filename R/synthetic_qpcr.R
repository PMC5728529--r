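# Synthetic qPCR generator: long-format Ct tables with technical duplicates,
# group effects on the log2 scale, per-sample input variation (cancelled by
# delta-Ct normalisation), reference-gene drift, and 1:2 dilution series.

#' Design of a synthetic qPCR experiment
#'
#' Ct values are generated on the cycle scale (Gaussian noise on Ct, the
#' standard qPCR error model): for a target gene,
#' `Ct = baseline + sample_shift - effect * log(2)/log(E) + biological noise`,
#' and for a reference gene `Ct = baseline + sample_shift + drift`. Each well
#' is measured as two technical replicates with independent
#' `N(0, duplicate_sd)` noise. At the default `efficiency_true = 2` one log2
#' unit of effect shifts Ct by exactly one cycle.
#'
#' @param target_genes Character vector of target gene names.
#' @param reference_genes Character vector (>= 2 for stability ranking) of
#'   reference gene names.
#' @param groups Character vector of group labels; the first is the
#'   control/baseline.
#' @param effects Numeric matrix of true log2 effects vs control,
#'   `length(groups)` rows x `length(target_genes)` columns; the control row
#'   must be zero. Defaults to all-zero.
#' @param n_fish Fish per group (scalar or per-group vector).
#' @param duplicate_sd Technical (between-duplicate) noise, Ct units.
#' @param biological_sd Between-fish noise on the target Ct, Ct units.
#' @param sample_sd Per-sample RNA-input shift common to all genes of a fish,
#'   Ct units (removed by delta-Ct normalisation).
#' @param reference_drift_sd Instability of reference genes, Ct units.
#' @param efficiency_true Amplification factor in (1, 2].
#' @param baseline_ct Named numeric vector of baseline Ct per gene; genes
#'   missing from it default to 26 (targets) / 19 (references).
#' @param tissue Tissue label written to the table.
#' @param seed Integer seed.
#' @return An object of class `sim_qpcr_design`.
#' @export
sim_qpcr_design <- function(target_genes = c("muc5b", "muc2"),
                            reference_genes = c("elf1a", "etif3"),
                            groups = c("control", "stress"),
                            effects = NULL,
                            n_fish = 15L,
                            duplicate_sd = 0.1, biological_sd = 0.3,
                            sample_sd = 0.5, reference_drift_sd = 0.1,
                            efficiency_true = 2, baseline_ct = NULL,
                            tissue = "skin", seed = 1L) {
  if (is.null(effects)) {
    effects <- matrix(0, length(groups), length(target_genes),
                      dimnames = list(groups, target_genes))
  }
  effects <- as.matrix(effects)
  if (!all(dim(effects) == c(length(groups), length(target_genes)))) {
    .stop("effects must be a %d x %d matrix (groups x target genes)",
          length(groups), length(target_genes))
  }
  dimnames(effects) <- list(groups, target_genes)
  if (any(effects[1, ] != 0)) .stop("control group effects must all be 0")
  for (s in c(duplicate_sd, biological_sd, sample_sd, reference_drift_sd)) {
    if (!is.finite(s) || s < 0) .stop("all sd parameters must be >= 0")
  }
  if (!is.finite(efficiency_true) || efficiency_true <= 1 || efficiency_true > 2) {
    .stop("efficiency_true must lie in (1, 2]")
  }
  n_fish <- as.integer(rep(n_fish, length.out = length(groups)))
  if (any(n_fish < 1)) .stop("n_fish must be >= 1 per group")
  bl <- setNames(c(rep(26, length(target_genes)), rep(19, length(reference_genes))),
                 c(target_genes, reference_genes))
  if (!is.null(baseline_ct)) bl[names(baseline_ct)] <- baseline_ct
  structure(list(target_genes = target_genes, reference_genes = reference_genes,
                 groups = groups, effects = effects, n_fish = n_fish,
                 duplicate_sd = duplicate_sd, biological_sd = biological_sd,
                 sample_sd = sample_sd, reference_drift_sd = reference_drift_sd,
                 efficiency_true = efficiency_true, baseline_ct = bl,
                 tissue = tissue, seed = as.integer(seed)),
            class = "sim_qpcr_design")
}

#' Simulate a long-format Ct table plus dilution series
#'
#' @param design A [sim_qpcr_design()].
#' @param dilution_sd Noise on the dilution-series Ct points (default 0,
#'   noiseless standard curves).
#' @return List of class `sim_qpcr` with `ct` (long Ct tibble with technical
#'   duplicates), `dilution` (5-point 1:2 series per gene: `gene`, `conc`,
#'   `ct`) and `design`.
#' @export
simulate_qpcr <- function(design = sim_qpcr_design(), dilution_sd = 0) {
  stopifnot(inherits(design, "sim_qpcr_design"))
  set.seed(design$seed)
  genes <- c(design$target_genes, design$reference_genes)
  ct_shift_per_log2 <- log(2) / log(design$efficiency_true)
  grp <- rep(design$groups, design$n_fish)
  fish <- sprintf("%s_f%02d", grp, unlist(lapply(design$n_fish, seq_len)))
  n_s <- length(fish)
  s_shift <- rnorm(n_s, 0, design$sample_sd)
  per_gene <- lapply(genes, function(gene) {
    is_ref <- gene %in% design$reference_genes
    mu <- design$baseline_ct[[gene]] + s_shift +
      if (is_ref) rnorm(n_s, 0, design$reference_drift_sd) else
        -design$effects[grp, gene] * ct_shift_per_log2 +
          rnorm(n_s, 0, design$biological_sd)
    tibble(sample_id = rep(paste(fish, design$tissue, sep = "_"), each = 2),
           fish_id = rep(fish, each = 2), tissue = design$tissue,
           group = rep(grp, each = 2), gene = gene,
           replicate = rep(1:2, n_s),
           ct = rep(mu, each = 2) + rnorm(2 * n_s, 0, design$duplicate_sd))
  })
  ct <- do.call(rbind, per_gene)
  ct <- ct[order(match(ct$fish_id, fish), match(ct$gene, genes), ct$replicate), ]
  conc <- 2^-(0:4)
  slope <- -1 / log10(design$efficiency_true)
  dil <- do.call(rbind, lapply(genes, function(g) {
    ct_pts <- design$baseline_ct[[g]] + 3 + slope * log10(conc) +
      rnorm(5, 0, dilution_sd)
    tibble(gene = g, conc = conc, ct = ct_pts)
  }))
  structure(list(ct = ct, dilution = dil, design = design), class = "sim_qpcr")
}
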