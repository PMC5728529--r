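#' Configuration of an end-to-end synthetic pipeline run
#'
#' Bundles all module parameters with a master seed; per-stage seeds are
#' derived as small offsets from it so a rerun with the same configuration
#' is bit-identical.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @param proteome A [sim_proteome_config()] (its seed is overridden by
#'   `seed`).
#' @param qpcr A [sim_qpcr_design()] (its seed is likewise derived).
#' @param pts [pts_params()] for the PTS scan.
#' @param evalue_max Domain-hit E-value threshold.
#' @param overlap_tol Domain overlap tolerance, residues.
#' @param funnel A [funnel_config()].
#' @param fp_rate Spurious-hit rate for the simulated domain table.
#' @param bootstrap_B Bootstrap pseudoreplicates for the VWD tree.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       proteome = sim_proteome_config(),
                       qpcr = sim_qpcr_design(
                         groups = c("control", "h3", "h24"),
                         effects = rbind(control = c(0, 0),
                                         h3 = c(-1.37, 0.94),
                                         h24 = c(-0.71, 1.43))),
                       pts = pts_params(), evalue_max = 1e-3,
                       overlap_tol = 10L, funnel = funnel_config(),
                       fp_rate = 0, bootstrap_B = 100L) {
  seed <- as.integer(seed)
  proteome$seed <- seed
  qpcr$seed <- seed + 3L
  structure(list(out_dir = out_dir, seed = seed, proteome = proteome,
                 qpcr = qpcr, pts = pts, evalue_max = evalue_max,
                 overlap_tol = as.integer(overlap_tol), funnel = funnel,
                 fp_rate = fp_rate, bootstrap_B = as.integer(bootstrap_B)),
            class = "run_config")
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates every input (proteome, domain table, FPKM matrix, Ct tables),
#' writes them to `inputs/`, reads them back through the format parsers,
#' runs PTS scanning, architecture building, the evidence funnel, VWD
#' extraction with a bootstrapped neighbor-joining tree, and the qPCR chain
#' (duplicate QC, efficiency, reference stability, delta-Ct, tissue
#' profile, log2 fold changes), writing per-stage TSVs plus a manifest with
#' parameters, seed and output checksums.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results (`funnel`,
#'   `tree`, `stability`, `log2fc`, `paths`, ...).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  ind <- file.path(out, "inputs")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # -- stage 1: simulate inputs -------------------------------------------
  sim <- simulate_proteome(config$proteome)
  hits0 <- simulate_domain_hits(sim$truth, fp_rate = config$fp_rate,
                                seed = config$seed + 1L)
  expr0 <- simulate_expression(sim$truth, seed = config$seed + 2L)
  qp <- simulate_qpcr(config$qpcr)
  p_fa <- file.path(ind, "proteins.fasta")
  p_dom <- file.path(ind, "domains.domtblout")
  p_expr <- file.path(ind, "fpkm.tsv")
  p_ct <- file.path(ind, "ct.tsv")
  p_dil <- file.path(ind, "dilution.tsv")
  p_truth <- file.path(ind, "truth.tsv")
  write_fasta(sim$proteins, p_fa)
  lens <- setNames(nchar(sim$proteins$sequence), sim$proteins$id)
  write_domtblout(hits0, p_dom, protein_lengths = lens)
  write_expression_tsv(expr0, p_expr)
  write_ct_table(qp$ct, p_ct)
  write.table(as.data.frame(qp$dilution), p_dil, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_truth_tsv(sim$truth, p_truth)
  say("simulated %d proteins (%d true mucins), %d domain hits",
      nrow(sim$proteins), sum(sim$truth$proteins$is_true_mucin), nrow(hits0))

  # -- stage 2: identify --------------------------------------------------
  records <- read_fasta(p_fa)
  hits <- parse_domtblout(p_dom)
  expr <- read_expression_tsv(p_expr)
  pts <- scan_pts(records, config$pts)
  archs <- build_architectures(records, hits, params = config$pts,
                               evalue_max = config$evalue_max,
                               overlap_tol = config$overlap_tol)
  report <- run_funnel(records, expr, archs, config$funnel)
  write.table(as.data.frame(pts), file.path(out, "pts_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  arch_tbl <- tibble(
    id = names(archs),
    architecture = vapply(archs, architecture_string, ""),
    architecture_grouped = vapply(archs, architecture_string, "",
                                  group = TRUE, compress = TRUE))
  write.table(as.data.frame(arch_tbl), file.path(out, "architectures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report$flags), file.path(out, "funnel_flags.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    "evidence funnel (counts within the annotated set)",
    sprintf("annotated\t%d", report$counts["n_annotated"]),
    sprintf("transcribed\t%d", report$counts["n_transcribed"]),
    sprintf("min_motif\t%d", report$counts["n_motif"]),
    sprintf("candidates\t%d", report$counts["n_candidates"]),
    paste("candidate_ids", paste(report$candidates, collapse = ","), sep = "\t")
  ), file.path(out, "funnel_summary.tsv"))
  say("funnel: %d -> %d -> %d -> %d",
      report$counts["n_annotated"], report$counts["n_transcribed"],
      report$counts["n_motif"], report$counts["n_candidates"])

  # -- stage 3: VWD phylogeny --------------------------------------------
  vwd <- do.call(rbind, lapply(report$candidates, function(id) {
    extract_vwd(archs[[id]], records[records$id == id, ])
  }))
  tree <- NULL
  if (!is.null(vwd) && nrow(vwd) >= 3 && length(unique(nchar(vwd$sequence))) == 1) {
    taxa <- paste(vwd$protein_id, vwd$label, sep = "_")
    aln <- alignment_from_strings(setNames(vwd$sequence, taxa))
    write_alignment(aln, file.path(out, "vwd_alignment.fasta"))
    tree <- bootstrap_support(aln, B = config$bootstrap_B,
                              seed = config$seed + 4L)
    write_newick(tree, file.path(out, "vwd_tree.nwk"))
    say("VWD tree: %d domains, %d bootstrap replicates",
        nrow(vwd), attr(tree, "effective_B"))
  } else {
    say("VWD tree skipped: fewer than 3 equal-length VWD domains")
  }
  if (!is.null(vwd) && nrow(vwd)) {
    write.table(as.data.frame(vwd), file.path(out, "vwd_domains.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- stage 4: qPCR ------------------------------------------------------
  ct <- read_ct_table(p_ct)
  collapsed <- suppressWarnings(collapse_duplicates(ct))
  eff <- do.call(rbind, lapply(split(qp$dilution, qp$dilution$gene), function(d) {
    e <- efficiency_from_dilution(d)
    tibble(gene = d$gene[1], efficiency = round(e$efficiency, 1),
           slope = e$slope, r_squared = e$r_squared)
  }))
  stab <- stability_ranking(
    collapsed[collapsed$gene %in% config$qpcr$reference_genes, ])
  ref <- attr(stab, "most_stable")
  dct <- delta_ct(collapsed, ref)
  dct_t <- dct[dct$gene %in% config$qpcr$target_genes, ]
  profile <- tissue_profile_matrix(dct_t)
  fc <- log2fc_vs_control(dct_t, control = config$qpcr$groups[1])
  write.table(as.data.frame(eff), file.path(out, "qpcr_efficiency.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(stab), file.path(out, "qpcr_stability.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(profile), profile, check.names = FALSE),
              file.path(out, "qpcr_tissue_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fc), file.path(out, "qpcr_log2fc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("qPCR: reference gene %s; %d group effects estimated", ref, nrow(fc))

  # -- manifest -----------------------------------------------------------
  outputs <- list.files(out, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out, c("manifest.tsv", "run.log")))
  sums <- tools::md5sum(sort(outputs))
  manifest <- data.frame(
    key = c("seed", "n_proteins", "n_true_mucins", "fp_rate", "evalue_max",
            "overlap_tol", "fpkm_threshold", "bootstrap_B",
            basename(names(sums))),
    value = c(config$seed, config$proteome$n_proteins,
              config$proteome$n_true_mucins, config$fp_rate,
              config$evalue_max, config$overlap_tol,
              config$funnel$fpkm_threshold, config$bootstrap_B,
              unname(sums))
  )
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(list(funnel = report, architectures = archs, pts = pts,
                 vwd = vwd, tree = tree, efficiency = eff, stability = stab,
                 delta_ct = dct, profile = profile, log2fc = fc,
                 truth = sim$truth, out_dir = out))
}
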