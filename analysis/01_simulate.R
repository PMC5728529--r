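#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs with known ground truth.
#
# Produces a 40-protein proteome carrying 7 planted gel-forming mucins
# (Muc5-type, Muc2-type and a short single-cassette variant), one decoy per
# evidence layer, an hmmscan-style domain table, a 9-tissue FPKM matrix, and
# qPCR Ct tables for a handling-stress design (control / 3 h / 24 h,
# n = 15 fish per group) with technical duplicates and two candidate
# reference genes.

suppressPackageStartupMessages(library(mucinscan))

out <- file.path("results", "inputs")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

cfg <- sim_proteome_config(seed = seed)
sim <- simulate_proteome(cfg)
hits <- simulate_domain_hits(sim$truth, fp_rate = 0.2, seed = seed + 1L)
expr <- simulate_expression(sim$truth, seed = seed + 2L)

qdes <- sim_qpcr_design(
  target_genes = c("muc5b", "muc2"),
  reference_genes = c("elf1a", "etif3"),
  groups = c("control", "h3", "h24"),
  effects = rbind(control = c(0, 0), h3 = c(-1.37, 0.94), h24 = c(-0.71, 1.43)),
  n_fish = 15, seed = seed + 3L)
qp <- simulate_qpcr(qdes)

write_fasta(sim$proteins, file.path(out, "proteins.fasta"))
write_domtblout(hits, file.path(out, "domains.domtblout"),
                protein_lengths = setNames(nchar(sim$proteins$sequence),
                                           sim$proteins$id))
write_expression_tsv(expr, file.path(out, "fpkm.tsv"))
write_ct_table(qp$ct, file.path(out, "ct.tsv"))
write.table(as.data.frame(qp$dilution), file.path(out, "dilution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_truth_tsv(sim$truth, file.path(out, "truth.tsv"))

tp <- sim$truth$proteins
cat(sprintf("simulated %d proteins: %d true mucins, %d decoys, %d background\n",
            nrow(tp), sum(tp$is_true_mucin),
            sum(!tp$role %in% c("true_mucin", "background")),
            sum(tp$role == "background")))
cat(sprintf("domain table: %d hits (%d planted)\n",
            nrow(hits), nrow(sim$truth$domains)))
cat(sprintf("Ct table: %d wells across %d fish\n",
            nrow(qp$ct) / 2, length(unique(qp$ct$fish_id))))
cat("inputs written under", out, "\n")
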