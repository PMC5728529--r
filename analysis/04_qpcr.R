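#!/usr/bin/env Rscript
# Stage 4 — qPCR relative quantification: duplicate QC, primer efficiency
# from the 1:2 dilution series, reference-gene stability ranking, delta-Ct
# normalisation against the most stable reference, the inverted-mean tissue
# profile, and log2 fold changes vs the control group tested with a linear
# model per gene and tissue (p < 0.05).

suppressPackageStartupMessages(library(mucinscan))

ind <- file.path("results", "inputs")
out <- "results"

ct <- read_ct_table(file.path(ind, "ct.tsv"))
dil <- read.delim(file.path(ind, "dilution.tsv"))

collapsed <- collapse_duplicates(ct)
dropped <- attr(collapsed, "qc_log")
cat(sprintf("duplicate QC: %d wells kept, %d discarded (Ct difference >= 0.5)\n",
            nrow(collapsed), nrow(dropped)))

eff <- do.call(rbind, lapply(split(dil, dil$gene), function(d) {
  e <- efficiency_from_dilution(d)
  data.frame(gene = d$gene[1], efficiency = round(e$efficiency, 1),
             slope = round(e$slope, 3), r_squared = round(e$r_squared, 4))
}))
write.table(eff, file.path(out, "qpcr_efficiency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("primer efficiencies:\n"); print(eff, row.names = FALSE)

refs <- c("elf1a", "etif3")
stab <- stability_ranking(collapsed[collapsed$gene %in% refs, ])
write.table(as.data.frame(stab), file.path(out, "qpcr_stability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ref <- attr(stab, "most_stable")
cat(sprintf("most stable reference gene: %s (aggregate rank %.2f)\n",
            ref, min(stab$aggregate_rank)))

dct <- delta_ct(collapsed, ref)
targets <- setdiff(unique(dct$gene), refs)
dct_t <- dct[dct$gene %in% targets, ]

profile <- tissue_profile_matrix(dct_t)
write.table(data.frame(gene = rownames(profile), profile, check.names = FALSE),
            file.path(out, "qpcr_tissue_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fc <- log2fc_vs_control(dct_t, control = "control")
write.table(as.data.frame(fc), file.path(out, "qpcr_log2fc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("log2 fold changes vs control:\n")
print(as.data.frame(fc[fc$group != "control",
                       c("gene", "tissue", "group", "log2fc", "p_value",
                         "significant")]),
      row.names = FALSE, digits = 3)
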