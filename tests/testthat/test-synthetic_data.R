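test_that("fixed seed gives byte-identical simulated FASTA", {
  cfg <- sim_proteome_config(n_proteins = 10, n_true_mucins = 2, seed = 1)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(simulate_proteome(cfg)$proteins, f1)
  write_fasta(simulate_proteome(cfg)$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_proteome_config(n_proteins = 3, n_true_mucins = 2),
               "too small")
  expect_error(sim_proteome_config(pts_st_frac = 0.8, pts_pro_frac = 0.3),
               "<= 1")
  expect_error(sim_proteome_config(pts_st_frac = 0), "\\(0, 1\\]")
  expect_error(sim_proteome_config(decoy_modes = "bogus"), "unknown decoy")
})

test_that("planted PTS segments are fully recovered by the detector", {
  cfg <- sim_proteome_config(n_proteins = 10, n_true_mucins = 3, pts_length = 300,
                             pts_st_frac = 0.6, pts_pro_frac = 0.1, seed = 37)
  sim <- simulate_proteome(cfg)
  found <- scan_pts(sim$proteins)
  for (i in seq_len(nrow(sim$truth$pts))) {
    tr <- sim$truth$pts[i, ]
    hit <- found[found$protein_id == tr$protein_id &
                   found$start <= tr$start & found$end >= tr$end, ]
    expect_equal(nrow(hit), 1L)
  }
})

test_that("background sequence stays far below the PTS composition bound", {
  sim <- simulate_proteome(sim_proteome_config(n_proteins = 12, n_true_mucins = 0,
                                               decoy_modes = character(0), seed = 41))
  st_frac <- vapply(sim$proteins$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("S", "T"))
  }, 0)
  expect_true(all(st_frac < 0.25))
  expect_equal(nrow(scan_pts(sim$proteins)), 0L)
})

test_that("decoys violate exactly the evidence layer their mode names", {
  cfg <- sim_proteome_config(n_proteins = 12, n_true_mucins = 2, seed = 43)
  sim <- simulate_proteome(cfg)
  tp <- sim$truth$proteins
  d <- function(mode) tp[tp$role == mode, ]
  expect_true(d("annotated_not_transcribed")$annotated &&
                !d("annotated_not_transcribed")$transcribed &&
                d("annotated_not_transcribed")$has_motif)
  expect_true(d("transcribed_no_motif")$annotated &&
                d("transcribed_no_motif")$transcribed &&
                !d("transcribed_no_motif")$has_motif)
  expect_true(!d("motif_not_annotated")$annotated &&
                d("motif_not_annotated")$transcribed &&
                d("motif_not_annotated")$has_motif)
  shuffled <- d("shuffled_motif_order")
  expect_true(shuffled$annotated && shuffled$transcribed && !shuffled$has_motif)
  # and the shuffled decoy's *built* architecture also fails the matcher
  hits <- simulate_domain_hits(sim$truth, fp_rate = 0, seed = 44)
  archs <- build_architectures(sim$proteins, hits)
  expect_false(has_min_mucin_motif(archs[[shuffled$id]]))
})

test_that("domain hit simulation matches planted truth, fp hits are resolvable", {
  cfg <- sim_proteome_config(n_proteins = 10, n_true_mucins = 3, seed = 47)
  sim <- simulate_proteome(cfg)
  h0 <- simulate_domain_hits(sim$truth, fp_rate = 0, seed = 48)
  expect_equal(nrow(h0), nrow(sim$truth$domains))
  h5 <- simulate_domain_hits(sim$truth, fp_rate = 0.5, seed = 48)
  expect_gt(nrow(h5), nrow(h0))
  planted <- sim$truth$domains
  for (id in unique(planted$protein_id)) {
    res <- resolve_overlaps(h5[h5$protein_id == id, ])
    pl <- planted[planted$protein_id == id, ]
    pl <- pl[order(pl$start), ]
    expect_equal(res[, c("protein_id", "family", "start", "end")],
                 pl[, c("protein_id", "family", "start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("expression matrix honours transcription truth over 9 tissues", {
  cfg <- sim_proteome_config(n_proteins = 20, n_true_mucins = 4, seed = 51)
  sim <- simulate_proteome(cfg)
  m <- simulate_expression(sim$truth, seed = 52)
  expect_equal(ncol(m), 9L)
  tp <- sim$truth$proteins
  expect_setequal(transcription_filter(m, 1), tp$id[tp$transcribed])
  off <- m[tp$id[!tp$transcribed], , drop = FALSE]
  expect_true(all(apply(off, 1, max) <= 1))
})

test_that("noiseless duplicates collapse without loss and efficiency is exact", {
  des <- sim_qpcr_design(duplicate_sd = 0, seed = 53)
  qp <- simulate_qpcr(des)
  col <- collapse_duplicates(qp$ct)
  expect_equal(nrow(col), nrow(qp$ct) / 2)
  expect_equal(nrow(attr(col, "qc_log")), 0L)
  for (g in unique(qp$dilution$gene)) {
    e <- efficiency_from_dilution(qp$dilution[qp$dilution$gene == g, ])
    expect_equal(e$efficiency, 2.0, tolerance = 1e-9)
  }
})

test_that("an injected -1.5 log2 effect is recovered within 0.1", {
  des <- sim_qpcr_design(target_genes = "muc5b",
                         groups = c("control", "stress"),
                         effects = rbind(control = 0, stress = -1.5),
                         n_fish = 15, duplicate_sd = 0, biological_sd = 0.05,
                         reference_drift_sd = 0, seed = 59)
  qp <- simulate_qpcr(des)
  col <- collapse_duplicates(qp$ct)
  d <- delta_ct(col, "etif3")
  fc <- log2fc_vs_control(d[d$gene == "muc5b", ], control = "control")
  est <- fc$log2fc[fc$group == "stress"]
  expect_lt(abs(est - (-1.5)), 0.1)
})

test_that("group log2FC estimates stay within 0.2 of truth at low noise", {
  # generator-level guarantee: effects in {-2,...,2}, sd <= 0.2, n >= 12
  effects <- c(-2, -1, 0, 1, 2)
  ok <- 0L; total <- 0L
  for (rep_i in 1:40) {
    des <- sim_qpcr_design(
      target_genes = "m", groups = c("control", paste0("g", 1:5)),
      effects = matrix(c(0, effects), ncol = 1,
                       dimnames = list(NULL, "m")),
      n_fish = 12, duplicate_sd = 0, biological_sd = 0.2,
      reference_drift_sd = 0, seed = 6000 + rep_i)
    qp <- simulate_qpcr(des)
    d <- delta_ct(collapse_duplicates(qp$ct), "etif3")
    fc <- log2fc_vs_control(d[d$gene == "m", ], control = "control")
    for (k in seq_along(effects)) {
      est <- fc$log2fc[fc$group == paste0("g", k)]
      ok <- ok + (abs(est - effects[k]) <= 0.2)
      total <- total + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})
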