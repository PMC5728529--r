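mk_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(sample_id = r[[1]], fish_id = r[[1]], tissue = r[[2]],
                   group = r[[3]], gene = r[[4]],
                   replicate = seq_along(r[[5]]), ct = r[[5]])
  }))
}

test_that("duplicate QC retains tight pairs and discards divergent ones", {
  ct <- mk_ct(list("s1", "skin", "c", "g", c(24.0, 24.2)),
              list("s2", "skin", "c", "g", c(24.0, 24.8)))
  out <- collapse_duplicates(ct)
  expect_equal(out$sample_id[!is.na(out$ct_diff) & out$ct_diff < 0.5], "s1")
  expect_equal(out$ct[out$sample_id == "s1"], 24.1)
  expect_false("s2" %in% out$sample_id)
  expect_equal(attr(out, "qc_log")$sample_id, "s2")
})

test_that("literal QC mode applies the rule as printed", {
  ct <- mk_ct(list("s2", "skin", "c", "g", c(24.0, 24.8)))
  out <- collapse_duplicates(ct, mode = "literal")
  expect_equal(out$sample_id, "s2")
  expect_equal(out$ct, 24.4)
})

test_that("singletons pass with a warning and triplicates are an error", {
  ct <- mk_ct(list("s1", "skin", "c", "g", 24.0))
  expect_warning(out <- collapse_duplicates(ct), "singleton")
  expect_equal(out$n_rep, 1L)
  ct3 <- tibble::tibble(sample_id = "s1", fish_id = "s1", tissue = "skin",
                        group = "c", gene = "g", replicate = c(1L, 2L, 2L),
                        ct = c(24, 24, 24))
  expect_error(collapse_duplicates(ct3), "more than 2")
})

test_that("efficiency closed form inverts dilution slopes exactly", {
  conc <- 2^-(0:4)
  for (E in c(1.8, 1.9, 2.0)) {
    drop_per_doubling <- log(2) / log(E)
    series <- data.frame(conc = conc,
                         ct = 20 - drop_per_doubling * log2(conc))
    e <- efficiency_from_dilution(series)
    expect_equal(e$efficiency, E, tolerance = 1e-9)
  }
  expect_error(efficiency_from_dilution(data.frame(conc = c(1, 0.5), ct = c(20, 21))),
               ">= 3 points")
  bad <- data.frame(conc = conc, ct = 20 + log10(conc))  # rises with dilution
  expect_error(efficiency_from_dilution(bad), "slope")
})

test_that("a constant Ct offset between two genes gives geNorm M of zero", {
  set.seed(79)
  base <- rnorm(10, 20, 1)
  m <- cbind(g1 = base, g2 = base + 3)
  st <- stability_ranking(m)
  expect_equal(st$genorm_m, c(0, 0), tolerance = 1e-12)
  expect_equal(st$comparative_dct, st$genorm_m)
})

test_that("a stable gene outranks an unstable one on all four measures", {
  set.seed(83)
  n <- 20
  m <- cbind(stable = 20 + rnorm(n, 0, 0.1),
             unstable = 22 + rnorm(n, 0, 2.0),
             middling = 21 + rnorm(n, 0, 0.8))
  st <- stability_ranking(m)
  s <- st[st$gene == "stable", ]
  expect_equal(unname(unlist(s[, c("rank_genorm", "rank_bestkeeper",
                                   "rank_comparative", "rank_normfinder")])),
               rep(1L, 4))
  expect_equal(attr(st, "most_stable"), "stable")
  expect_error(stability_ranking(m[1, , drop = FALSE]), ">= 3")
})

test_that("geNorm and comparative measures ignore per-sample shifts", {
  set.seed(89)
  m <- cbind(g1 = rnorm(12, 20, 0.5), g2 = rnorm(12, 22, 0.5),
             g3 = rnorm(12, 24, 0.5))
  m2 <- m; m2[3, ] <- m2[3, ] + 5  # global shift of one sample
  s1 <- stability_ranking(m); s2 <- stability_ranking(m2)
  expect_equal(s1$genorm_m, s2$genorm_m, tolerance = 1e-12)
  expect_equal(s1$comparative_dct, s2$comparative_dct, tolerance = 1e-12)
})

test_that("delta-Ct subtracts the reference within each sample", {
  ct <- rbind(mk_ct(list("s1", "skin", "c", "tgt", c(25, 25)),
                    list("s1", "skin", "c", "ref", c(20, 20)),
                    list("s2", "skin", "c", "tgt", c(24, 24))))
  col <- suppressWarnings(collapse_duplicates(ct))
  expect_message(d <- delta_ct(col, "ref"), "dropped")
  expect_equal(d$delta_ct[d$gene == "tgt" & d$sample_id == "s1"], 5)
  expect_equal(d$delta_ct[d$gene == "ref"], 0)
  expect_false("s2" %in% d$sample_id)
  expect_error(delta_ct(col, "nope"), "absent")
})

test_that("tissue profile is the inverted mean delta-Ct with absent cells NA", {
  d <- tibble::tibble(sample_id = paste0("s", 1:6), fish_id = paste0("f", 1:6),
                      tissue = rep(c("skin", "gill"), each = 3),
                      group = "c", gene = "muc",
                      delta_ct = c(4, 5, 6, 1, 2, 3))
  m <- tissue_profile_matrix(d)
  expect_equal(m["muc", "skin"], -5)
  expect_equal(m["muc", "gill"], -2)
  expect_gt(m["muc", "gill"], m["muc", "skin"])  # lower dCt -> larger value
  d2 <- rbind(d, tibble::tibble(sample_id = "s7", fish_id = "f7",
                                tissue = "skin", group = "c", gene = "muc2",
                                delta_ct = 1))
  m2 <- tissue_profile_matrix(d2)
  expect_true(is.na(m2["muc2", "gill"]))
  # invariant under fish reordering (up to row/column order)
  m_perm <- tissue_profile_matrix(d[sample(6), ])
  expect_equal(m_perm[rownames(m), colnames(m), drop = FALSE], m)
})

test_that("log2FC contrasts vs control behave at the degenerate extremes", {
  d0 <- tibble::tibble(sample_id = paste0("s", 1:10), fish_id = paste0("f", 1:10),
                       tissue = "skin", group = rep(c("control", "t"), each = 5),
                       gene = "muc", delta_ct = 5)
  fc0 <- log2fc_vs_control(d0)
  expect_equal(fc0$log2fc, c(0, 0))
  expect_equal(fc0$p_value[fc0$group == "t"], 1)
  d1 <- d0
  d1$delta_ct[d1$group == "t"] <- 3.5
  fc1 <- log2fc_vs_control(d1)
  expect_equal(fc1$log2fc[fc1$group == "t"], 1.5)
  expect_lt(fc1$p_value[fc1$group == "t"], 1e-10)
  expect_equal(fc1$log2fc[fc1$group == "control"], 0)
})

test_that("singleton non-control groups report an effect without a p-value", {
  d <- tibble::tibble(sample_id = paste0("s", 1:6), fish_id = paste0("f", 1:6),
                      tissue = "skin",
                      group = c("control", "control", "control", "a", "a", "b"),
                      gene = "muc", delta_ct = c(5, 5.2, 4.8, 4, 4.4, 3))
  expect_message(fc <- log2fc_vs_control(d), "one fish")
  b <- fc[fc$group == "b", ]
  expect_equal(b$log2fc, 2)
  expect_true(is.na(b$p_value))
  expect_error(log2fc_vs_control(d[d$group == "control", ]), "fewer than 2")
})

test_that("power simulation recovers a -1.5 effect with near-total rejection", {
  hits <- 0L; within <- 0L; reps <- 60
  ests <- numeric(reps)
  for (i in seq_len(reps)) {
    des <- sim_qpcr_design(target_genes = "m", groups = c("control", "s"),
                           effects = rbind(control = 0, s = -1.5), n_fish = 15,
                           duplicate_sd = 0, biological_sd = 0.3,
                           reference_drift_sd = 0, seed = 9000 + i)
    qp <- simulate_qpcr(des)
    d <- delta_ct(collapse_duplicates(qp$ct), "etif3")
    fc <- log2fc_vs_control(d[d$gene == "m", ])
    row <- fc[fc$group == "s", ]
    ests[i] <- row$log2fc
    hits <- hits + (row$p_value < 0.05)
  }
  expect_gt(hits / reps, 0.99)
  expect_lt(abs(mean(ests) - (-1.5)), 0.05)
})
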