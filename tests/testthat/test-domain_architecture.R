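mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein_id = "p",
    family = vapply(rows, `[[`, "", 1),
    start = as.integer(vapply(rows, function(r) r[[2]], 0)),
    end = as.integer(vapply(rows, function(r) r[[3]], 0)),
    i_evalue = vapply(rows, function(r) r[[4]], 0),
    score = vapply(rows, function(r) if (length(r) > 4) r[[5]] else 10, 0)
  )
}

test_that("filter_hits keeps hits at or below the E-value threshold", {
  h <- mk_hits(list("VWD", 1, 100, 1e-10), list("C8", 200, 260, 0.5))
  expect_equal(nrow(filter_hits(h, 1e-3)), 1L)
  expect_equal(nrow(filter_hits(h[0, ], 1e-3)), 0L)
  expect_equal(filter_hits(h, Inf), h)
})

test_that("resolve_overlaps keeps the best E-value among identical spans", {
  h <- mk_hits(list("VWD", 1, 100, 1e-5), list("C8", 1, 100, 1e-20))
  out <- resolve_overlaps(h)
  expect_equal(nrow(out), 1L)
  expect_equal(out$family, "C8")
})

test_that("disjoint hits are all kept in coordinate order", {
  h <- mk_hits(list("TIL", 300, 360, 1e-4), list("VWD", 1, 100, 1e-8),
               list("C8", 150, 220, 1e-6))
  out <- resolve_overlaps(h)
  expect_equal(out$family, c("VWD", "C8", "TIL"))
  expect_equal(out$start, c(1L, 150L, 300L))
})

test_that("the greedy chain rule keeps flank-sharing hits within tolerance", {
  h <- mk_hits(list("VWD", 1, 100, 1e-9), list("C8", 90, 190, 1e-8),
               list("TIL", 180, 280, 1e-7))
  out <- resolve_overlaps(h, overlap_tol = 10)
  expect_equal(nrow(out), 3L)
  # a tighter tolerance breaks the chain
  out2 <- resolve_overlaps(h, overlap_tol = 5)
  expect_equal(out2$family, c("VWD", "TIL"))
})

test_that("resolve_overlaps output is overlap-free and deterministic", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    s <- sample(1:400, n, replace = TRUE)
    h <- tibble::tibble(protein_id = "p", family = sample(c("VWD", "C8", "TIL"),
                                                          n, replace = TRUE),
                        start = s, end = s + sample(40:120, n, replace = TRUE),
                        i_evalue = 10^-runif(n, 2, 12), score = runif(n, 10, 90))
    out <- resolve_overlaps(h, overlap_tol = 10)
    if (nrow(out) > 1) {
      for (a in 1:(nrow(out) - 1)) for (b in (a + 1):nrow(out)) {
        ov <- min(out$end[a], out$end[b]) - max(out$start[a], out$start[b])
        expect_lte(ov, 10)
      }
    }
    expect_identical(out, resolve_overlaps(h[sample(n), ], overlap_tol = 10))
  }
})

test_that("build_architecture interleaves domains and PTS by start", {
  hits <- mk_hits(list("VWD", 1, 100, 1e-9), list("C8", 110, 150, 1e-9),
                  list("TIL", 160, 200, 1e-9))
  pts <- tibble::tibble(protein_id = "p", start = 250L, end = 500L)
  a <- build_architecture(hits, pts)
  expect_equal(architecture_string(a), "VWD-C8-TIL-PTS")
  b <- build_architecture(hits[0, ], pts, protein_id = "p")
  expect_equal(architecture_string(b), "PTS")
})

test_that("PTS regions overlapping a domain are truncated to the free interval", {
  hits <- mk_hits(list("VWD", 100, 260, 1e-9))
  pts <- tibble::tibble(protein_id = "p", start = 200L, end = 500L)
  a <- build_architecture(hits, pts)
  el <- a$elements
  expect_equal(el$element, c("VWD", "PTS"))
  expect_equal(el$start[el$element == "PTS"], 261L)
  expect_equal(el$end[el$element == "PTS"], 500L)
})

test_that("grouped rendering brackets cassettes, with optional compression", {
  muc2_human <- c(rep(c("VWD", "C8", "TIL"), 3), "PTS", "VWD", "C8", "TIL")
  expect_equal(architecture_string(muc2_human, group = TRUE),
               "(VWD-C8-TIL)-(VWD-C8-TIL)-(VWD-C8-TIL)-PTS-(VWD-C8-TIL)")
  muc5 <- c(rep(c("VWD", "C8", "TIL", "VWC"), 3), "PTS", "VWD", "C8", "TIL")
  expect_equal(architecture_string(muc5, group = TRUE, compress = TRUE),
               "3X(VWD-C8-TIL-VWC)-PTS-(VWD-C8-TIL)")
  # grouping is presentation-only
  expect_equal(architecture_string(muc5), paste(muc5, collapse = "-"))
})

test_that("minimum mucin motif requires consecutive VWD-C8-TIL, PTS transparent", {
  expect_true(has_min_mucin_motif(c("VWD", "C8", "TIL", "VWC")))
  expect_false(has_min_mucin_motif(c("C8", "VWD", "TIL")))
  expect_true(has_min_mucin_motif(c("VWD", "PTS", "C8", "TIL")))
  expect_false(has_min_mucin_motif(c("VWD", "VWC", "C8", "TIL")))  # blocked
  expect_false(has_min_mucin_motif(character(0)))
})

test_that("motif detection is invariant under PTS insertion and removal", {
  set.seed(29)
  for (i in 1:30) {
    el <- sample(c("VWD", "C8", "TIL", "VWC", "CTCK"), sample(3:7, 1),
                 replace = TRUE)
    base <- has_min_mucin_motif(el)
    pos <- sample(0:length(el), 1)
    expect_equal(has_min_mucin_motif(append(el, "PTS", after = pos)), base)
    expect_equal(has_min_mucin_motif(el[el != "PTS"]), base)
  }
})

test_that("extract_vwd labels domains D1..Dk from the N-terminus", {
  a <- arch_of(c("VWD", "C8", "TIL", "VWD", "C8", "TIL", "VWD", "PTS", "VWD"))
  prot <- list(id = "p", sequence = strrep("A", 2000))
  v <- extract_vwd(a, prot)
  expect_equal(v$label, c("D1", "D2", "D3", "D4"))
  expect_equal(nchar(v$sequence), v$end - v$start + 1)
  expect_equal(nrow(extract_vwd(arch_of(c("C8", "TIL")), prot)), 0L)
  short <- list(id = "p", sequence = strrep("A", 50))
  expect_error(extract_vwd(a, short), "exceed")
})
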