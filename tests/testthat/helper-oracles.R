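# Independent oracles and small fixture builders shared across tests.

# Brute-force PTS oracle: enumerate every window of size params$window,
# check the composition criterion directly on the substring, and return the
# sorted set of residue positions covered by any qualifying window.
brute_force_pts_positions <- function(sequence, params = pts_params()) {
  w <- params$window
  L <- nchar(sequence)
  if (L < w) return(integer(0))
  covered <- logical(L)
  for (s in seq_len(L - w + 1)) {
    if (window_qualifies(substring(sequence, s, s + w - 1), params)) {
      covered[s:(s + w - 1)] <- TRUE
    }
  }
  which(covered)
}

# positions covered by scan_pts regions
scan_pts_positions <- function(sequence, params = pts_params()) {
  r <- scan_pts(c(x = sequence), params)
  if (nrow(r) == 0) return(integer(0))
  sort(unique(unlist(mapply(seq, r$start, r$end, SIMPLIFY = FALSE))))
}

# random test sequence with composition hovering around the PTS bounds so
# that qualifying and non-qualifying windows both occur
random_boundary_sequence <- function(len) {
  st <- runif(1, 0.30, 0.50)
  p <- runif(1, 0.03, 0.08)
  pool <- c("S", "T", "P", "A", "G", "L", "V", "E", "K")
  prob <- c(st / 2, st / 2, p, rep((1 - st - p) / 6, 6))
  paste(sample(pool, len, replace = TRUE, prob = prob), collapse = "")
}

# 100-mer with exact residue counts, shuffled
window_of <- function(...) {
  parts <- list(...)
  ch <- unlist(lapply(parts, function(p) rep(p$res, p$n)))
  stopifnot(length(ch) == 100)
  paste(ch, collapse = "")
}

# quick architecture object from element names with synthetic coordinates
arch_of <- function(elements, protein_id = "p") {
  n <- length(elements)
  if (n == 0) {
    return(build_architecture(
      tibble::tibble(protein_id = character(), family = character(),
                     start = integer(), end = integer(),
                     i_evalue = numeric(), score = numeric()),
      protein_id = protein_id))
  }
  starts <- seq(1L, by = 200L, length.out = n)
  hits <- tibble::tibble(protein_id = protein_id, family = elements,
                         start = starts, end = starts + 99L,
                         i_evalue = 1e-10, score = 100)
  dom <- hits[hits$family != "PTS", , drop = FALSE]
  pts <- hits[hits$family == "PTS", c("protein_id", "start", "end")]
  build_architecture(dom, pts, protein_id = protein_id)
}

# support value attached to the edge realizing the unrooted bipartition
# {taxa} | {rest}; NA if the tree has no such edge
bipartition_support <- function(tree, taxa) {
  nt <- ape::Ntip(tree)
  all_tips <- tree$tip.label
  for (node in seq(nt + 2, nt + tree$Nnode)) {
    desc <- ape::extract.clade(tree, node)$tip.label
    if (setequal(desc, taxa) || setequal(desc, setdiff(all_tips, taxa))) {
      return(as.numeric(tree$node.label[node - nt]))
    }
  }
  NA_real_
}

# random additive distance matrix from a random tree, plus the tree
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, D = stats::cophenetic(tr))
}
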