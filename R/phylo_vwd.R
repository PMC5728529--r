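#' Pairwise distances from a protein domain alignment
#'
#' Pairwise-deletion distances: for each pair of taxa, only columns where
#' neither row is a gap (`-` or `.`) are compared. `model = "p"` gives the
#' proportion of differing sites; `model = "poisson"` applies the Poisson
#' correction `d = -ln(1 - p)`.
#'
#' @param aln Character alignment matrix (taxa x columns, see
#'   [alignment_from_strings()]) or named character vector of aligned
#'   strings.
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  if (!is.matrix(aln)) aln <- alignment_from_strings(aln)
  if (nrow(aln) < 2) .stop("alignment needs >= 2 taxa")
  taxa <- rownames(aln)
  gap <- aln == "-" | aln == "."
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      n_ok <- sum(ok)
      if (n_ok == 0) {
        .stop("no shared non-gap columns for pair %s / %s", taxa[i], taxa[j])
      }
      p <- sum(aln[i, ok] != aln[j, ok]) / n_ok
      d <- if (model == "p") p else {
        if (p >= 1) .stop("saturated pair %s / %s (p = 1): Poisson distance undefined",
                          taxa[i], taxa[j])
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration with deterministic tie-breaking:
#' among equal-minimum Q values the pair with the lowest (row, column) index
#' is joined. Exact on additive distance matrices; negative branch lengths
#' are retained as computed.
#'
#' @param D Symmetric distance matrix with >= 3 taxa and zero diagonal.
#' @return Unrooted tree of class `phylo` (from \pkg{ape}).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) .stop("neighbor joining needs >= 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > 1e-8) .stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) .stop("distance matrix must have a zero diagonal")
  taxa <- rownames(D)
  # placeholder labels avoid any Newick quoting issues; restored at the end
  lab <- paste0("zz", seq_len(n), "zz")
  sub <- lab
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    Da <- D[active, active, drop = FALSE]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair among minima: scan i < j in row-major order
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- Da[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Da[i, j] - vi
    newd <- (Da[i, ] + Da[j, ] - Da[i, j]) / 2
    ai <- active[i]; aj <- active[j]
    merged <- sprintf("(%s:%.12g,%s:%.12g)", sub[ai], vi, sub[aj], vj)
    # reuse slot ai for the merged cluster
    D[ai, active] <- D[active, ai] <- newd
    D[ai, ai] <- 0
    sub[ai] <- merged
    active <- active[-j]
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[a[1]], v1, sub[a[2]], v2, sub[a[3]], v3)
  tr <- ape::read.tree(text = nwk)
  idx <- as.integer(sub("^zz(\\d+)zz$", "\\1", tr$tip.label))
  tr$tip.label <- taxa[idx]
  tr
}

#' Bootstrap support for the full-data neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the tree
#' for each pseudoreplicate, and annotates each internal bipartition of the
#' full-data tree with the percentage of replicate trees containing it
#' (stored in `node.label`). Replicates on which a distance is undefined
#' (all-gap pair overlap or Poisson saturation) are skipped and logged; the
#' percentage is taken over the effective number of replicates, reported in
#' attribute `"effective_B"`.
#'
#' @param aln Alignment matrix or named aligned strings.
#' @param B Number of bootstrap pseudoreplicates (default 100).
#' @param seed Integer seed.
#' @param model Distance model passed to [pairwise_distance()].
#' @return `phylo` tree with supports in `node.label` (the basal node label
#'   is `NA`; pendant edges carry no support by construction).
#' @export
bootstrap_support <- function(aln, B = 100L, seed = 1L, model = "poisson") {
  if (!is.matrix(aln)) aln <- alignment_from_strings(aln)
  B <- as.integer(B)
  if (B < 1) .stop("B must be >= 1")
  full <- nj_tree(pairwise_distance(aln, model))
  set.seed(seed)
  L <- ncol(aln)
  reps <- list(); skipped <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    tr <- tryCatch(nj_tree(pairwise_distance(aln[, cols, drop = FALSE], model)),
                   error = function(e) NULL)
    if (is.null(tr)) skipped <- skipped + 1L else reps[[length(reps) + 1]] <- tr
  }
  if (skipped > 0) {
    message(sprintf("%d bootstrap replicate(s) skipped (undefined distances)", skipped))
  }
  b_eff <- length(reps)
  if (b_eff == 0) .stop("all bootstrap replicates failed")
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / b_eff, 1)
  support[1] <- NA_real_  # basal trifurcation: trivial bipartition
  full$node.label <- support
  attr(full, "effective_B") <- b_eff
  attr(full, "skipped") <- skipped
  full
}

#' Root a tree on an outgroup taxon
#'
#' @param tree A `phylo` tree.
#' @param outgroup_taxon Leaf label to root on (its pendant edge becomes the
#'   root edge).
#' @return Rooted `phylo` tree; node labels (bootstrap supports) follow
#'   their edges.
#' @export
root_at <- function(tree, outgroup_taxon) {
  if (!outgroup_taxon %in% tree$tip.label) {
    .stop("outgroup '%s' is not a leaf of the tree", outgroup_taxon)
  }
  ape::root(tree, outgroup = outgroup_taxon, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Write / read a tree in Newick format
#'
#' Supports are written as internal node labels; the output string ends with
#' `;` and parses back to an isomorphic tree.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly (`read_newick` returns the tree).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
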