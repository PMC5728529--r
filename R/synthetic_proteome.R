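# Synthetic proteome generator: plants mucin-like domain architectures and
# PTS-rich segments into background sequence with known ground truth, plus
# decoys that each violate exactly one evidence layer of the funnel.

# typical Pfam envelope lengths for the cassette domains; VWD is held fixed
# so extracted VWD domains stack into an ungapped alignment
.DOMAIN_LEN <- c(VWD = 160L, C8 = 70L, TIL = 60L, VWC = 70L,
                 CTCK = 90L, Mucin2_WxxW = 50L)

# background amino-acid frequencies, deliberately poor in S/T/P so that no
# unplanted 100-residue window can approach the PTS composition bounds
.BACKGROUND_FREQ <- local({
  f <- setNames(rep(1, 20), .AA20)
  f[c("S", "T")] <- 0.3
  f["P"] <- 0.4
  f / sum(f)
})

.DECOY_MODES <- c("annotated_not_transcribed", "transcribed_no_motif",
                  "motif_not_annotated", "shuffled_motif_order")

#' Mucin-family architecture templates
#'
#' Element sequences used to plant true mucins: the canonical Muc5-type
#' template (three VWD-C8-TIL-VWC cassettes, a PTS segment and a C-terminal
#' VWD-C8-TIL), the MUC2-type template (three VWD-C8-TIL cassettes, PTS,
#' VWD-C8-TIL), and a short single-cassette variant.
#'
#' @return Named list of character vectors of element names.
#' @export
default_mucin_templates <- function() {
  list(
    muc5_type = c(rep(c("VWD", "C8", "TIL", "VWC"), 3), "PTS", "VWD", "C8", "TIL"),
    muc2_type = c(rep(c("VWD", "C8", "TIL"), 3), "PTS", "VWD", "C8", "TIL"),
    short_type = c("VWD", "C8", "TIL", "PTS", "VWD", "C8", "TIL")
  )
}

#' Configuration for the synthetic proteome
#'
#' @param n_proteins Total number of proteins.
#' @param n_true_mucins Number of planted true mucins (must fit alongside one
#'   decoy per requested mode).
#' @param architecture_templates List of element-name vectors cycled over the
#'   true mucins; see [default_mucin_templates()].
#' @param pts_length Length of planted PTS segments in residues (>= 100).
#' @param pts_st_frac Combined serine+threonine fraction of planted PTS
#'   segments, in (0, 1].
#' @param pts_pro_frac Proline fraction of planted PTS segments.
#' @param decoy_modes Subset of
#'   `c("annotated_not_transcribed", "transcribed_no_motif",
#'   "motif_not_annotated", "shuffled_motif_order")`; one decoy of each
#'   requested mode is planted.
#' @param vwd_ancestor_rate Per-site substitution rate from the shared root
#'   VWD to each positional (D1, D2, ...) ancestor.
#' @param vwd_tip_rate Per-site substitution rate from a positional ancestor
#'   to each planted VWD copy. Together the two rates keep same-position
#'   copies similar and cross-position copies clearly diverged but
#'   unsaturated.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `sim_proteome_config`.
#' @export
sim_proteome_config <- function(n_proteins = 40L, n_true_mucins = 7L,
                                architecture_templates = default_mucin_templates(),
                                pts_length = 300L, pts_st_frac = 0.6,
                                pts_pro_frac = 0.1,
                                decoy_modes = .DECOY_MODES,
                                vwd_ancestor_rate = 0.3,
                                vwd_tip_rate = 0.1,
                                seed = 1L) {
  n_proteins <- as.integer(n_proteins); n_true_mucins <- as.integer(n_true_mucins)
  if (is.na(n_proteins) || n_proteins < 1) .stop("n_proteins must be >= 1")
  if (is.na(n_true_mucins) || n_true_mucins < 0) .stop("n_true_mucins must be >= 0")
  if (n_true_mucins + length(decoy_modes) > n_proteins) {
    .stop("n_proteins too small for %d mucins plus %d decoys",
          n_true_mucins, length(decoy_modes))
  }
  if (!all(decoy_modes %in% .DECOY_MODES)) {
    .stop("unknown decoy mode(s): %s",
          paste(setdiff(decoy_modes, .DECOY_MODES), collapse = ", "))
  }
  if (!is.finite(pts_st_frac) || pts_st_frac <= 0 || pts_st_frac > 1) {
    .stop("pts_st_frac must lie in (0, 1]")
  }
  if (!is.finite(pts_pro_frac) || pts_pro_frac < 0) .stop("pts_pro_frac must be >= 0")
  if (pts_st_frac + pts_pro_frac > 1) .stop("pts_st_frac + pts_pro_frac must be <= 1")
  if (as.integer(pts_length) < 100L) .stop("pts_length must be >= 100")
  for (r in c(vwd_ancestor_rate, vwd_tip_rate)) {
    if (!is.finite(r) || r < 0 || r > 1) .stop("VWD substitution rates must lie in [0, 1]")
  }
  structure(list(n_proteins = n_proteins, n_true_mucins = n_true_mucins,
                 architecture_templates = architecture_templates,
                 pts_length = as.integer(pts_length),
                 pts_st_frac = pts_st_frac, pts_pro_frac = pts_pro_frac,
                 decoy_modes = decoy_modes,
                 vwd_ancestor_rate = vwd_ancestor_rate,
                 vwd_tip_rate = vwd_tip_rate, seed = as.integer(seed)),
            class = "sim_proteome_config")
}

.sample_background <- function(n) {
  paste(sample(names(.BACKGROUND_FREQ), n, replace = TRUE,
               prob = .BACKGROUND_FREQ), collapse = "")
}

# substitute each position with probability `rate` by a different residue
.mutate_seq <- function(sequence, rate) {
  ch <- strsplit(sequence, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    repl <- sample(names(.BACKGROUND_FREQ), sum(hit), replace = TRUE,
                   prob = .BACKGROUND_FREQ)
    same <- repl == ch[hit]
    while (any(same)) {  # force a visible substitution
      repl[same] <- sample(names(.BACKGROUND_FREQ), sum(same), replace = TRUE,
                           prob = .BACKGROUND_FREQ)
      same <- repl == ch[hit]
    }
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

# Planted PTS construction: one 100-residue unit with *exact* composition
# counts (round(100*st_frac) S/T, round(100*pro_frac) P, filler from non-STP
# background), tiled to the requested length. A sliding 100-window over a
# 100-periodic sequence contains every unit position exactly once, so every
# interior window has exactly the unit composition.
.sample_pts <- function(len, st_frac, pro_frac) {
  n_st <- round(100 * st_frac)
  n_p <- round(100 * pro_frac)
  filler_pool <- setdiff(.AA20, c("S", "T", "P"))
  unit <- c(sample(c("S", "T"), n_st, replace = TRUE),
            rep("P", n_p),
            sample(filler_pool, 100 - n_st - n_p, replace = TRUE))
  unit <- sample(unit)  # one random arrangement, then tiled verbatim
  paste(rep(unit, length.out = len), collapse = "")
}

# assemble a protein from element names; returns sequence + element coords.
# Planted VWD copies descend from per-position ancestors (themselves derived
# from a shared root), so extracted VWDs carry phylogenetic signal: copies at
# the same N-terminal rank cluster together, as expected for mucin VWDs.
.assemble_protein <- function(elements, cfg, vwd_ancestors = NULL) {
  pieces <- character(0)
  coords <- list()
  pos <- 1L
  vwd_k <- 0L
  lead <- sample(10:40, 1)
  pieces <- c(pieces, .sample_background(lead)); pos <- pos + lead
  for (e in elements) {
    len <- if (e == "PTS") cfg$pts_length else .DOMAIN_LEN[[e]]
    seq_e <- if (e == "PTS") {
      .sample_pts(len, cfg$pts_st_frac, cfg$pts_pro_frac)
    } else if (e == "VWD" && !is.null(vwd_ancestors)) {
      vwd_k <- vwd_k + 1L
      anc <- vwd_ancestors[[min(vwd_k, length(vwd_ancestors))]]
      .mutate_seq(anc, cfg$vwd_tip_rate)
    } else {
      .sample_background(len)
    }
    coords[[length(coords) + 1]] <- list(element = e, start = pos, end = pos + len - 1L)
    pieces <- c(pieces, seq_e); pos <- pos + len
    gap <- sample(12:40, 1)  # > overlap_tol, keeps planted hits non-conflicting
    pieces <- c(pieces, .sample_background(gap)); pos <- pos + gap
  }
  list(sequence = paste(pieces, collapse = ""),
       coords = do.call(rbind, lapply(coords, function(x)
         data.frame(element = x$element, start = x$start, end = x$end))))
}

.MUCIN_DESCRIPTIONS <- c("mucin-5AC-like protein", "mucin-5B-like protein",
                         "mucin-2-like protein")
.BACKGROUND_DESCRIPTIONS <- c("collagen alpha-1 chain", "zinc finger protein",
                              "uncharacterized protein", "keratin, type I",
                              "heat shock protein beta")

#' Simulate a proteome with planted mucins and layer-specific decoys
#'
#' Plants `n_true_mucins` proteins carrying full mucin architectures (with
#' PTS segments whose every 100-residue window satisfies the PTS criterion),
#' one decoy per requested mode -- each violating exactly the evidence
#' layer(s) its name states -- and background proteins. Background
#' composition is deliberately S/T/P-poor so decoys cannot contain
#' accidental PTS windows.
#'
#' @param config A [sim_proteome_config()].
#' @return List with `proteins` (records tibble: `id`, `description`,
#'   `sequence`) and `truth` (class `sim_truth`: `proteins` flag tibble,
#'   `domains` planted-domain tibble, `pts` planted-PTS tibble, `config`).
#' @export
simulate_proteome <- function(config = sim_proteome_config()) {
  stopifnot(inherits(config, "sim_proteome_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  roles <- c(rep("true_mucin", config$n_true_mucins), config$decoy_modes)
  roles <- c(roles, rep("background", n - length(roles)))
  ids <- sprintf("SP%04d", seq_len(n))
  templates <- config$architecture_templates

  # shared VWD evolutionary structure: root -> positional ancestors -> copies
  max_vwd <- max(1L, vapply(templates, function(t) sum(t == "VWD"), 0L))
  vwd_root <- .sample_background(.DOMAIN_LEN[["VWD"]])
  vwd_ancestors <- lapply(seq_len(max_vwd), function(k)
    .mutate_seq(vwd_root, config$vwd_ancestor_rate))
  names(vwd_ancestors) <- paste0("D", seq_len(max_vwd))

  recs <- vector("list", n)
  flag_rows <- vector("list", n)
  dom_rows <- list(); pts_rows <- list()
  for (i in seq_len(n)) {
    role <- roles[i]
    if (role == "true_mucin") {
      el <- templates[[((i - 1) %% length(templates)) + 1]]
      desc <- .MUCIN_DESCRIPTIONS[((i - 1) %% length(.MUCIN_DESCRIPTIONS)) + 1]
      annotated <- TRUE; transcribed <- TRUE
    } else if (role == "annotated_not_transcribed") {
      el <- templates[[1]]
      desc <- "mucin-like protein"
      annotated <- TRUE; transcribed <- FALSE
    } else if (role == "transcribed_no_motif") {
      el <- c("VWD", "VWC", "CTCK")  # VWD present but no C8-TIL cassette
      desc <- "mucin-related protein"
      annotated <- TRUE; transcribed <- TRUE
    } else if (role == "motif_not_annotated") {
      el <- c("VWD", "C8", "TIL", "PTS", "VWD", "C8", "TIL")
      desc <- "von Willebrand factor D and EGF domain-containing protein"
      annotated <- FALSE; transcribed <- TRUE
    } else if (role == "shuffled_motif_order") {
      el <- c("C8", "VWD", "TIL", "PTS")  # same parts, wrong grammar
      desc <- "mucin-like protein, partial"
      annotated <- TRUE; transcribed <- TRUE
    } else {
      el <- character(0)
      desc <- .BACKGROUND_DESCRIPTIONS[((i - 1) %% length(.BACKGROUND_DESCRIPTIONS)) + 1]
      annotated <- FALSE; transcribed <- runif(1) < 0.5
    }
    asm <- .assemble_protein(el, config, vwd_ancestors)
    recs[[i]] <- tibble(id = ids[i], description = desc, sequence = asm$sequence)
    if (!is.null(asm$coords) && nrow(asm$coords)) {
      cc <- asm$coords
      dom <- cc[cc$element != "PTS", , drop = FALSE]
      pts <- cc[cc$element == "PTS", , drop = FALSE]
      if (nrow(dom)) {
        dom_rows[[length(dom_rows) + 1]] <-
          tibble(protein_id = ids[i], family = dom$element,
                 start = as.integer(dom$start), end = as.integer(dom$end))
      }
      if (nrow(pts)) {
        pts_rows[[length(pts_rows) + 1]] <-
          tibble(protein_id = ids[i],
                 start = as.integer(pts$start), end = as.integer(pts$end))
      }
    }
    has_motif <- has_min_mucin_motif(el)
    flag_rows[[i]] <- tibble(
      id = ids[i], role = role, description = desc,
      annotated = annotated, transcribed = transcribed, has_motif = has_motif,
      is_true_mucin = annotated && transcribed && has_motif,
      architecture = architecture_string(el),
      length = nchar(asm$sequence)
    )
  }
  proteins <- do.call(rbind, recs)
  truth <- structure(list(
    proteins = do.call(rbind, flag_rows),
    domains = if (length(dom_rows)) do.call(rbind, dom_rows) else
      tibble(protein_id = character(), family = character(),
             start = integer(), end = integer()),
    pts = if (length(pts_rows)) do.call(rbind, pts_rows) else
      tibble(protein_id = character(), start = integer(), end = integer()),
    vwd_ancestors = c(list(root = vwd_root), vwd_ancestors),
    config = config
  ), class = "sim_truth")
  list(proteins = proteins, truth = truth)
}

#' Simulate an hmmscan-style domain hit table from planted truth
#'
#' One hit per planted domain, with E-values well below the default 1e-3
#' threshold. With `fp_rate > 0`, spurious hits overlapping planted domains
#' are added with strictly worse E-values, so that [resolve_overlaps()]
#' recovers exactly the planted hits.
#'
#' @param truth A `sim_truth` object.
#' @param fp_rate Probability, per planted domain, of adding one spurious
#'   overlapping hit; in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble of domain hits in shuffled row order.
#' @export
simulate_domain_hits <- function(truth, fp_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.finite(fp_rate) || fp_rate < 0 || fp_rate >= 1) {
    .stop("fp_rate must lie in [0, 1)")
  }
  set.seed(seed)
  d <- truth$domains
  n <- nrow(d)
  if (n == 0) {
    return(tibble(protein_id = character(), family = character(),
                  start = integer(), end = integer(),
                  i_evalue = numeric(), score = numeric()))
  }
  iev <- 10^(-runif(n, 8, 30))
  hits <- tibble(protein_id = d$protein_id, family = d$family,
                 start = d$start, end = d$end, i_evalue = iev,
                 score = -2 * log10(iev) + runif(n, 0, 5))
  fp <- which(runif(n) < fp_rate)
  if (length(fp)) {
    # shift bounded so every spurious hit still conflicts (extent > 10) with
    # its source domain, whatever the domain length in .DOMAIN_LEN
    shift <- sample(15:30, length(fp), replace = TRUE)
    sp <- tibble(
      protein_id = d$protein_id[fp],
      family = sample(.MUCIN_DOMAINS, length(fp), replace = TRUE),
      start = d$start[fp] + shift,
      end = d$end[fp] + shift,
      i_evalue = pmin(hits$i_evalue[fp] * 10^runif(length(fp), 2, 4), 5e-4),
      score = hits$score[fp] / 2
    )
    hits <- rbind(hits, sp)
  }
  hits[sample(nrow(hits)), , drop = FALSE]
}

.DEFAULT_TISSUES <- c("pyloric_caeca", "foregut", "skin", "pancreas", "gill",
                      "spleen", "liver", "heart", "brain")

#' Simulate a tissue FPKM matrix from planted truth
#'
#' Genes flagged transcribed receive 1-3 signal tissues with FPKM well above
#' 1 and low background elsewhere; non-transcribed genes stay at or below 1
#' in every tissue.
#'
#' @param truth A `sim_truth` object.
#' @param seed Integer seed.
#' @param tissues Tissue (column) names; default is a 9-tissue panel.
#' @return Numeric genes x tissues matrix.
#' @export
simulate_expression <- function(truth, seed = 1L, tissues = .DEFAULT_TISSUES) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  p <- truth$proteins
  m <- matrix(runif(nrow(p) * length(tissues), 0, 0.95),
              nrow = nrow(p), dimnames = list(p$id, tissues))
  for (i in which(p$transcribed)) {
    k <- sample(1:3, 1)
    sig <- sample(length(tissues), k)
    m[i, sig] <- 10^runif(k, 0.7, 2.5)
  }
  round(m, 3)
}

#' Write the ground-truth manifest as TSV
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(as.data.frame(truth$proteins), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
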