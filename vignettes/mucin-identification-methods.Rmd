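---
title: "Methods: multi-evidence mucin identification and qPCR stress-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence mucin identification and qPCR stress-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinscan)
```

## The problem

Secreted gel-forming mucins (Muc2 and Muc5 families) oligomerise through
cysteine-rich cassettes — von Willebrand D (VWD), C8 and trypsin-inhibitor-
like (TIL) domains, sometimes extended by VWC, CTCK or Mucin2_WxxW — and
carry long Pro/Thr/Ser-rich (PTS) segments that are densely O-glycosylated.
Annotating them in a genome is unreliable from any single source: keyword
annotation over-calls (many VWD-bearing non-mucins are named "mucin-like"),
many annotated loci are never transcribed, and the PTS segments defeat both
Pfam models and assemblers. `mucinscan` therefore demands three independent
layers of evidence at once and treats everything else as a decoy.

## The evidence funnel

`run_funnel()` computes three per-gene flags and intersects them:

* **annotated** — the FASTA description contains a keyword, default
  `"mucin"`, matched as a case-insensitive substring. The empty keyword
  matches everything, which turns the layer off.
* **transcribed** — maximum FPKM across tissues is strictly greater than
  the threshold (default 1). The complementary phrasing — "FPKM ≤ 1 in
  every tissue means not transcribed" — motivates the strict inequality.
* **has_motif** — the ordered domain architecture contains VWD, C8, TIL
  consecutively. PTS elements are transparent to the matcher (a PTS can
  interrupt the cassette without breaking it) but any other domain blocks
  it: the minimum cassette is read as a contiguous structural unit, not a
  scattered triple. A fully gapped reading would accept architectures such
  as VWD-CTCK-C8-CTCK-TIL that no gel-forming mucin shows.

Stage counts are reported *within the annotated set* (transcribed-of-
annotated, motif-of-annotated), matching the usual presentation of such
funnels as successive restrictions of the annotation universe, and the
candidate set is the three-way intersection. The counts are therefore
non-increasing in the order annotated → transcribed → candidates, which the
test suite asserts as a property.

## PTS detection

PTS segments have no Pfam model, so they are found compositionally.
With parameters `pts_params(window = 100, st_min_frac = 0.40,
pro_min_frac = 0.05, step = 1)`, a window of 100 residues qualifies iff the
combined serine+threonine fraction is **strictly** greater than 0.40 and the
proline fraction is **at least** 0.05 — the bound types differ deliberately
and are kept exactly as the definition states. "Serine or threonine" is read
as the combined S+T fraction (the standard PTS usage), not as
either-residue-alone. `X` residues count toward window length but toward no
composition class, which can only make the detector more conservative.

`scan_pts()` slides the window at stride 1 (maximal sensitivity; the stride
is configurable but every guarantee below is stated at stride 1) and merges
all qualifying windows whose spans overlap **or abut** into maximal regions,
reporting per-region maxima of the window fractions. Sequences shorter than
the window yield no regions — the statistic is defined at window 100 and a
shrunken-window fallback would quietly change it. Whether adjacent-but-not-
overlapping windows should merge is a genuine free choice; merging them is
our documented behaviour and the brute-force oracle (enumerate every
window, take the union of qualifying spans) is the defining semantics: a
property test checks the detector against this oracle position-for-position
on hundreds of random sequences whose composition hovers around the
thresholds.

## Architectures and VWD extraction

Domain hits come from hmmscan `--domtblout` tables. The parser takes
coordinates from the **envelope** columns (they bound the full domain
occurrence; alignment columns can clip it) and all coordinates are 1-based
inclusive throughout, the Pfam reporting convention. Hits are filtered at
`i_evalue <= 1e-3` (common Pfam practice; the threshold is configurable
because published analyses rarely state theirs), then resolved greedily in
ascending E-value order (ties: higher score, then smaller start). A hit is
kept iff its overlap extent with every kept hit — measured as
`min(end) − max(start)` — is at most `overlap_tol = 10` residues, so short
flank sharing between adjacent domains survives but genuine double calls do
not. The greedy result is guaranteed conflict-free and deterministic; it is
not guaranteed maximum-cardinality, and the tests assert exactly that
(feasibility plus determinism, checked against enumeration on small cases).

PTS regions are interleaved with resolved hits by start coordinate; a PTS
region overlapping a kept domain by more than the tolerance is truncated to
its largest domain-free sub-interval, since the compositional scan has no
notion of domain boundaries. Rendered strings join elements with `-`;
grouping (`(VWD-C8-TIL)`) and run compression (`3X(...)`) are presentation
only — architecture equality is defined on the flat element sequence.

`extract_vwd()` labels each VWD element D1..Dk by start order from the
N-terminus. The labels are positional, not homology-based: if an N-terminal
VWD is missing from a sequence, its D1 is another protein's D2, which is
exactly the behaviour wanted when the tree is used to diagnose truncated
gene models.

## The VWD phylogeny

The tree stage is deliberately self-contained: distance-based neighbor
joining on the domain alignment rather than a likelihood search. NJ on
Poisson-corrected distances is deterministic, exact on additive matrices
(which gives a closed-form oracle for testing), and adequate for the
question the tree answers here — do VWD domains cluster by family and by
N-terminal position — which is a topology question, not a branch-length
inference. Maximum-likelihood optimisation is out of scope by design.

Distances use pairwise deletion: for each pair, only columns where neither
sequence has a gap are compared, maximising usable signal on short domain
alignments. `p` is the mismatch proportion; the Poisson correction is
`d = −ln(1 − p)`, undefined at `p = 1` — saturated pairs and pairs with no
shared non-gap columns raise errors naming the pair rather than producing
silent infinities. Neighbor joining breaks Q-matrix ties by the lowest
(row, column) index pair, making the topology reproducible; negative branch
lengths, when the data imply them, are retained as computed. The
implementation is checked two ways: path lengths must reproduce additive
input matrices within 1e-9, and topologies must agree (Robinson–Foulds
distance 0) with the independent NJ implementation in `ape`.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per pseudoreplicate (default B = 100), and annotates each internal
bipartition of the full-data tree with the percentage of replicates
containing it. A replicate that produces an undefined distance is skipped
and logged, and percentages use the effective replicate count — silently
treating a failed replicate as "clade absent" would bias supports downward.
Pendant edges carry no support by construction. Rooting is by outgroup
(`root_at()`), with node labels kept attached to their edges.

## The qPCR chain

**Duplicate QC.** The conventional rule — discard a duplicate pair whose
Ct difference is ≥ 0.5 cycles, keep and average tight pairs — is the
default. The rule is sometimes printed in the inverted form ("duplicates
showing a Ct difference < 0.5 were removed"), which taken literally would
discard every good well and keep every bad one; a `literal` mode implements
that reading for comparison, and the default documents our interpretation.
Singleton wells pass with a warning, more than two replicates per well is a
data error.

**Efficiency.** From a dilution series, `Ct = a + b·log10(conc)` by least
squares and `E = 10^(−1/b)`; a perfect assay doubles per cycle, so Ct drops
exactly one cycle per 2× concentration and `E = 2`. At `E = 1.9` the drop
per doubling is `log(2)/log(1.9) = 1.0799` cycles. A non-negative slope is
an estimation error (Ct must fall as template rises), and at least three
points are required.

**Reference stability.** Four measures are computed per candidate gene over
complete samples: geNorm-style M (mean SD of pairwise Ct differences),
BestKeeper SD (raw Ct SD), the comparative ΔCt measure (identical to M
under this pairwise definition — both are reported for the familiar
four-column summary), and a NormFinder-style measure (SD of the doubly
centred residual `Ct_ji − rowmean_i − colmean_j + grandmean`). NormFinder
proper partitions variance by experimental group; the group-free
doubly-centred form is a documented simplification appropriate when the
ranking tool is used without strata. Ranks are aggregated by geometric mean
(lowest = most stable). Adding a constant to all genes of one sample (an
RNA-input shift) leaves M and the comparative measure unchanged — asserted
as a property. With zero variance everywhere all measures are 0 and ranks
fall back to gene order, with a message.

**ΔCt, profiles and effects.** `delta_ct()` subtracts the reference Ct per
sample, dropping (and logging) samples without the reference.
`tissue_profile_matrix()` gives `−mean(ΔCt)` per gene × tissue so that
higher transcription shows as larger values; combinations never measured
are `NA`, not zero — an undetected transcript is absent, not at the
baseline. `log2fc_vs_control()` fits `ΔCt ~ group` per gene and tissue and
tests each group against the control with the pooled residual variance,
two-sided. The displayed effect `−(mean ΔCt_g − mean ΔCt_control)` is a
difference of means, so the control is exactly 0; means rather than medians
are used because the linear model is mean-based. No multiple-testing
correction is applied, deliberately matching the single-contrast-per-panel
convention of stress-response qPCR figures. Degenerate inputs are handled
explicitly: if the residual SD is numerically zero, identical groups get
`p = 1` and an exact nonzero shift gets the smallest representable positive
p; singleton non-control groups report an effect without a p-value.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. Its defaults
encode the study conditions the pipeline targets: a proteome of 40 proteins
with 7 true mucins (Muc5-type `3X(VWD-C8-TIL-VWC)-PTS-(VWD-C8-TIL)`,
Muc2-type, and a short single-cassette variant, cycled); one decoy per
evidence layer — annotated-but-silent, transcribed-without-cassette,
cassette-without-annotation, and a shuffled-order decoy (C8-VWD-TIL) that
has all the parts but the wrong grammar; a 9-tissue FPKM matrix; and qPCR
designs with 12–15 fish per group, technical duplicates, Gaussian noise on
the Ct scale (the standard qPCR error model and the one the linear model
assumes), and amplification factor 2 so that one log2 unit of effect is
exactly one cycle.

Three constructions are deliberate:

* **Planted PTS segments are exact, not stochastic.** One 100-residue unit
  with exact composition counts (`round(100·st_frac)` S/T, `round(100·
  pro_frac)` P) is tiled to the requested length. A sliding 100-window over
  a 100-periodic sequence contains every unit position exactly once, so
  *every* interior window has exactly the planted composition — detector
  recovery assertions are exact rather than probabilistic, a stronger
  guarantee than per-window rejection sampling, and a tandem repeat is
  incidentally what real PTS segments look like.
* **Background is S/T/P-poor** (S+T ≈ 3% expected) so decoys cannot contain
  accidental PTS windows and the funnel's architecture layer is driven only
  by planted structure.
* **Planted VWDs are evolutionarily structured**: a root sequence, one
  ancestor per N-terminal position (substitution rate 0.3 from the root),
  and per-copy tips (rate 0.1). Same-position copies are therefore similar,
  cross-position copies diverged but unsaturated — the tree stage has real
  signal and Poisson distances stay defined under column resampling.

What the generator does **not** emulate: FPKM values are drawn directly
(uniform background below 1, log-uniform signal above) rather than from any
fitted distribution of real RNA-seq — the real distribution is unknown and
the funnel only consumes the threshold crossing; there is no read-level
simulation, no sequencing error, no alignment ambiguity in the VWD
alignment (planted VWDs share one length and stack ungapped), no
amplification-curve or melting-curve structure, and no PCR inhibition.
Passing tests therefore demonstrate correctness of the *computations* under
the stated noise models, not robustness to real-data pathologies such as
fragmented gene models or primer cross-hybridisation.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales their properties
are defined at: 200 random sequences (≤ 1000 aa) for the PTS oracle, 50
seeded proteomes for exact funnel recovery, 100 random additive 4–8 taxon
matrices (tolerance 1e-9) plus a constructed-certainty bootstrap case for
the tree stage, 200 replicates of the five-effect recovery design and
500–1000 null replicates for the test size, and noiseless five-point
dilution series for the efficiency closed form. Equality tolerances are
1e-9 or tighter wherever a closed form exists; stochastic assertions use
wide, pre-stated bands (test size in [0.03, 0.07]).

One power note, stated here because it is a property of the design and not
of the implementation: with biological SD 0.3 and 15 fish per group, the
sampling SD of a difference of group means is `0.3·sqrt(2/15) ≈ 0.11`, so a
±0.2 recovery band captures about 93% of estimates, not 95%; at SD ≤ 0.2
(the generator-level guarantee asserted in the property tests) the same
band captures over 99%.

## Limitations

* Membrane-bound mucins are out of scope; the cassette grammar targets the
  gel-forming families only.
* The funnel cannot rescue genes the annotation mislabels *and* the domain
  scan misses; evidence layers are conjunctive by design.
* NJ supports are not posterior probabilities, and on real, gappy domain
  alignments pairwise deletion can make distances non-additive; the tree is
  a classification aid, not a dated phylogeny.
* The qPCR model assumes per-cycle efficiency independent of concentration
  and Gaussian Ct noise; deviations (inhibition, saturation) are upstream
  of this package, as is instrument-level Ct calling.
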