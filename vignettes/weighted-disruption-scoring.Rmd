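---
title: "Scoring structural variant disruption of 3D genome folding at regulatory interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring structural variant disruption of 3D genome folding at regulatory interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdisrupt)
```

## The problem

Structural variants (SVs) — deletions, duplications, inversions and complex
rearrangements — can reorganize the 3D folding of the genome around them.
When a variant removes or displaces an insulating boundary (typically a
CTCF-bound site), contacts between a gene promoter and its distal
regulatory elements can be lost or newly created, misregulating the gene
without touching any coding sequence. Testing hundreds of variants for this
mechanism experimentally is infeasible, so the strategy implemented here is
*in silico* mutagenesis (ISM): predict the local contact frequency map from
the reference sequence and from the sequence carrying the variant, and
measure how much the two maps differ — overall, and specifically at
regulatory interactions of interest.

`svdisrupt` implements the full scoring framework: window construction and
allele-sequence mutagenesis, map alignment and comparison, region-of-
interest (ROI) weighting driven by promoter-anchored chromatin loops
(CREints), variant–loop pairing with window shifting, a 12-criterion
prioritization engine, cohort statistics, and a tiled 1-bp deletion scan
that maps the sequence determinants of a predicted change.

## The predictor seam and the surrogate

The framework is predictor-agnostic. A predictor is any deterministic
function from a fixed-length nucleotide sequence to a binned, log-scaled,
observed/expected contact map; the geometry defaults follow the published
convolutional predictors of this map type: an input span of
$2^{20} = 1{,}048{,}576$ bp mapped to $448$ bins of $2{,}048$ bp (an output
span of $917{,}504$ bp, i.e. 32 bins cropped from each input side). All
four numbers are configurable through `predictor_geometry()`; the output
identities `448 \times 2048 = 917{,}504` and
`(448 + 64) \times 2048 = 1{,}048{,}576` are enforced, not assumed. Trained
neural networks are deliberately not bundled: `register_predictor()` is the
seam where one plugs in.

So that every stage is exercisable and testable without network weights,
the package ships a deterministic **surrogate predictor**
(`surrogate_motif_predictor()`). It produces

$$\mathrm{value}(i,j) \;=\; -\alpha\,\log(|i-j|+1)\;-\;\sigma\, m(i,j),$$

where $m(i,j)$ counts occurrences of a fixed 19-mer boundary motif (on
either strand) whose midpoint falls strictly between the centers of bins
$i$ and $j$. This is a distance-decay baseline with block insulation at
motif hits — the qualitative anatomy of a real contact map (TAD-like blocks
separated at CTCF-bound boundaries). The frozen parameters are the motif
`CCACCAGGGGGCGCTAGTC`, $\sigma = 0.6$ and $\alpha = 1.0$; freezing them
keeps every derived expectation in the test suite stable. Three properties
make the surrogate a faithful stand-in for scoring purposes: it is exactly
symmetric; it is local (editing sequence away from motif hits changes no
value); and it is reverse-complement equivariant (the map of the
reverse-complemented sequence is the original map flipped on both axes),
which is the property that makes reverse-complement augmentation averaging
meaningful. Because the motif midpoint of a 19-mer never coincides with a
bin-center boundary, the equivariance is exact, with no tie-breaking.

What the surrogate does *not* emulate: learned sequence grammar beyond a
single consensus motif, dosage/orientation effects of CTCF sites, loop
anchors as peaks (only insulation blocks), and cell-type specificity.
Passing tests therefore demonstrate the correctness of the scoring
machinery around the predictor, not predictive accuracy on real genomes.

## Windows, mutagenesis and exclusions

Each variant is scored in a prediction window centered on its midpoint
(`build_prediction_window()`); a signed `shift_bp` can recenter the window,
which is how variant–CREint pairs are centered later. Windows that would
leave the chromosome are clamped inside it and flagged; flagged windows are
scored unaugmented rather than silently biased.

All SV types reduce to a span substitution on the reference window
(`construct_allele_sequences()`): deletions substitute the empty string,
duplications substitute two copies of the span (an extra copy inserted
immediately 5′ of the original), inversions the reverse complement, complex
variants a user-supplied alternate sequence. Length changes are compensated
at the window edges so both alleles are exactly the input span long: for a
net deletion the flanks are extended into the chromosome, for a net
insertion they are trimmed. The compensation is split evenly between the
two flanks — the even split keeps the variant midpoint centered; when an
even split does not fit (a net insertion close to a window edge), the
remainder moves to the other flank. Augmentation
(`make_augmentations()`) scores four sequence pairs — identity, ±1 bp
window shifts, reverse complement — and averages the four scores.

Variants are filtered before scoring (`apply_exclusion_filters()`), each
exclusion carrying exactly one code, assigned in a fixed order so the
ledger is deterministic: `UNKNOWN_ALT` (SV classes whose alternate sequence
is unknown — insertion classes and translocations), `TOO_LONG_ABS`
(> 700 kb), `TOO_LONG_REL` (> 2/3 of the input span, or otherwise unable to
fit), `OFF_CONTIG`, `N_CONTENT` (> 5% unknown sequence in the reference
window). There is no lower length bound by default (`min_len = 1`),
configurable because published callsets differ in their minimum SV size.

## Map alignment and disruption scores

After mutagenesis the two maps cover slightly different material wherever
the variant changed sequence length. `align_allele_maps()` restores
bin-for-bin comparability: bins left of the changed region shift by the
left-flank compensation (in bins), bins right of it by the right-flank
compensation, and bins straddling the change have no comparable partner.
For bin-aligned variants this is exactly the classical
"insert $\lceil |\Delta L| / \mathrm{bin} \rceil$ masked rows/columns at
the variant, trim both ends evenly" construction; for sub-bin variants it
is bp-accurate, which matters for the 1-bp deletion scan (a 1-bp deletion
must align as the identity, not as a whole-bin shift). All bins overlapping
the variant, plus one **guard bin** on each side, are masked in both maps:
a bin partially overlapping the SV is not comparable between alleles. Two
near-diagonal bands are excluded from all comparisons
(`diagonal_offset = 2`), matching the undefined diagonals of the maps this
framework targets.

Scores, all computed over comparable (jointly unmasked, off-diagonal,
finite) entries:

* **global** (`score_global()`): $1 - \rho$ with $\rho$ the Spearman
  correlation of the paired upper-triangle entries (average ranks for
  ties), in $[0, 2]$; and the mean squared error. A constant map makes the
  correlation undefined and is reported as missing with a reason, never as
  a number.
* **disruption track** (`disruption_track()`): one value per bin, comparing
  the bin's map column between alleles (448 values at default geometry).
  The default per-column metric is MSE — a rank correlation on a
  near-constant column is unstable — with `spearman` available.
* **weighted** (`build_weight_track()`, `weighted_score()`): bins
  overlapping any ROI by ≥ 1 bp get weight $s$ (default 10), others 1. The
  weighted score is the weight-normalized mean
  $\sum d_i w_i / \sum w_i$: normalization makes it collapse exactly to
  the unweighted mean when disruption is uniform or when weights are
  uniform, which is the behavior the weighting scheme is specified to
  have; the unnormalized form $\mathrm{mean}(d \cdot w)$ is available
  behind `normalize = FALSE`. `roi_only` is the plain mean over ROI bins.

## CREints: loops to regions of interest

Raw loops (e.g. PLAC-Seq paired peaks) become CREints in three steps
(`loops_to_creints()`): drop inter-chromosomal pairs and pairs whose
anchors are ≥ 900 kb apart (they cannot fit one output window; distance is
measured inner edge to inner edge); merge redundant loops — among loops
sharing a left anchor, right anchors within 10 kb are replaced by their
union, then symmetrically for left anchors, repeated to a fixed point so
merging is idempotent ("sharing" an anchor means overlapping or within the
10 kb radius, since real anchors rarely coincide exactly); and keep only
loops with an anchor at the promoter — the strand-aware 2 kb immediately
upstream of the TSS — of a gene with TPM > 0. The separate `genes` ROI mode
instead uses a 2 kb window *centered* on every TSS. Loops destined for
plotting can skip the promoter filter (`skip_promoter_filter`).

`pair_variant_creints()` pairs a variant with every CREint such that the
union span of variant and both anchors is under 900 kb and the variant
overlaps neither anchor; the recorded shift centers the union span in the
prediction window (within half a bin). Pair scoring up-weights all CREint
anchors in the window by default; `paired_only` restricts weighting to the
paired CREint. Per-variant summaries take the maximum across pairs.
Complex variants are excluded from the CREint-weighted stage by flag.

## Prioritization

`evaluate_criteria()` renders 7 required and 5 optional criteria per
variant, each with evidence text; missing inputs mark a criterion
unevaluable (`NA`), never passed. Numeric thresholds are percentile-based
(type-7 linear interpolation): prediction-vs-experiment MSE below the 85th
percentile, disruption scores above the 65th. Choices the criteria text
left open, decided here: the "standard scores" against which the CREint
score is compared are the global $1-\rho$ scores of the variant-centered
stage; the percentiles are computed across all scored variants of both
cohorts; and the CTCF criterion is read as "the variant clips but does not
swallow any touched CTCF peak" (every touched peak covered over less than
half its length). Enrichment of variants near CREints uses 1 Mb genome
bins, a 2×2 Pearson chi-squared with one degree of freedom and no
continuity correction (the closed-form statistic is cross-checked against
`chisq.test` in the tests). Cohort comparisons are two-sided Mann–Whitney
tests within pooled length quantiles (two-sided because the direction is
the hypothesis under test, not an assumption), with exact p-values for
small untied samples and the tie-corrected normal approximation otherwise.
The final qualitative selection step (visual inspection of candidate maps)
is out of scope; the engine emits ranked candidates.

## Synthetic study conditions

The fixture generator (`fixture_spec()`, `simulate_fixture()`) emulates the
statistical structure every stage assumes, at a scale a single CPU handles
in minutes: 2 chromosomes × 4 Mb with 8 planted boundary motifs each
(spaced on a jittered grid, random strands); 40 variants per cohort with a
DEL 0.5 / DUP 0.2 / INV 0.2 / CPX 0.1 type mix and log-uniform lengths
between 50 bp and 100 kb (spanning sub-bin to multi-bin effects); probands
place 80% of their variants on a motif while siblings are uniform — the
planted signal that makes the proband cohort genuinely more disruptive;
12 loops per chromosome with motif-adjacent right anchors and 80% of left
anchors at gene promoters; 30 genes per chromosome with log-normal TPM and
20% zeros. An `exclusion_showcase` preset plants a 100 kb N-run and one
variant per exclusion code. All generation is deterministic per seed.

These conditions are a caricature of a real cohort: real dnSV length
spectra are heavier-tailed, real loops do not all snap to boundaries, and
real disruption signal is far weaker than an 80% motif-targeting rate. The
end-to-end test (proband vs sibling rank-sum p < 0.05 at 40 + 40 variants)
therefore validates the pipeline's ability to transmit a planted signal
into a cohort-level statistic — not effect sizes on real data.

## Numerical choices and limitations

* Percentiles and quantile cutoffs: type-7 (linear interpolation)
  throughout.
* Spearman ties: average ranks; masked/missing entries excluded pairwise.
* The tiled 1-bp deletion scan is unaugmented (augmentation is orthogonal
  and quadruples cost) and capped by a configurable region length.
* Off-motif positions in a scan can score slightly above zero when the
  1 bp shift moves a downstream motif across a bin-center boundary; the
  motif-destroying positions dominate regardless, and a window containing
  no motif scores numerically zero.
* Problem sizes used by the shipped checks: unit tests run a 12 × 64 bp
  toy geometry; the end-to-end suites and the acceptance script run the
  default 448 × 2,048 bp geometry on the 8 Mb fixture genome, with
  enrichment binned at 100 kb (80 bins) since 1 Mb bins would tile the toy
  genome into only 8.
* Experimental contact matrices are accepted as pre-binned, pre-balanced,
  log-scaled text; no matrix balancing is performed here.
* Breakends, multi-allelic records and phased alleles are out of scope; so
  is loop calling from raw reads.
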