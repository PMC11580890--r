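# svdisrupt

Scoring structural variants for predicted disruption of local 3D genome
folding — globally, and specifically at regulatory interactions.

## What it is for

Structural variants (SVs) can rewire gene regulation without touching a
coding base: deleting an insulating CTCF boundary can fuse two contact
domains and expose a gene to a foreign enhancer. `svdisrupt` ranks SV
callsets (e.g. de novo SVs from affected probands and their unaffected
siblings) by how much each variant is predicted to change chromatin
contacts in its ~1 Mb neighborhood, and focuses that signal on putative
cis-regulatory element interactions (CREints) — promoter-anchored chromatin
loops derived from PLAC-Seq data.

The engine is *in silico* mutagenesis against a sequence-to-contact-map
predictor. For each variant it builds the surrounding prediction window,
constructs reference and alternate allele sequences (deletions,
duplications, inversions, complex variants), predicts both contact maps,
pads/masks the maps so every bin compares like sequence with like, and
scores the difference:

- **global disruption**: `1 − ρ` (Spearman) and MSE over comparable map
  entries;
- **disruption track**: one score per 2,048 bp bin (448 bins at default
  geometry);
- **weighted score**: the track averaged with weight *s* (default 10) on
  bins overlapping regions of interest, `Σ d·w / Σ w`, plus an ROI-only
  mean.

Around that core: PLAC-Seq loop processing (900 kb span filter, 10 kb
redundancy merging to a fixed point, expressed-promoter filter),
variant–CREint pairing with window-centering shifts and max-across-pairs
summaries, a 7-required + 5-optional criteria prioritization engine, 1 Mb
genome-bin enrichment (chi-squared), cohort rank tests within length
quantiles, and a tiled 1-bp deletion scan that localizes the sequence
driving a predicted change (it recovers disrupted CTCF motifs).

No trained network is bundled. The predictor is a registry seam
(`register_predictor()`); the package ships a deterministic, motif-based
**surrogate** predictor (distance decay + block insulation at a planted
19-mer, exactly reverse-complement equivariant) so the entire pipeline
runs, and is tested, without weights or downloads. A synthetic fixture
generator produces genomes, cohorts, loops, peaks and expression tables
with the statistical structure the method assumes.

## Worked example

```r
library(svdisrupt)

dir <- file.path(tempdir(), "toy")
simulate_fixture(fixture_spec(seed = 1), dir)     # 8 Mb toy genome + cohort

genome <- read_genome(file.path(dir, "genome.fa"))
sv     <- read_sv_records(file.path(dir, "variants.tsv"))
motifs <- rtracklayer::import(file.path(dir, "motifs.bed"), format = "BED")
rois   <- GenomicRanges::resize(motifs, 2000, fix = "center")

score_variant(sv[1], genome, rois = rois, scale = 10, augment = TRUE)
```

```
 variant_id spearman_score mse_score unweighted weighted roi_only  augmentation
    pro_001         0.0429     0.354      0.354    0.351    0.282 averaged-of-4
 n_augment window_clamped
         4          FALSE
```

`pro_001` is an 87 kb proband deletion that removes a planted boundary
motif. `spearman_score` (0.043) is the global `1 − ρ` disruption, averaged
over the four augmentation sequences (identity, ±1 bp shifts, reverse
complement); `unweighted` is the mean of the 448-bin disruption track;
`weighted` re-averages it with 10× weight on bins overlapping the supplied
ROIs; `roi_only` is the mean over ROI bins alone. A background variant that
hits no boundary scores near zero (~0.006 on this fixture).

End-to-end runs go through a config:

```r
cfg <- run_config(genome = file.path(dir, "genome.fa"),
                  variants = file.path(dir, "variants.tsv"),
                  loops = file.path(dir, "loops.bedpe"),
                  genes = file.path(dir, "genes.bed"),
                  expression = file.path(dir, "expression.tsv"),
                  asd_gene_exons = file.path(dir, "asd_gene_exons.bed"),
                  asd_genes = file.path(dir, "asd_genes.bed"),
                  ctcf_peaks = file.path(dir, "ctcf_peaks.bed"),
                  outdir = "run1")
run_pipeline(cfg, stages = c("score", "pair", "prioritize", "enrich", "cohort"))
```

which writes `scores.tsv`, `exclusions.tsv`, `creints.bedpe`, `pairs.tsv`,
`pair_summary.tsv`, `report.tsv` (12 criteria columns + ranks),
`enrichment.tsv`, `cohort_tests.tsv` and a count-reconciled `run.log`. A
thin CLI wrapper with subcommands (`simulate`, `score`, `pair-creints`,
`prioritize`, `enrich`, `cohort-stats`, `scan-tiles`) lives at
`inst/cli/svdisrupt.R`.

See `vignettes/weighted-disruption-scoring.Rmd` for the model, the
surrogate predictor, all tunable parameters and the design decisions.

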