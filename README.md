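# serotile

Linear epitope mapping from tiled peptide-microarray serology.

## What this is for

High-content peptide microarrays can display **every possible linear
16-mer** of a whole family of homologous allergens — the motivating case is
the fish β-parvalbumin family (~20 isoforms and isoallergens of ~109
residues, >1000 unique peptides after deduplication) probed with
longitudinal serum samples (IgG / IgG4 / IgE, up to four timepoints over
several years). serotile turns the raw per-sample peptide intensities into
epitope biology:

* **Tiling & indexing** — exhaustive overlapping k-mer tiling of a panel
  FASTA (offset-1 16-mers: a length-L sequence gives L − 15 peptides
  sharing 15 residues with their neighbours) and a unique-peptide index
  that collapses identical 16-mers across isoforms.
* **Coordinates** — mapping between allergen-local residues and the column
  numbering of a fixed master alignment, plus per-column diversity
  profiling (consensus residue frequency < 50% ⇒ diverse).
* **Antigenicity** — the Kolaskar–Tongaonkar sliding-window propensity
  method with IEDB-style mean-threshold segment calling.
* **Reactive calling with artifact control** — per-sample robust scores
  `z = (log2 I − median) / (1.4826 · MAD)`; a call is *confirmed* only with
  independent support (same peptide at ≥2 timepoints, an overlapping
  reactive tile, or a homologous reactive tile at the same aligned start on
  another isoform). Lone bright spots are flagged artifact candidates.
* **Epitope deconvolution** — maximal runs of reactive tile starts give the
  epitope *span* (union of coverage) and the *minimal epitope*
  (intersection: `[last, first + 15]`, length `16 − (n − 1)` for a run of
  n tiles); residue-level attribution of binding differences across
  isoforms; isoallergen-differential recognition; unique-k-mer carrier
  queries.
* **Longitudinal analysis** — within- vs between-subject profile
  stability, and detection of *induced* reactivities (baseline z below 1 at
  all earlier timepoints, later z ≥ 3 with ≥ 2 log2-units increase).
* **Profile similarity** — PCA (centred SVD, deterministic signs) of
  sample and allergen profiles, and sample-only hierarchical clustering
  with columns kept in tiling order (pheatmap conventions).
* **Synthetic serology** — a fully seeded generator (homologous family
  with planted polymorphic key columns, per-subject stable repertoires,
  induction events, key-residue-dependent cross-reactivity, log-normal
  array noise) with ground-truth recovery metrics, so the whole chain is
  testable without clinical data.

## Worked example

```r
library(serotile)

cohort <- simulate_cohort(seed = 1)   # 19 allergens x 109 aa, 15 subjects,
                                      # 4 timepoints, IgG + IgG4
cohort
#> synthetic_cohort: 15 subjects x 4 timepoints x 2 isotypes, 1240 peptides, noise_sd 0.50

res <- run_recovery(cohort)           # z-scores -> calls -> segments ->
                                      # induction -> truth comparison
res$metrics
#> recovery_metrics (IgG layer)
#>   confirmed-call precision: 1.000  recall: 0.879
#>   epitope-window recall:    1.000  mean Jaccard: 1.000
#>   key-residue accuracy:     1.000
#>   induction recall:         1.000  timepoint accuracy: 1.000  false events: 0

head(res$segments[, .(sample_id, allergen_id, first_start, last_start,
                      minimal_epitope)], 3)
#>    sample_id  allergen_id first_start last_start minimal_epitope
#> 1: S01|1|IgG Syn p 1.0101          15         22       LNRAYDGLL
#> 2: S01|1|IgG Syn p 1.0101          77         84       CLAMRLSNH
#> 3: S01|1|IgG Syn p 1.0201          15         22       LNRAYDGLL

stability_correlation(res$rmat, "IgG")
#> stability_summary: mean r within-subject 0.770 (n=90), between 0.086 (n=1680)
```

Reading the output: each planted 9-residue epitope elevates exactly the
eight 16-mers containing it, so the run of reactive starts 15–22 narrows to
the 9-mer `LNRAYDGLL` — the minimal epitope — recovered identically on both
isoforms that carry it. The recovery metrics compare every pipeline layer
with the generator's planted truth; the within-subject correlation of 0.77
against 0.09 between subjects is the stable-repertoire signature that makes
consecutive samples of one subject co-cluster.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/serotile-cli.R`
(`simulate | tile | call | epitopes | longitudinal | profiles`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the default synthetic cohort
for the given seed — cohort simulation, tiling and indexing, robust
calling with confirmation, epitope segment deconvolution, induction
detection and recovery scoring — printing the metrics and writing the JSON
report to `--out`.

## Layout

```
R/                  panel, alignment, antigenicity, reactivity, epitope,
                    longitudinal, profiles, synthetic, recovery
inst/extdata/       synthetic stand-in fixture panel (design metadata of the
                    21-isoform array; sequences are synthetic)
inst/scripts/       command-line wrapper
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, design choices)
scripts/            acceptance.R
```
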