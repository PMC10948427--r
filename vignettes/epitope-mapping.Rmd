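---
title: "Mapping linear epitopes from tiled peptide-microarray serology"
author: "serotile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping linear epitopes from tiled peptide-microarray serology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serotile)
library(data.table)
```

## The problem

High-content peptide microarrays can carry every possible linear k-mer of a
whole family of homologous proteins. For a food-allergen family such as the
fish beta-parvalbumins (roughly 20 isoforms and isoallergens of ~109
residues each, tiled as overlapping 16-mers at offset 1), probing such an
array with longitudinal serum samples yields, per sample, a reactivity
profile over more than a thousand unique peptides. Turning those profiles
into biology requires a chain of small, well-defined inferences:

1. which peptides are *reactive*, and which apparent signals are spot-level
   artifacts;
2. which runs of overlapping reactive peptides form one *epitope*, and what
   its *minimal* sequence is;
3. which residue differences between isoforms explain differential binding;
4. which reactivities are stable in a subject over years and which are
   *induced* at a later timepoint;
5. how similar reactivity profiles are across samples and across allergens.

serotile implements this chain as composable functions plus a seeded
synthetic-data generator, so that every stage is testable against a known
ground truth without access to clinical array data.

## Tiling and coordinates

A panel is a set of isoform records (`allergen_panel()`); records flagged
incomplete in the source database are kept for bookkeeping but never tiled,
because a tile across undefined residues would be meaningless. Tiling
(`tile_panel()`) enumerates every k-mer (default k = 16, offset 1), so a
sequence of length L yields L − 15 peptides and adjacent peptides share 15
residues. Identical 16-mers from different isoforms are one physical
peptide on the array; `build_peptide_index()` collapses them into unique
sequences with occurrence lists, conserving the total tile count.

Whether a record's stored sequence carries the N-terminal methionine is
treated as metadata (`includes_initial_met`), never as string surgery: the
stored sequence is exactly what gets tiled.

Positions are reported in two systems: allergen-local 1-based residues, and
columns of a *master alignment* supplied as gapped FASTA
(`read_alignment()`, `local_to_aligned()`). The alignment is an input, not
computed, because cross-isoform numbering must match one fixed published
alignment; `check_alignment()` verifies that ungapping each row reproduces
the panel sequence. Per-column diversity (`column_diversity_profile()`)
flags columns whose consensus residue falls strictly below a threshold
(default 50%) of non-gap entries, ties broken alphabetically.

## Antigenicity prediction

`antigenic_propensity()` reimplements the Kolaskar–Tongaonkar method: each
residue receives the mean of a published per-residue propensity scale over
a centred window (default 7). The flanking (window−1)/2 residues carry no
value. `predict_antigenic_segments()` reports maximal runs strictly above a
threshold that defaults to the protein's own mean propensity — the
behaviour of the IEDB web tool — keeping runs of at least `min_length`
residues (default 6). Window, threshold and minimum length are exposed
because published analyses rarely state them.

## Reactive-peptide calling

Microarray scanners report raw fluorescence; no absolute threshold
transfers between instruments or serum dilutions. serotile therefore scores each sample on its
own robust scale (`robust_z()`):

$$z = \frac{\log_2 I - \mathrm{median}}{1.4826\,\cdot\,\mathrm{MAD}}$$

computed within each (subject, timepoint, isotype) sample. This is
invariant to scanner gain and overall serum brightness. Intensities at or
below zero are floored to 1 fluorescence unit before the log transform
(negative values are rejected as corrupt input). A peptide is reactive at
`z_cut` (default 3).

A single bright spot is not evidence of binding. A reactive call is
**confirmed** only with at least one independent line of support, mirroring
how serologists distinguish binding from local artifacts:

* the same peptide is reactive at ≥ 2 timepoints of the subject
  (`consecutive_sample`; strict adjacency is a config flag, off by default
  because sampling gaps are common);
* another reactive peptide of the same sample overlaps it by at least
  `overlap_min` residues (default 8, half a tile) on the same allergen
  (`overlapping_peptide`);
* a different reactive peptide starts at the same alignment column on
  another isoform in the same sample (`homologous_peptide`).

Everything reactive-but-unconfirmed is flagged an `artifact_candidate` —
the "singular high signal in one peptide of one sample" situation.

## Epitope deconvolution

Confirmed calls are grouped per sample and allergen and split into maximal
runs of consecutive tile starts (`call_segments()`; a config option absorbs
single failed spots). Each run yields:

* the **span** — the union of tile coverage, `[first, last + k − 1]`;
* the **minimal epitope** — the intersection of tile coverage,
  `[last, first + k − 1]`, of length `k − (n_starts − 1)` for a contiguous
  run.

The intersection convention is the standard tiling-deconvolution reading of
"minimal": the residues every reactive peptide shares. A run of one tile
returns the full 16-mer (some epitopes genuinely need the whole peptide); a
run of k tiles narrows to a single residue.

`group_homologs()` collects, at one aligned start, each isoform's tile,
collapsing isoforms with identical peptides into one representative.
`residue_association()` then scans every alignment column in the tile
window and scores candidate key residues as the difference of class means
of the signal (classes must each hold at least `min_class = 2` member
allergens). With at most ~20 isoforms per class a formal test would be
theatre; the function reports a ranking with a flagging threshold
(`effect_cut`, default 2 log2 units — a four-fold intensity difference).
Means are taken over representatives (each physical peptide measured once)
while class sizes count member allergens.

`isoallergen_contrasts()` reports aligned positions where exactly one
member of an isoform pair is reactive in a sample, and
`unique_kmer_index()` answers "is this minimal epitope uniquely carried by
one isoform?" by brute-force k-mer indexing of the panel.

## Longitudinal analysis

`stability_correlation()` computes Pearson correlations of log2 profiles
over jointly observed peptides for all sample pairs of one isotype and
splits them into within- and between-subject groups; stable individual
repertoires show a clear within > between gap.

`detect_induced()` looks for *inductions*: trajectories whose earlier
observed timepoints all sit below `z_low` (default 1) and that reach
`z_cut` later with a log2 increase of at least `fold_min` (default 2) over
the baseline mean. A rise from an already-elevated baseline is an increase,
not an induction, and is deliberately excluded. Missing timepoints are
simply not evaluated — several subjects lack intermediate samples and
imputation would manufacture evidence. Qualifying peptides are merged into
aligned-start windows per subject, isotype and allergen; when calls are
supplied, only confirmed peptides contribute and events carry the union of
their support tags. The quantification of "novel or greatly increased" as
(`z_low`, `z_cut`, `fold_min`) is this package's choice; no numeric
criterion exists in the motivating literature, so all three are config.

## Profile similarity

`sample_profile_matrix()` arranges samples × unique peptides (log2).
`allergen_profile_matrix()` compares allergens over features =
(sample, aligned start) within a configurable start range (default columns
9–95, the region where most isoforms are alignable without terminal gaps);
features with any missing value — an isoform with a gap at that start — are
dropped so that all allergens are compared on identical features. That
drop-columns rule is the simplest defensible treatment; how the original
interactive tools handled gap positions is not documented.

`profile_pca()` is a plain column-centred SVD with explained-variance
fractions from squared singular values and a fixed sign convention (the
largest-magnitude loading of each component is positive) so results are
bit-deterministic. `cluster_order()` clusters samples only — columns stay
in linear tiling order so per-position structure remains readable — with
Euclidean distance and complete linkage, the pheatmap defaults.

## The synthetic world

`generate_panel()` builds a gap-free family: a random base sequence of 109
residues mutated independently per isoform at a per-site rate (default
0.05, which reproduces the observed regime where a 19-member family of
109-mers collapses from 1786 tiles to ~1200–1300 unique peptides — close to
the ~1400 of the real panel). On top of the random substitutions it plants
a small number of **key columns**: two-residue polymorphisms splitting the
family into classes of ≥ 3 isoforms, spaced ≥ 16 columns apart so any tile
window contains at most one. These emulate the surface polymorphisms that
drive isoform-dependent epitope recognition.

`simulate_subjects()` draws per-subject repertoires (default 15 subjects ×
3 epitopes of width 9, window starts ≥ 17 columns apart so reactive runs
stay distinct). A fraction of epitopes (default 1/3) is key-residue
dependent: only isoforms carrying the base residue react. A fraction
(default 0.2) is induced at a random timepoint ≥ 2. Affinities are
log-additive in log2 units (default 3, i.e. eight-fold over baseline —
a clearly-reactive spot, not a borderline one); IgG carries the full
affinity while IgG4 carries half of it for a quarter of epitopes, emulating
the observation that most reactivity is IgG with a small IgG4 component.

`simulate_intensities()` realises
`log2 I = baseline + effect + N(0, noise_sd)` with `noise_sd = 0.5`
(multiplicative log-normal array noise; about ±40% intensity scatter) and
`baseline = 10` (~1000 fluorescence units). Output is byte-reproducible
under a fixed seed.

What the generator does **not** emulate: spatial spot artifacts, print
batches, saturation, missing timepoints (available as a parameter, off by
default), indels in the family (gap-free by default so local and aligned
coordinates coincide — the mapping API is still exercised, the degenerate
way), and cross-reactivity that decays smoothly with sequence distance
(effects are all-or-none per window). A green recovery test therefore
establishes that the inference chain is correct under the stated noise
model, not that it is robust to every array pathology.

## Recovery metrics and what the tests establish

`run_recovery()` executes the standard pipeline on a synthetic cohort and
`evaluate_recovery()` scores it on the IgG layer: confirmed-call
precision/recall against planted effect cells; epitope-window recall
(interval Jaccard of minimal spans with planted windows, threshold 0.5);
key-residue accuracy (the planted column must rank first and be flagged);
induction recall, first-timepoint accuracy and cohort-wide false events
(clusters of detected events matching no planted induced window).

At the default stated world, the pipeline achieves precision ≈ 1, window
recall ≈ 1, key-residue accuracy ≈ 1 and induction recall ≈ 1 with 0 false
events; confirmed-call recall sits around 0.88–0.9 because the robust MAD
is mildly inflated by the true signal mass (~20% of peptides per sample),
which pushes borderline cells just under the z cut-off. That is a real
property of median/MAD normalisation under signal contamination, not a
bug, and the suite asserts recall ≥ 0.8 accordingly.

## Numerical and design choices

* **Thresholds** (`z_cut = 3`, `z_low = 1`, `fold_min = 2`,
  `overlap_min = 8`, `effect_cut = 2`) are all exposed; none is stated in
  the motivating literature, so defaults were chosen once for scanner-gain
  invariance and four-fold interpretability and are not tuned per dataset.
* **Ties** — consensus residues alphabetical; PCA signs by
  largest-magnitude loading; hclust leaf order as returned by
  `stats::hclust`.
* **Degenerate inputs** — zero MAD is an error advising a floor rather
  than a silent division by zero; constant matrices are a PCA error;
  non-contiguous start sets whose tiles share no residue are a
  minimal-epitope error (the caller must split runs).
* **"Multiple consecutive samples"** is operationalised as ≥ 2 timepoints,
  not necessarily adjacent, with a strict-adjacency flag; the loose
  reading matches cohorts with missing intermediate samples.
* The printed-design fixture under `inst/extdata/` transcribes the public
  design metadata (21 isoform names, two incomplete, initial-Met flags) but
  carries **synthetic stand-in sequences** (marked in the filename), since
  the real sequences are not redistributed here; two printed minimal
  epitope peptides are embedded verbatim so coordinate and uniqueness
  queries are exercised against known strings.

## Worked example

```{r example}
cohort <- simulate_cohort(seed = 1)
cohort

res <- run_recovery(cohort)
res$metrics

## one recovered epitope segment with its minimal epitope
head(res$segments[, .(sample_id, allergen_id, first_start, last_start,
                      minimal_epitope)], 3)

## induced reactivities of one subject
head(res$induced[, .(subject_id, allergen_id, window_start, window_end,
                     first_induced_tp, log2_fold)], 3)
```

## Known limitations

* Linear epitopes only: conformational epitopes are invisible to tiled
  peptides, and no claim is made about them.
* Confirmation by homology assumes a trustworthy master alignment; a
  misaligned column silently weakens `homologous_peptide` support.
* `residue_association()` is a ranking over tiny classes; treat flagged
  columns as hypotheses for structural follow-up, not significance calls.
* With `max_gap > 0`, very long gapped runs can have an empty tile
  intersection; the minimal epitope is then reported as `NA` rather than
  invented.
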