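---
title: "Methods: DIA spectrum reconstruction, metabolite-family classification, and chemodiversity statistics"
author: "specfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIA spectrum reconstruction, metabolite-family classification, and chemodiversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfam)
```

## The problem

In data-independent acquisition (DIA/SWATH) mass spectrometry every
precursor ion inside a stepped isolation window is co-fragmented in every
cycle. The resulting MS2 spectra are multiplexed: fragment ions are
recorded per window, not per precursor, so the precursor–fragment links
that a classical DDA experiment gives for free must be reconstructed
computationally. Once precursor-resolved MS/MS spectra exist, they can be
classified into *metabolite families* — compound classes in the sense of a
chemical ontology (superclass → class → subclass) — without identifying
individual compounds, and the per-sample class composition supports
ecological-style diversity and chemotaxonomic analyses, e.g. comparing
fresh plant material against long-term dried herbarium specimens across
many species.

`specfam` implements this chain as a tested R library plus a thin CLI:

1. **Reconstruction** — correlation-based assignment of MS2 chromatographic
   peaks to MS1 precursors (`reconstruct_spectra`).
2. **Classification** — a classifier trained from annotated fragment
   spectra via neutral-loss decomposition, fragment-matrix clustering and
   per-family consensus spectra (`train_family_classifier`, `predict`).
3. **Statistics** — Shannon/Pielou diversity, Fisher composition tests,
   relative-frequency shifts, ontology roll-ups, and dendrogram-vs-phylogeny
   comparison (Mantel, cophenetic, Robinson–Foulds, Procrustes).
4. **Simulators** — seeded generators for every input class, so the whole
   pipeline is testable without instrument data.

## DIA reconstruction

Chromatographic peaks are detected per trace by a deliberately simple
detector (`detect_peaks`): local maxima qualify when the apex exceeds
`snthresh` (default 5) times the noise level — the median absolute
deviation of the off-peak trace — and the peak base width lies within
`peakwidth` (default 10–20 s). A half-max-width floor rejects single-point
noise spikes whose base bounds wander wide by chance. This detector is not
a continuous-wavelet (centWave-style) implementation and is intended for
reconstructed or simulated traces; full-resolution raw-data peak picking
should be delegated to a dedicated MS package.

For each MS1 peak, candidate fragments are the MS2 peaks of the isolation
window covering the precursor m/z whose retention-time bounds overlap the
precursor's. A fragment is retained iff the Pearson correlation between
its trace and the precursor trace is at least `min_cor` (default 0.5).
The correlation is evaluated on the intersection of the two peaks' RT
supports, with the fragment trace linearly interpolated onto the MS1 grid;
fewer than three shared grid points skip the fragment. Because the
criterion is a hard threshold, the retained set is monotone in `min_cor`,
and every retained fragment's correlation is stored on the spectrum for
post-hoc auditing.

Downstream filters follow the published workflow's defaults, collected in
`pipeline_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `min_cor` | 0.5 | – | fragment–precursor trace correlation floor |
| `rt_window` | 60–1200 | s | precursor RT retention (inclusive); trims salt-dominated early and lipid-dominated late RT |
| `merge_mzd`, `merge_ppm` | 0.05, 50 | Da, ppm | peak unification when merging overlapping spectra (intensity = max) |
| `msms_intensity_threshold` | 10 | counts | absolute MS2 peak floor |
| `min_intensity_of_max_ms2_peak` | 1e-4 | relative | spectrum rejection vs the run's strongest MS2 signal |
| `min_proportion_ms2_peaks` | 0.05 | relative | spectrum rejection when too few peaks survive the floor |
| `grouping_mz_abs`, `grouping_ppm` | 0.01, 20 | Da, ppm | fragment-matrix binning |
| `deisotope_mz_abs`, `deisotope_ppm` | 0.01, 10 | Da, ppm | C13 isotopologue matching |
| `max_rt_difference` | 0.02 | min | spectrum→feature mapping and precursor deisotoping co-elution window |
| `presence_threshold` | 0.001 | relative | presence call vs the sample's largest peak |

Numerical conventions worth stating explicitly:

* All retention times are seconds internally; `max_rt_difference` is
  expressed in minutes (the convention of the tool family this workflow
  descends from) and converted on use. Readers convert minute-valued RT
  fields on ingest.
* The RT window is inclusive at both bounds, chosen for determinism where
  prose like "between 60 and 1200 s" is ambiguous.
* The relative spectrum-rejection threshold is interpreted against the
  largest MS2 intensity of the run, the most conservative available
  referent.
* C13 deisotoping removes peaks +1.003355 or +2.006710 Da above a stronger
  peak; the isotopologue must be strictly weaker than its parent. Spectrum
  rejection (`NULL`) is distinct from the error raised on empty input.
* Peak merging is single-linkage in m/z, so it is idempotent: after one
  pass, adjacent bin centers are provably farther apart than the
  tolerance.

## The metabolite-family classifier

**Decomposition.** Each cleaned spectrum yields one *fragment* feature per
peak and one *neutral loss* (precursor m/z − fragment m/z, when positive)
per peak; fragment-to-fragment losses are off by default
(`include_fragment_pairs`). Losses are the substructure-indicative signal:
two glycosides with different aglycones share the 162.05 Da hexose loss,
not the fragment m/z.

**Fragment matrix.** Features are binned by single linkage within
`max(0.01 Da, 20 ppm)`, fragments and losses separately. Entries are peak
intensities normalised to the spectrum base peak, so every row has maximum
1 and the matrix is scale-free; bin centers are intensity-weighted means.

**Clustering and family selection.** Spectra are clustered by
average-linkage agglomeration on the Jaccard distance between binary
feature profiles — the natural choice for presence/absence substructure
sharing (identical spectra merge at 0, disjoint ones at 1). A subtree of
this clustering becomes a metabolite family when

1. it contains at least 10 fragment spectra,
2. at least one feature is present in ≥ 75 % of its member spectra,
3. it covers at least 5 distinct compounds, and
4. its parent subtree fails criterion 2,

so the most inclusive subtree that still shares a conserved feature wins.
A candidate must also carry a majority ontology term (> 50 % of member
spectra); ties resolve toward the shallower ontology term, then
lexicographically. When several accepted subtrees map to one term, the
largest is kept.

**Consensus and scoring.** The family consensus records, for every feature
bin present in at least two members, the occurrence frequency $w_f$ and
the median relative intensity (median, not mean, for robustness to single
outlier intensities); bins with $w_f < 0.1$ are dropped. The score of a
query spectrum against a family is the frequency-weighted fraction of
matched consensus features,

$$\mathrm{score}(s, F) \;=\; \frac{\sum_{f \in C_F \,\cap\, s} w_f}{\sum_{f \in C_F} w_f} \in [0, 1],$$

which is deterministic, monotone in the matched set, and invariant to
peak order and uniform intensity scaling. The family literature delegates
its exact score to internal references; this concrete form was chosen so
every property is testable.

**Background distributions and p-values.** Each family stores background
scores: the scores of all non-member training spectra, supplemented up to
at least `bg_size` (default 100) samples with *feature-permuted* spectra —
a random training spectrum's feature count re-drawn uniformly from the
global bin dictionary. The p-value of an observed score is its
conservative rank, $(1 + \#\{b \ge s\}) / (1 + \#b)$. Families with
$p \le 0.05$ enter the candidate list, ranked by score with ties broken by
term id; the top candidate is the primary compound class, the remainder
alternative parents; an empty list leaves the spectrum unclassified.

Because the background scores are atomic (few distinct values), the
conservative p-values are *valid* — $P(p \le t) \le t$ under the null —
rather than exactly uniform. The test suite checks both properties on
spectra drawn from the background generator at $n = 1000$: the one-sided
excess $\max_t(\hat F(t) - t)$ stays within sampling noise, and the
tie-randomised transform of the same p-values passes a two-sided
Kolmogorov–Smirnov test against the uniform.

**Validation** (`validate_classifier`) repeats a stratified split (default
10 repeats, 70 % training) per annotated class, retrains, and reports
per-family sensitivity and specificity of the $p \le 0.05$ call plus the
AUC of the score ranking, averaged over repeats. Families untrainable in a
split are skipped for that repeat.

## Chemodiversity statistics

Abundance tables are log10-transformed with zeros imputed to zero
(base 10; transformed tables carry a flag so the transform cannot be
applied twice). Presence is called per sample: a compound is present when
its abundance strictly exceeds 0.1 % of that sample's largest peak. The
per-sample referent — rather than a global one — makes presence calls
invariant to between-run intensity drift; this was a genuinely open
reading and is the package's choice.

Per composition, with $p_i = N_i / N$ over positive entries:

* richness $S$ = number of positive entries,
* Shannon index $H' = -\sum_i p_i \ln p_i$ (the leading minus sign is the
  standard form; it guarantees $H' \ge 0$, maximal $\ln S$ at uniformity),
* Pielou's evenness $J = H' / \ln S$, undefined (reported `NA`) at
  $S \le 1$. Natural logarithm in both, for consistency.

Composition differences between two conditions use, per class $k$, the
2×2 contingency table (in-class vs other) × (fresh vs dry) with the
two-sided Fisher exact test at $\alpha = 0.005$, deliberately without
multiplicity correction, mirroring the published workflow; the exact test
is conservative, so the realised null significant-class rate sits at or
below $\alpha$. The relative-frequency shift

$$f_k = \frac{\mathrm{dry}_k}{\sum_i \mathrm{dry}_i} - \frac{\mathrm{fresh}_k}{\sum_i \mathrm{fresh}_i}$$

telescopes to $\sum_k f_k = 0$ exactly and is antisymmetric under
condition swap. Class-level counts can be taken as compound–sample
occurrences (default) or distinct compounds per condition
(`class_condition_counts(mode=)`); both views are exposed because the
source material does not fix one.

Group comparisons use a one-way ANOVA with Tukey HSD post hoc
(`stats::aov` + `multcomp`), summarised as a compact letter display.
Ontology roll-ups count, per node, the compounds whose primary term equals
or descends from it; unresolvable terms accumulate under a reserved
`unclassified` node so the root total conserves the number of classified
compounds.

## Chemotaxonomy

Species profiles are the mean of the (log-transformed) sample profiles per
species. Chemotaxonomic dendrograms use Bray–Curtis dissimilarity
($d = \sum|a_i - b_i| / \sum(a_i + b_i)$, via `vegan`) and Ward.D
agglomeration — the unsquared Lance–Williams convention, named explicitly
in the workflow this package implements, as opposed to Ward.D2. Trees are
compared by:

* **Mantel r** — Pearson correlation of the cophenetic upper triangles,
  significance by joint row/column permutation
  ($p = (1 + \#\{r^* \ge r\})/(1 + N_\mathrm{perm})$, seeded);
* **cophenetic c** — the plain Pearson correlation of the same vectors;
* **rf** — Robinson–Foulds distance normalised by the total internal
  split count of both trees, so $rf \in [0, 1]$ with 0 iff identical
  unrooted topologies (the unnormalised count is available via
  `robinson_foulds(..., normalized = FALSE)`);
* **Procrustes m²** — symmetric Procrustes sum of squares after aligning
  two-axis classical-scaling embeddings of the cophenetic matrices. Two
  axes were chosen as the smallest embedding that still distinguishes
  topologies; the source material does not state a dimensionality.

Cophenetic distances are merge heights for dendrograms and patristic path
lengths for phylogenies. The cosmetic top-subtree swap used in published
tanglegrams is available as `swap_top` and provably leaves cophenetic
structure unchanged.

## What the simulators emulate — and what they do not

`simulate_spectral_library` plants per-class signature sets of fragments
and neutral losses (each member spectrum realises ≥ 75 % of its signature
plus noise peaks), with a controllable shared-feature fraction between
classes, compounds nested in classes, and a miniature ontology. The
defaults (3 classes × 20 spectra, 8-feature signatures, 3 noise peaks)
are the library scale at which the selection criteria are all active yet
training stays in seconds.

`simulate_dia_run` produces Gaussian MS1 elution profiles (σ = 3 s, within
the 10–20 s base-width detection band), true fragments as scaled copies of
the precursor profile in the correct isolation window, and decoys as
RT-displaced Gaussians (default 25 s, enough for partial bound overlap so
the *correlation* criterion, not the overlap pre-filter, does the
rejecting). Decoys differ only in RT, deliberately isolating the
correlation criterion.

`simulate_condition_study` draws compound presence from a logistic model
with per-compound baselines, per-species random effects, and class-level
logit shifts under the dry condition (defaults: one class at +2, one at
−2, rest null — a strong but not saturating effect), and log-normal
abundances with species intercepts. Ten species × 2 conditions × 4
replicates mirrors a balanced two-factor herbarium design.

None of the simulators model electrospray physics, adducts, isotope
patterns beyond the C13 pairs used to test deisotoping, retention-time
drift between samples, or chimeric co-isolation. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under their
stated assumptions, not instrument-level performance on raw vendor data;
for real accessions, MS1 peak picking and mzML parsing should be
delegated to dedicated MS infrastructure, and this package consumes the
resulting tables and MSP spectra.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale: 20-precursor
DIA runs (5 true + 5 decoy fragments each), 60-spectrum training
libraries, 30-spectrum selection fixtures, 100-replicate study
simulations, and ≤ 10-leaf tree-comparison instances — sizes at which
every stochastic check is replicated across seeds and brute-force oracles
(exhaustive hypergeometric enumeration, Lance–Williams re-implementation,
LCA walks, bipartition sets) remain feasible. Every stochastic component
takes an explicit integer seed; training, simulation and the pipeline are
reproducible to the byte given the seed.

## Known limitations

* The peak detector is a simplified local-maximum device; it will split
  strongly tailing peaks and cannot deconvolve co-eluting isomers.
* Scoring ignores intensity agreement (only the matched set matters); the
  consensus median intensities are carried for inspection, not used in the
  score.
* Positive- and negative-mode tables are joined by row concatenation with
  mode-prefixed ids; duplicate compounds across modes are not merged, as
  no cross-mode identity is available without identification.
* Fisher tests are uncorrected by design (matching the workflow this
  reproduces); with hundreds of classes, control the family-wise error
  externally if needed.
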