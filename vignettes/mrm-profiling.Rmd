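---
title: "MRM-profiling lipidomics: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRM-profiling lipidomics: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmrm)
```

## The measurement model

MRM-profiling screens lipid extracts by flow injection on a triple
quadrupole: each analyte is a *transition* — a parent m/z selected in Q1 and
a diagnostic fragment monitored in Q3 — and each 2-minute injection yields
one intensity burst per transition. Discovery scans find the transitions
(precursor-ion scans fix Q3 on a class fragment; neutral-loss scans fix the
Q1−Q3 offset; free fatty acids, whose collision-induced fragmentation is
uninformative, are monitored with Q1 = Q3 in negative mode), and the
screening phase runs the assembled transition lists over all samples.

Because skin-barrier lipid biology is governed by the *relative* amounts of
lipids, every statistic operates on TIC-normalized intensities: each
transition is divided by the summed intensity of all transitions in its
method for that sample, so a sample's profile is a point on the simplex.
Normalization is idempotent and scale-invariant, which makes the analysis
immune to injection-to-injection total-signal drift — a property the test
suite checks directly.

## Mass arithmetic and attribution

All masses are monoisotopic (C 12, H 1.0078250, N 14.0030740, O 15.9949146,
P 30.9737615; proton 1.00728). An acyl chain *n*:*d* with *h* hydroxyls has
the free-fatty-acid formula CₙH₍₂ₙ₋₂d₎O₍₂₊h₎; a ceramide is sphingoid base +
N-acyl − H₂O; acylcarnitines and cholesteryl esters are carnitine /
cholesterol + acyl − H₂O; glycerophospholipids and sphingomyelins are
modelled at sum composition (total carbons : double bonds), since
flow-injection scans cannot resolve sn-positions.

Attribution matches an observed Q1 against candidate precursor m/z values
within **±0.5 Da** — the tolerance of a unit-resolution quadrupole, also
used for Q3 class keys and MS/MS fragment matching. Printed set-points in
screening tables are low-resolution (e.g. a computed 554.51 monitored as
554.2); the window absorbs that discrepancy deliberately, and we never
switch to average masses to force agreement.

Design choices a maintainer should know:

- **Adducts.** Positive classes fly as `[M+H]+`; FFAs as `[M−H]−`;
  cholesteryl esters as `[M+NH4]+`. Phytosphingosine (t-base) and
  sphinganine ceramides additionally consider `[M+H−H2O]+`: in-source
  dehydration is prominent for these bases, and the dehydrated reading is
  the one that reconciles observed phytoceramide parents with their Q3
  fragment. Sphingosine (d18:1) ceramides use `[M+H]+` only.
- **Candidate grids.** Chains are enumerated over even carbon counts
  (2–36): mammalian straight-chain fatty acyls are overwhelmingly
  even-numbered, and admitting odd chains lets implausible isomers (e.g. an
  odd-chain triene) shadow genuine assignments at unit resolution. Ceramide
  N-acyls allow ≤ 2 double bonds (epidermal amide-linked fatty acids are
  saturated or lightly unsaturated); FFA unsaturation is capped by chain
  length (≤ 3 below C18, 4 at C18, 5 at C20, 6 from C22 — through
  docosahexaenoate). PC/SM sum compositions allow odd totals because
  odd-chain sphingomyelins (15:0, 17:0 acyls) are real. All bounds live in
  `attribution_grid()` and are overridable.
- **Ties.** Candidates are ranked by |mass error|; exact m/z ties
  (isomeric formulas, e.g. an alkyl-ether PC(34:1) vs a plasmalogen
  PC(34:0)) are broken toward fewer double bonds, then fewer hydroxyls, and
  *all* candidates within 0.1 Da of the best are reported as co-candidates
  with status `ambiguous` — multi-name attribution cells are a feature, not
  a failure. For the PC/SM family, a species whose M+1 isotopologue
  (+1.00336) would land on the observed Q1 is reported as an isotope note.
- **Degenerate inputs.** Unknown classes attribute to `not_attributed`
  (a value, not an error); empty spectra, all-zero samples, orphan
  transitions and duplicate sample/transition pairs are hard errors with
  the offending identifiers in the message.

## The synthetic cohort generator

The generator emulates the study design the pipeline was built around:
a testing set of 7 *cpdm* + 8 WT and a validation set of 10 *cpdm* + 11 WT
mice, screened on a positive method of 217 transitions and a negative
method of 83. Raw intensity for sample *s* and transition *t* is

```
raw(s, t) = scale · TIC_s · p_g(t) · ε_st
```

with `p_g` the group's expected relative-abundance profile, `ε` log-normal
multiplicative noise of mean 1 and CV `cv`, and `TIC_s` a per-sample,
per-injection log-normal factor. Effects are specified **on the normalized
scale**: the *cpdm* profile sets `baseline · FC` on affected transitions and
rescales the unaffected ones by a common factor so the profile still sums
to 1. The published fold changes are therefore recoverable by construction —
the ratio of group means of TIC-normalized intensities estimates `FC(t)`
directly — at the price that "unaffected" transitions carry a small common
compensatory shift (≈ 0.93 under the default effects), which is exactly what
a zero-sum relative scale implies.

Defaults, with units and rationale:

| Parameter | Default | Meaning |
|---|---|---|
| `cv` | 0.2 | within-group CV of a transition intensity (fraction). No variance components are published for this assay type; 20% is a realistic flow-injection repeatability figure and is a documented knob, not a claim. |
| `tic_scale_sd` | 0.3 | log-scale SD of the per-sample total-intensity factor. Irrelevant to all downstream statistics by TIC invariance; present so raw tables look like instrument output. |
| `effects` | packaged fold changes | per-transition *cpdm*/WT ratios of the significant-feature table; transitions without an entry take the compensatory factor. |
| `baseline` | `default_baselines()` | deterministic epidermis-like composition: PC/SM dominate the positive method; FFAs peak at palmitate/oleate with an ultra-long-chain bump at cerotic acid. |

What the generator does **not** emulate: chemical noise, isobaric
interference, in-source fragmentation cross-talk, retention behaviour,
carry-over and blank injections, or detector saturation. Passing tests
therefore demonstrate that the *computational* pipeline recovers what was
planted under realistic sampling noise — not that the assay itself would
behave this way on new tissue.

The packaged 217/83-transition methods are a **synthetic reconstruction**:
the significant-feature transitions are included verbatim, and deterministic
grid-enumerated fillers bring each lipid class to its reported discovery
count (68 phospholipid + 32 cholesteryl ester + 21 acylcarnitine +
33 ceramide + 63 acyl-residue neutral-loss features positive; 83 FFA
negative). They are a stand-in for the instrument method tables, not a copy.

## Statistics

- **Univariate testing** uses the pooled-variance unpaired t-test (Welch
  behind `var_equal = FALSE`; the upstream tooling convention is ambiguous,
  and with n = 7/8 per group on relative abundances the pooled form is the
  conventional default). Family-wise error is controlled by the Holm–Šidák
  step-down: order p ascending; feature *k* is significant iff
  `p₍ⱼ₎ ≤ 1 − (1−α)^{1/(m−j+1)}` for every *j* ≤ *k*. This is not the same
  procedure as `p.adjust`'s Holm (Bonferroni-based) method, so it is
  implemented directly and verified against a literal-definition oracle on
  random inputs.
- **Volcano selection** uses *raw* p ≤ 0.05 with a two-fold cut in either
  direction — the reported p-value column of the significant-feature table
  is on raw scale (values like 4e-4 would not survive a 300-test
  correction), so the corrected flag is carried alongside rather than used
  for selection.
- **Fold change** is the ratio of arithmetic group means of normalized
  intensities (*cpdm*/WT; values < 1 are down-regulation).
- **PCA** runs on autoscaled values (per-feature mean 0, SD 1); constant
  features are dropped with a warning; component signs are fixed by making
  the largest-magnitude loading positive. **Clustering** is Ward linkage
  (`ward.D2`) on Euclidean distances of autoscaled values — a documented
  choice; no linkage is canonical for heat maps of this kind.
- **Aggregate profiles** sum attributed relative amounts per sample into
  interpretable schemes (ceramides by base, hydroxylation, chain length;
  FFAs by saturation and chain-length bins 12–18 / 20–24 / ≥ 26) and report
  per-phenotype mean ± SE.

## Biomarker panels

Univariate AUC is the Mann–Whitney rank statistic with midranks for ties;
it equals the trapezoidal ROC integral on every input, and both routes are
exported so the equality is a standing cross-check. Thresholds maximize the
Youden index and sit at midpoints between adjacent observed values.

The multivariate panel is PLS-DA with 2 latent components (the smallest
panel has 3 features; the count is config-exposed), fitted via `mixOmics`;
class probability is the predicted class indicator truncated to [0, 1], and
hard calls threshold at 0.5. An optional random forest (500 trees, seeded)
is available behind `algorithm = "rf"`. Out-of-sample performance uses
repeated stratified Monte-Carlo cross-validation — 2/3 train fraction, 100
repeats, seeded — a documented stand-in for unstated upstream tool
internals; the headline quantity, accuracy on the *blind validation split*,
does not depend on the CV scheme. Training is restricted to the testing
split, prediction refuses samples seen in training, and shuffling
validation labels provably cannot change fitted weights.

## Quantification

Internal-standard quantification is `(analyte area / IS area) × IS nmol /
dry weight` in nmol/mg (IS default 0.5 nmol), homogeneous of degrees
(+1, −1, −1) in its three inputs. Calibration linearity is ordinary least
squares of intensity on concentration over the spiked levels (default 1 to
10,000 ppm, 3 replicates × 5 levels = 15 points), with verdict `linear`
when R² ≥ 0.99 — a documented numeric cut-off for a qualitative published
claim. qPCR expression uses the population form of 2^−ΔΔCt (group-mean ΔCt
difference against *Actb*) with an unpaired t-test on per-sample ΔCt.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
the study's own scale: 36-sample cohorts over the 300 packaged transitions,
200-seed replicate banks for fold-change recovery, 100-repeat CV for
panels, 1000 random draws for the step-down oracle. Every stochastic stage
takes an explicit integer seed, and `run_pipeline()` derives logged
sub-seeds from a single master seed so a config reproduces its artifact
bundle byte-for-byte.

## Known limitations

- Attribution is tentative by construction: unit-resolution matching within
  ±0.5 Da cannot separate isomers, and several printed attributions in the
  curated table are only reachable as co-candidates or, for a handful of
  rows, not reconcilable with exact-mass arithmetic at all (the engine then
  reports its own mass-consistent candidate or `not_attributed`).
- The ingest layer reads the tabular acquisition dialects (scalar
  intensities and chronograms); vendor raw formats and mzML parsing are out
  of scope for this package.
- No isotope-envelope deconvolution: the M+1 note on isobaric PC/SM calls
  is an annotation, not a correction.
- Real-data quantities that depend on the deposited raw measurements
  (explained-variance percentages of the published PCA, the FFA panel's
  misclassification counts, gene-expression p-values) are not
  desk-reproducible; the package checks their *directional* analogues on
  synthetic cohorts instead.
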