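# lipidmrm

Flow-injection shotgun lipidomics by **MRM-profiling**, packaged as a tested,
reusable R pipeline. The scientific setting is the epidermis of
SHARPIN-deficient *cpdm* mice, a model of chronic dermatitis: relative
amounts of specific ceramides and free fatty acids (FFA) discriminate
diseased from wild-type (WT) skin, and a small panel of sphingosine
ceramides classifies unseen animals perfectly. `lipidmrm` implements every
computational step of that workflow — from class-specific scan design to the
ROC-validated biomarker panel — together with a seeded synthetic-cohort
generator that emulates the study design, so the whole analysis is
reproducible at the desk.

## What the package does

- **Scan design** (`build_discovery_scans()`, `assemble_screening_methods()`):
  precursor-ion scans (m/z 184 for PC/SM, 264.3/266.4/282.4 for sphingosine /
  sphinganine / phytosphingosine ceramides, 85 for acylcarnitines, 369.1 for
  cholesteryl esters), neutral-loss scans (141/185/277 Da for PE/PS/PI,
  299/321 Da for oleate/arachidonate acyl residues) and negative-mode FFA
  single-ion monitoring, assembled into two polarity-split flow-injection
  methods (217 positive + 83 negative transitions) with the class
  collision-energy map (ceramides/PE/acyl-residues 22 V, PC/SM 20 V, PS/PI
  16 V, CE 17 V, AC 30 V; 2 V negative; fragmentor 100 V).
- **Lipid mass arithmetic** (`parse_lipid()`, `acyl_mass()`,
  `precursor_mz()`, `base_fragment_mz()`): shorthand nomenclature parsing and
  monoisotopic masses for acyl chains, sphingoid bases, head groups and
  adducts; e.g. the sphingosine fragment `[d18:1 + H − 2 H₂O]⁺` computes to
  m/z 264.2686 and CerNS(d18:1/16:0) `[M+H]⁺` to 538.519.
- **Ingest & normalization** (`ingest_cohort()`, `tic_normalize()`): reads
  tabular acquisitions or chronograms (trapezoidal integration), matches
  transitions within ±0.5 m/z, and normalizes each sample by the total ion
  intensity of all transitions in its method, yielding relative amounts that
  sum to 1.
- **Attribution** (`classify_transition()`, `attribute_species()`,
  `interpret_msms()`): class calls from diagnostic fragments, candidate
  species enumerated over bounded chain grids and matched within ±0.5 Da
  (ties reported as ambiguous co-candidates, M+1 isotope co-assignments
  flagged), and ceramide MS/MS spectra interpreted into fatty-acyl residue
  masses.
- **Statistics** (`holm_sidak_ttests()`, `volcano_select()`,
  `pca_autoscaled()`, `cluster_heatmap()`, `aggregate_profiles()`): unpaired
  t-tests with Holm–Šidák step-down correction (feature *k* significant iff
  `p₍ⱼ₎ ≤ 1 − (1−α)^{1/(m−j+1)}` for all *j* ≤ *k*), volcano selection
  (p ≤ 0.05, ≥ 2-fold), autoscaled PCA, Ward clustering, and the ceramide /
  FFA aggregate profiles (by sphingoid base, hydroxylation, chain length,
  saturation).
- **Biomarker panels** (`univariate_roc()`, `fit_panel()`,
  `predict_validation()`): Mann–Whitney rank AUC (provably equal to the
  trapezoidal ROC integral), PLS-DA (default) or random-forest panels
  trained on the testing split with repeated stratified Monte-Carlo CV, and
  blind class prediction of the validation split with leakage guards.
- **Quantification** (`quantify_sample()`, `fit_calibration()`,
  `ddct_fold_change()`): internal-standard concentrations
  `(area/IS area) × IS nmol / mg dry tissue`, calibration linearity over
  1–10,000 ppm, and qPCR `2^−ΔΔCt` fold changes against *Actb*.
- **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): seeded
  two-group intensity tables (7 *cpdm* + 8 WT testing, 10 *cpdm* + 11 WT
  validation) with log-normal within-group noise (CV 0.2), per-sample TIC
  factors, and per-transition fold changes defaulting to the packaged
  significant-feature table.
- **Orchestration** (`run_pipeline()`): one call from config (R list or
  YAML) to the full artifact bundle (matrices, statistics, attributions,
  profiles, ROC report, quantification), byte-reproducible under a fixed
  seed.

## Worked example

```r
library(lipidmrm)

methods <- reference_screening_methods()      # 217 (+) and 83 (−) transitions
cfg     <- cohort_config()                    # the study design, cv = 0.2
tab     <- generate_cohort(cfg, seed = 42)    # 36 samples, both methods
fm      <- ingest_cohort(tab, methods$positive)

st <- holm_sidak_ttests(subset_samples(fm, split = "testing"))
st[st$transition == "666.35/264.1+", c("fold_change", "p", "significant")]
#>   fold_change            p significant
#>       19.0725 1.023525e-07        TRUE

attribute_species(666.35, "Cer[S]")
#> <attribution 666.35 [Cer[S]]: attributed -> CerAS(d18:1/24:0)2OH (delta +0.289)>

model <- fit_panel(fm, biomarker_panel("ceramide"), seed = 7)
model
#> <plsda panel of 3 features; CV AUC 1, CV accuracy 1>
pred <- predict_validation(model, fm)
attr(pred, "accuracy")
#> [1] 1
```

The estimated fold change of transition 666.35→264.1 (CerAS(d18:1/24:0)2OH)
recovers the generator truth of 18.73 up to sampling noise; the
three-ceramide PLS-DA panel trained on the 15 testing samples classifies all
21 blind validation samples correctly (accuracy 1 = 100%).

## Scope and limitations

The package operates on transition intensities; vendor raw files, peak
deconvolution, instrument control and the original deposited raw data are
out of scope. Synthetic cohorts emulate the published group structure and
effect sizes but not chemical noise or isobaric interference; see the
methods vignette (`vignettes/mrm-profiling.Rmd`) for the model, its
assumptions and the numerical choices.
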