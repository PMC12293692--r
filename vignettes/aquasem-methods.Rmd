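---
title: "Models and design choices in aquasem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in aquasem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquasem)
```

`aquasem` analyses boar seminal plasma along two arms: near-infrared
chemometrics of the water first overtone (1300–1600 nm) and emPAI-based
proteomics of seminal-plasma extracellular vesicles. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic benchmark can
and cannot say about real data.

## The spectral model

Aquaphotomics treats the first overtone of the O–H stretch as a
superposition of twelve water species — dimers, free water, progressively
hydrogen-bonded clusters, solvation shells — each absorbing in a narrow
band (the WAMACS coordinates C1–C12). The synthetic generator follows the
same picture. A noise-free group spectrum is

$$A_g(\lambda) = b(\lambda) + \sum_{c=1}^{12} a_{g,c}
  \exp\!\left(-\frac{(\lambda - \mu_{g,c})^2}{2\sigma_c^2}\right),$$

where $b(\lambda)$ is a smooth water continuum (a low-order polynomial in
the scaled coordinate $(\lambda - 1450)/150$; default
$0.60 + 0.05x - 0.25x^2$, a broad hump peaking near 1460 nm), and each
WAMACS band contributes a Gaussian with group-specific centre
$\mu_{g,c}$ (nm) and amplitude $a_{g,c}$ (absorbance units, default
0.02 AU) of width $\sigma_c$ (default 5 nm).

The default configuration plants group differences only where the study
system shows them: Passed peaks at 1348 (C1), 1404 (C5) and 1507 nm
(C12) against Failed peaks at 1344, 1398 and 1518 nm. All other bands
are identical between groups. Two variance components sit on top:

* `sample_sd` (default 0.004 AU) — a per-sample constant absorbance
  offset, the kind of between-filling variation that concentration and
  effective path-length differences produce when a cuvette is repacked.
  Keeping it constant across wavelengths also keeps the per-wavelength
  within-group standard deviation flat, which matters for the
  normalization step below.
* `noise_sd` (default 0.002 AU) — independent per-wavelength replicate
  noise.

The study never reports within- versus between-sample spectral variance,
so these magnitudes are the package's own choice: small enough that the
planted band shifts dominate (the benchmark is achievable by design),
large enough that every estimator faces nonzero noise. They are synthetic
calibrations, not measured quantities, and results on real spectra will
depend on the real variance structure.

The generator emits the 1300–1600 nm analysis grid directly at the
instrument's 2.0-nm step for that range; the 1.4-nm step used below
1000 nm is irrelevant to the modeled window and is not simulated.
Separately, `resample_to_grid()` harmonises real multi-step acquisitions
by linear interpolation (never extrapolation).

## Preprocessing conventions

* Transmittance converts by the Beer–Lambert convention
  $A = -\log_{10} T$; the inverse $T = 10^{-A}$ makes the conversion a
  bijection on positive transmittance. The source instrument records
  transmittance; plots of "normalized absorbance" imply this transform
  without naming it, so the package states it explicitly.
* The analysis region is the closed interval [1300, 1600] nm — 151 grid
  points at 2 nm.
* Replicate policy: by default the ten replicate scans of a sample are
  averaged before modeling. Whether the original models used 640
  replicate spectra or 64 sample means is not stated in the source;
  averaging is the safer default because it makes replicate leakage
  across cross-validation folds impossible. Replicate-level rows remain
  available (`average_replicates` toggled off in the pipeline config);
  folds are then still grouped by sample.
* No scatter correction is applied by default, since none is named by
  the source; "transformed absorbance" is read as absorbance after
  conversion, resampling and trimming. A standard-normal-variate option
  (`snv_correct()`, `scatter_correction` in the pipeline config) exists
  for data with multiplicative scatter.

## PCA–LDA classification

PCA is computed by singular value decomposition of the mean-centered
matrix; explained-variance ratios are $d_i^2 / \sum_j d_j^2$. Loading
signs follow the convention that each component's largest-magnitude
element is positive, so plots are reproducible across platforms. The
component count is the smallest $k$ whose cumulative ratio reaches the
variance threshold (default 0.9999, the reported operating point).

"Full random cross-validation" is implemented as k-fold cross-validation
with random sample-grouped partition, defaulting to leave-one-sample-out.
Inside each fold, centering, the PCA, the component count and the LDA are
all re-derived from the training rows only; the held-out rows are
projected with the training column means and loadings. A test in the
suite poisons held-out samples with extreme outliers and verifies that
co-fold predictions do not move. Because $k$ is re-selected per fold it
may vary across folds; the per-fold counts are reported.

LDA uses pooled within-class covariance and empirical priors. At a
99.99% threshold on low-noise data, $k$ routinely exceeds the pooled
covariance's degrees of freedom ($n_\text{train} - 2$), so the matrix is
singular; a ridge of $10^{-8}\,\mathrm{tr}(\Sigma)/k$ is added to the
diagonal and a warning is issued once per cross-validation run. Ties in
the discriminant resolve to the lexicographically smaller label.
Sensitivity treats *Passed* as the positive class — the source does not
say which class it counted as positive, and Passed is the detection
target. Metrics with zero denominators are reported as `NA`, never as 0.

## Aquaphotomics

Normalization follows the stated recipe: subtract the mean absorbance of
the distilled-water reference, then divide by the per-wavelength standard
deviation of each category. Two details are pinned down here because the
recipe leaves them open:

* SD convention — the sample standard deviation (n − 1 denominator),
  per wavelength, per category.
* Degenerate categories — a category with zero spread at a wavelength is
  an error (it names the wavelength), except in the well-defined limit
  where the category also equals the water mean there, which normalizes
  to 0. This is what makes a noise-free water reference its own zero.

WABS detection is a grid argmax within each band's closed limits, ties
to the lower wavelength, no sub-grid interpolation (a parabolic
refinement exists behind a flag but is off, since the source reports
whole-nanometre peaks). Detection operates on reference-normalized
spectra: subtracting the water continuum matters, because on raw
absorbance the sloping continuum tilts a 0.02-AU band enough to move its
argmax a grid step or two off-centre.

The twelve-band registry ships literature-standard first-overtone limits,
slightly widened so that the wavelengths reported for this system fall
inside their bands: 1348 nm in C1, 1398 and 1404 nm in C5, 1507 and
1518 nm in C12. The source also lists 1398 nm alongside C1; since bands
must be ordered and non-overlapping and 1398 nm belongs to C5's range,
the registry records that value in C1's `reported_nm` metadata without
asserting membership. The registry is validated on construction
(ordering, non-overlap, containment), and users may supply their own
limits.

Aquagram values are the group-mean normalized absorbance at each group's
own WABS wavelength (the peak "identified at baseline"); passing `at`
evaluates all groups at a fixed wavelength per band instead, trading the
per-group peak definition for cross-group comparability. The reference
group's aquagram is identically zero at zero noise and within sampling
error of zero otherwise.

## EV proteomics

emPAI is $10^{N_\text{observed}/N_\text{observable}} - 1$, taken from
the index's defining literature since the source names but does not
print the formula. Protein tables read from TSV may carry peptide-count
columns; when present, emPAI is recomputed and any supplied values must
agree within $10^{-9}$.

Differential calling tests only proteins shared by both tables: proteins
unique to one group have no variance estimate on the absent side and are
reported as presence/absence findings. The test is a two-sided Welch
t-test on $\log_{10}(\text{emPAI} + \varepsilon)$ with
$\varepsilon$ = smallest nonzero emPAI / 10 — Welch because group
variances need not match, the log because emPAI is a ratio-scale
abundance. The source does not state which test produced its p-values; a
Mann–Whitney alternative is available by config. P-values are raw by
default, mirroring the reported raw values; Benjamini–Hochberg is a
flag. Direction is the sign of the mean log-ratio Passed/Failed. The
replicate structure behind the original emPAI values (how 18 animals map
to replicates) is unstated, so the generator parameterises replicates
explicitly (default 9 per group) rather than guessing the original
layout.

The generator draws one baseline $\log_{10}$-emPAI per protein from
$\mathcal{N}(0, 0.5)$ (emPAI mostly between 0.1 and 10, as typical for
this index), shared between groups; per-sample values add
$\mathcal{N}(0, 0.2)$ noise. Planted differential proteins add their
full effect (default +1 log₁₀, a tenfold ratio) to the favoured group.
Uniqueness is presence/absence: unique proteins draw abundances from the
same distribution.

## Pipeline and reproducibility

`run_pipeline()` runs the configured stages in order and assembles a
JSON-serialisable report with no wall-clock values, so identical configs
give byte-identical reports. The single config seed fans out to fixed
per-stage offsets (+1009 spectra, +2003 water, +3001 proteins, +4001
cross-validation), which keeps stages independently reproducible:
deleting the proteomics section cannot change the classification
results. A stage error aborts with the stage name; sections already
computed are still written when an output directory is configured.

## Problem sizes in the test suite

The unit tests run reduced designs (typically 6–16 samples, 2–3
replicates) chosen to exercise every code path quickly; the end-to-end
checks use the full benchmark design (64 samples × 10 replicates), 100
seeded repetitions for the water-band recovery rate, 50 random matrices
for the PCA oracle, and 10 × 1000 null proteins for the type-I-error
calibration of the differential test.

## Known limitations

* The generator is phenomenological: additive Gaussians on a polynomial
  continuum, no Beer–Lambert path-length physics, no temperature
  dependence of the water bands, no instrument drift. Passing the
  benchmark shows the estimators recover planted structure under this
  model, not that real seminal plasma is this well-behaved.
* Between-sample variation is a constant offset; real biological
  variation also reshapes band amplitudes, which would inflate the
  per-wavelength SD near bands and make WABS detection on normalized
  spectra harder than it is here.
* The classifier stack is deliberately limited to PCA-LDA; no PLS-DA or
  SIMCA, and no attempt to reproduce any proprietary package's exact
  numerics.
* Proteomics starts at emPAI tables: no spectrum processing, database
  search, PSM-level FDR, or downstream enrichment/network analysis.
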