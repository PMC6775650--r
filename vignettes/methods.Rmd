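---
title: "Tissue classification from diffuse reflectance spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue classification from diffuse reflectance spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscascade)
```

## The problem

During colorectal cancer surgery the surgeon must decide, at the resection
surface, whether tissue is peritumoral fat, healthy colorectal wall or
tumor. Diffuse reflectance spectroscopy (DRS) probes the tissue with
broadband light through a needle carrying one emitting and two receiving
fibers 1.29 mm apart; the re-emitted spectrum over 400–1700 nm is shaped by
the tissue's absorbers (hemoglobin, water, lipid) and its scattering, and
carries enough contrast to separate the three tissue types. `drscascade`
implements the full analysis: preprocessing of the raw two-band frames, a
two-stage linear SVM classifier, MCC-based evaluation, a tumor-depth
sensitivity analysis, and a sensitivity-constrained operating point for
comparison with the surgeon's own judgement.

Because in vivo patient spectra of this kind are not publicly available,
the package ships a physics-motivated generator that produces datasets
with the same statistical structure, so every stage is testable end to end.

## Preprocessing

Each measurement consists of a visible-band frame (400–1100 nm) and a
near-infrared frame (900–1700 nm) in detector counts. Three steps produce
the classifier input:

1. **Calibration.** `(raw - dark) / (white - dark)` per band, against the
   white and dark reference frames recorded before each patient's
   measurements. This removes lamp spectrum, detector response and
   per-patient gain. Values pushed below zero by noise are clipped to 0,
   since reflectance is non-negative.
2. **Stitching.** The two calibrated bands are interpolated onto one
   uniform 400–1700 nm grid (default step 5 nm, giving 261 features) and
   blended in the 900–1100 nm overlap with a linear cross-fade. A
   cross-fade rather than a hard cut or plain average avoids a step
   discontinuity at an arbitrary wavelength that the classifier could
   latch onto. The single stitched vector is this package's choice of SVM
   input; per-band feature vectors would be an alternative.
3. **Normalization at 800 nm.** All values are divided by the value at
   800 nm, obtained by linear interpolation so the grid need not contain
   800 nm exactly. This removes residual overall-intensity differences
   (probe contact pressure, coupling); the classifier then sees only
   spectral shape. The operation is idempotent and scale-invariant.

## The cascaded classifier

Two linear SVMs (cost parameter 1.0, no feature scaling beyond the 800 nm
normalization) form a cascade: the first separates fat from everything
else (wall and tumor merged during training); spectra not classified as
fat go to the second SVM, trained on wall and tumor spectra only. The
second stage's signed distance to the hyperplane is the *tumor score*; a
spectrum is called tumor only if the score strictly exceeds an adjustable
threshold (default 0). Ties at either boundary deliberately fall to the
healthy side, which keeps predictions deterministic and consistent with
the threshold semantics below.

Performance is estimated by stratified ten-fold cross-validation repeated
ten times. The fold unit is the *measurement location*, never the single
spectrum: the three replicate spectra of one site always share a fold,
because replicate leakage across folds would be the most optimistic
distortion available. Grouping whole patients into folds is supported
(`group_by_patient = TRUE`) but off by default; with the generator's
per-location property sampling there is no patient-level signal to leak,
and for real data the option makes the leakage check explicit. Metrics are
computed per repeat and reported as mean ± SD across the ten repeats.

Results are exposed at two levels: per measurement, and per location after
a majority vote over the replicates (score = mean of replicate scores;
a three-way tie falls back to re-running the cascade routing on the mean
scores).

## Evaluation

All metrics are one-vs-all. The Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

is the primary measure because it is far less sensitive to the strong
class imbalance (fat outnumbers conclusive tumor measurements roughly
4.6:1) than accuracy. When a denominator factor is zero the conventional
value 0 is returned; the tests verify MCC equals the Pearson correlation
of the binary label vectors on every 2×2 table with total ≤ 12. Accuracy,
sensitivity and specificity follow their usual definitions, with undefined
rates reported as `NA` rather than 0. The weighted accuracy is the
per-class accuracy weighted by measurements per class. ROC curves sweep
the decision threshold over all distinct scores with infinite endpoints,
so every curve is anchored at (0,0) and (1,1); AUC uses the trapezoid rule
and equals the normalized Mann–Whitney statistic.

For ROC purposes each class needs a score for *every* spectrum, so the
stage-two score is evaluated even for fat-routed spectra there; the wall
score is the smaller of the two negated stage scores (wall = "neither fat
nor tumor").

## Depth labeling and the depth sweep

The probe senses roughly as deep as its fiber separation, so
histopathology truth is depth-dependent: a location is labeled tumor when
tumor starts within 1.5 mm of the measurement surface; a location whose
tumor lies within depth but extends laterally less than 0.5 mm cannot be
reliably co-registered with the H&E section and is excluded as
inconclusive (the generator produces such locations at rate 0.38, matching
the exclusion accounting of the motivating study). Tumor-containing
locations deeper than the rule present healthy wall to the probe and are
labeled wall.

The depth sweep re-runs the entire labeled analysis — relabel, drop
inconclusive, re-train, re-test — for each maximum depth in
{0, 1, 1.5, 2, 3, 4, ∞} mm (∞ = no depth limit, "more than 4 mm"; the
exact bin edges are an interpretation, since only the endpoints and the
1.5 mm point are fixed by the design). Two opposing effects shape the
resulting curve: at small maximum depth few locations qualify as tumor
(at 0 mm only surface tumors, a small and hence noisy class) while
optically tumor-like locations just below the cut contaminate the wall
class; at large maximum depth the tumor class absorbs locations whose
tumor is too deep to influence the measured spectrum at all. Performance
therefore peaks near the 1–1.5 mm sensing depth. In sparse depth bins the
fold count is reduced to the smallest class size (recorded in the
`k_used` column) instead of failing; a bin with no tumor locations at all
is flagged `empty` with `NA` metrics, never silently dropped.

## The zero-false-negative operating point

To rule out positive resection margins, a dedicated threshold is
calibrated so that *no* tumor location is called healthy: on the
calibration subset — the locations the surgeon judged with certainty —
the threshold is placed just below the minimum location-level tumor score
among true tumors (midpoint to the next distinct score below; a fixed
epsilon of 10⁻⁶ below when it is the global minimum, the placement being
a package choice since only the constraint is prescribed). This gives
FN = 0 on the calibration subset by construction and provably minimal FP
subject to that constraint; a healthy location tied exactly with the
minimum tumor score is counted as a false positive. Three further choices
matter:

* Calibration uses **out-of-fold** scores from the cross-validation, never
  resubstitution scores, so the FN = 0 guarantee is not optimistic.
* The threshold operates on **location-level** scores (mean of the
  replicates' tumor scores, averaged over repeats), matching the
  per-location accounting of the surgeon comparison. Whether spectrum- or
  location-level scores were used originally is unstated; locations are
  the clinically meaningful unit.
* For the binary healthy/tumor decision the stage-two score is used for
  all locations (healthy = fat ∪ wall); routing a location through the
  fat stage first could silently veto the FN = 0 guarantee.

The calibrated threshold is then applied to the uncertain locations and
the classifier's 2×2 table against histopathology is set beside the
surgeon's.

## The synthetic-data generator

The generator is a first-class, tested module, not a fixture. Its default
configuration *is* the emulated study design: 32 patients; 4 fat, 3 wall
and 2 tumor locations per patient with 3 replicate spectra each (864
spectra at a 4.3:3.2:2.1 class ratio, emulating the motivating cohort's
402/282/151 imbalance); two spectrometer bands 400–1100 and 900–1700 nm;
1.29 mm fiber separation; per-patient white/dark reference frames; 1%
relative Gaussian intensity noise; 38% of tumor locations laterally
inconclusive; a tumor-depth distribution with 30% surface tumors and an
exponential tail of mean 1.5 mm truncated at 6 mm, so every depth bin of
the sweep is populated; 20% of locations judged "uncertain" by the
simulated surgeon, who over-calls tumor on 69% of truly healthy uncertain
locations and is 97% correct on certain ones.

Spectra are built from latent optical properties per location, drawn from
class-specific Gaussian distributions (clipped to valid ranges): a reduced
scattering power law $\mu_s'(\lambda) = a (\lambda/800)^{-b}$ and
chromophore volume fractions. Absorption uses fixed Gaussian
*pseudo-chromophore* bands (Soret and α/β hemoglobin bands in the
visible, the 760 nm deoxy-hemoglobin band, lipid near 930/1210 nm, water
near 970/1450 nm) rather than literature extinction tables, so the package
needs no external data; the constants are module-level and documented.
The class means are plausible for colorectal tissue — lipid-dominated fat
with a flat scattering slope; water-dominated wall with ~1% blood; tumor
with ~3% blood, lower oxygen saturation and denser scattering — but they
are *chosen, not fitted*: the true optical parameters of the study's
tissues were never published. Reflectance comes from the classic
steady-state diffusion-approximation two-dipole closed form for a
semi-infinite medium (refractive index 1.4) at the 1.29 mm separation.
A buried tumor is rendered as
$w \cdot R_\text{tumor} + (1-w) \cdot R_\text{wall}$ with
$w = e^{-\text{depth}/1.29\,\text{mm}}$ — the simplest model that
reproduces the observed decline of detectability with depth, with the
mixing scale tied to the probe geometry. Raw frames are then
`dark + (white − dark) × scale × R` with multiplicative noise, so the
calibration step has real work to undo.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: Monte-Carlo-accurate radiative transport;
surface blood contamination during surgery; fibrosis and inflammation as
distinct tissue states; patient-level correlation of optical properties
(properties are drawn per location, which is also why the default
cross-validation does not group by patient); co-registration error
between measurement and histopathology beyond the inconclusive-extent
mechanism. The synthetic classes are cleaner than in vivo tissue: the
default cohort yields per-class MCCs around 0.9–1.0, above the 0.73–0.83
of the real study, with the same ordering (fat easiest, tumor hardest).
Absolute synthetic metrics should never be read as expected clinical
performance.

## Numerical choices and degenerate inputs

* Confusion counts are held as doubles: the MCC denominator product
  overflows 32-bit integers already at a few hundred measurements.
* SVM fitting is delegated to libsvm (via `e1071`), a deterministic convex
  fit; the hyperplane weights are extracted and re-oriented by the sign of
  the class-mean scores so that positive always means fat (stage one) or
  tumor (stage two), independent of internal label ordering.
* `calibrate` refuses references with `white <= dark` anywhere;
  `normalize_at_800` refuses non-positive values at 800 nm; `stitch`
  refuses non-overlapping bands; empty confusion input, missing tumor
  depths, and calibration subsets without tumors are all hard errors.
* All randomness flows from explicit integer seeds; identical
  configuration plus seed gives bit-identical datasets, folds, models and
  reports.

## Problem sizes

The shipped tests exercise the full default cohort (32 patients, 864
spectra, 10×10 CV) once, and use reduced cohorts (6–12 patients, coarser
wavelength grids) and single-repeat sweeps elsewhere; the depth-sweep
shape check runs 20 seeds at the default cohort size with one CV repeat
per depth endpoint. The acceptance script runs the default cohort with
the full 10×10 CV and the complete seven-point depth sweep. These sizes
were chosen to estimate each quantity stably while keeping a full run in
the minutes range on one core.
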