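---
title: "Methods: spectral fingerprinting, OSC-PLS-DA and band deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral fingerprinting, OSC-PLS-DA and band deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfinger)
```

This vignette is the package's own account of its models, numerical choices
and limitations. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The measurement model and the synthetic world

The package analyses mid-infrared absorbance spectra of the
low-molecular-weight fraction of dried blood, sampled by ATR. Because no
public cohort exists, a generator (`simulate_cohort()`) stands in for
patient data. Each synthetic spectrum is

$$A(\nu) = s \Big[ \sum_k g(\nu; c_k, w_k, a_k) + B(\nu) \Big]
          + b\,(\nu - \bar\nu) + z\,u(\nu) + \varepsilon(\nu),$$

where $g$ is an FWHM-parameterized Gaussian band
($g(\nu) = h\, e^{-4\ln 2\, (\nu - c)^2/w^2}$, area $= h w \sqrt{\pi/4\ln 2}$),
$B$ collects broad background features (lipid ester C=O near 1740 cm⁻¹,
methyl bending near 1400 cm⁻¹, and the O–H/C–H envelope when the grid covers
it), $s$ is a per-sample global scale, $b$ a linear baseline slope, $z$ a
score on a fixed class-unrelated nuisance direction $u$ (a broad unit-norm
Gaussian at 1740 cm⁻¹ — structured inter-individual variance for OSC to
remove), and $\varepsilon$ white noise.

The class fingerprints are the deconvolved band tables of the source cohort:
FM has bands at 1565/1588/1639/1670 cm⁻¹ with relative areas
0.361/0.382/0.047/0.213 (renormalized to 1), LC at 1581/1635/1670 with
0.703/0.099/0.239, and healthy controls at 1545 (4.1%) plus 1580/1639/1670
splitting the remainder 70/10/20 — the only published constraint for
controls is the 1545 share, so the remainder mirrors the LC pattern.

Parameters the sources do not state were chosen once, on realism grounds,
and frozen:

* **Grid** 1800–1400 cm⁻¹ at 2 cm⁻¹ (stored descending). The acquisition
  resolution (8 cm⁻¹) constrains band shapes, not the digitized spacing;
  2 cm⁻¹ keeps the 5/7-point filters local. A full 4000–700 range is
  supported.
* **Band FWHM** 25 cm⁻¹ for fingerprint bands (typical amide-region widths),
  80–250 cm⁻¹ for backgrounds.
* **Amplitude scale**: total fingerprint band area 12 a.u.·cm⁻¹ per class,
  putting the strongest band near 0.17 absorbance units — a typical
  dried-film ATR magnitude.
* **Dispersions**: amplitude CV 5% (film thickness), baseline slope sd
  2×10⁻⁵ a.u./cm⁻¹, additive noise sd 0.002 a.u., nuisance score sd 0.05.
* **Between-patient band jitter** is opt-in
  (`simulate_cohort(jitter_bands = TRUE)`): the reported band-table sds
  conflate biological and curve-fitting variance, so they are not imposed on
  the default cohort; the default world's stochastic terms are scale, slope,
  nuisance and noise only.

What a green test on this world does establish: the chain recovers known
band structure and class membership under realistic noise, baseline and
nuisance variation. What it does not: robustness to water-vapor/CO₂
artifacts, ATR penetration-depth dispersion, scan co-addition effects, or
non-Gaussian line shapes — none of which are simulated.

## 2. Pretreatment

`pretreat()` follows the protocol order: unit-vector (2-norm) normalization
of the full recorded range (the standard correction for film-thickness
variation; "normalization" was otherwise unspecified), Savitzky–Golay
smoothing (5 points, polynomial order 2), SG second derivative (7 points,
order 2 — the minimum order supporting a second derivative), region
selection (closed interval; 1528–1624 cm⁻¹ for classification), then mean
centering with training column means only. Filter edges are handled by
evaluating the terminal window's polynomial at the edge offsets, so the
output grid equals the input grid; derivatives are scaled by the grid step.
Whether normalization preceded the derivative in the source protocol is
not stated beyond sentence order; sentence order is followed, and the
normalization is configurable for sensitivity analysis.

## 3. Orthogonal signal correction and PLS-DA

OSC removes structured variance unrelated to the class response before
regression. The textbook iterative recipe (orthogonalize a score against y,
regress, project, repeat) has no guarantee at its fixed point: on this
package's own cohorts (80 samples × 49 variables) the converged score
correlates with y at |r| ≈ 0.8. The package therefore uses the exact
constrained formulation: the component weight $w$ maximizes $\|Xw\|$ subject
to $w \perp X^\top y$ and $\|w\| = 1$ (a one-line eigenproblem), so the
score $t = Xw$ is orthogonal to y to machine precision, and applying the
stored $(w, p)$ to the training matrix reproduces the corrected matrix
exactly. If every X direction is response-related (zero orthogonal
variance), the component is skipped.

PLS is plain NIPALS on the dummy response (FM = 1, LC = 2, centered), with
regression vector $b = W(P^\top W)^{-1}q$ and the intercept restoring the
class-code scale. The decision rule is the midpoint: ŷ < 1.5 → FM, ties and
above → LC. One latent variable and one OSC component are the defaults.

Validation conventions (the sources print values but no formulas):
SECV/SEP are root-mean-square residuals with denominator $n$ (no df
correction); Rcv is the Pearson correlation of leave-one-out predictions
with the class codes, and R² its square on the external set; sensitivity
treats FM as positive (configurable — the reference table is symmetric).
The LOOCV refits the entire chain — centering means, OSC, PLS — on every
fold; the per-sample pretreatment steps (normalization, filters) are
sample-independent and are computed once, which the test suite verifies
against a brute-force refit-from-raw oracle. Whether the original software
refit OSC inside the cross-validation loop is unknowable; refitting (the
stricter choice) is implemented. ROC curves sweep the empirical score
thresholds; the trapezoid AUC equals the Mann–Whitney pairwise concordance
with ties counted ½.

## 4. Band deconvolution

The 1500–1700 cm⁻¹ region is resolved per sample in three steps.

**Signal preparation.** Normalize, smooth, second-derivative transform,
multiply by −1, restrict to the region, subtract the line through the region
endpoints, and offset so the minimum is zero (`prepare_signal()`).

**Seeding.** Local maxima above
max(`min_prominence`·max(signal), 10th-percentile floor + 4·robust noise sd)
become band candidates; maxima closer than `merge_distance` (8 cm⁻¹) merge
to their amplitude-weighted mean; maxima within `edge_margin` (10 cm⁻¹) of
the window boundary are discarded (a band centered at the window edge is
unresolvable, and the endpoint-anchored baseline makes edges
artifact-prone). Initial widths come from the half-height width of the
derivative lobe, rescaled by the lobe/band width ratio of a Gaussian
(≈ 0.524).

**Fitting.** The model fitted to the prepared signal is *not* a plain sum of
Gaussians: the negative second derivative of a Gaussian has ~45%-amplitude
side lobes, and fitting bare Gaussians to such a signal misstates relative
areas by 10 points and more even in noise-free constructions. Instead, each
band contributes the negative second derivative of its absorbance-domain
Gaussian, passed through the same SG composite kernel and endpoint-line
baseline operator applied to the data, plus a quadratic polynomial absorbing
broad background residue. The fit is then a consistent inverse of the
preparation, and fitted areas live on the absorbance scale where relative
percentage areas are meaningful. Numerical choices:

* bounded L-BFGS-B with analytic gradients; per-band parameters are scaled
  (amplitude O(1), center offset in units of `center_bound`, FWHM/10) —
  without this the optimizer stalls in long anisotropic valleys;
* convergence at relative χ² change `chi_tol` = 10⁻⁹ (mapped to the
  optimizer's `factr`), iteration cap 400 — a cap, not a guarantee;
  non-convergence is flagged, not fatal;
* FWHM bounds [8, 50] cm⁻¹: in the derivative domain a band's absorbance
  area scales as amplitude × FWHM³, so wide low-amplitude components are
  degenerate background absorbers; 50 cm⁻¹ covers every plausible
  fingerprint band here;
* bands whose fitted derivative amplitude falls below `min_prominence` of
  the largest, or whose center collides with a stronger band within
  `merge_distance`, or drifts within `edge_margin`/2 of the boundary, are
  pruned and the reduced model refit (≤ 3 passes).

Relative percentage area is a band's analytic Gaussian area as a share of
the summed fitted band areas in the region (background polynomial excluded);
doubling the raw amplitude leaves the shares unchanged. Goodness of fit is
reported as χ² (residual sum of squares), reduced χ², and the regression F
of the fitted model against a constant (the exact F-statistic definition of
the original curve-fitting software is unstated).

An absorbance-domain fitting mode (Gaussians fitted to the baselined
absorbance itself) is deliberately not implemented: the derivative-domain
forward model subsumes it while staying consistent with the prepared signal
that seeds and displays the fit.

**Group summaries.** Bands are matched across samples by single-linkage
clustering of centers with `merge_distance` tolerance; samples missing a
band contribute no value (counts are reported). A caveat found during
development: at the reported between-patient center dispersions (sd
3–4 cm⁻¹ on bands 23 cm⁻¹ apart) per-sample centers span the doublet gap
continuously and single-linkage chains the two clusters — a geometric
limitation of the matching rule, not of the per-sample fits. The
group-level tests therefore assert full band-structure recovery on the
default cohort and the robust disease contrast (FM occupies the sub-1580
region, LC never shows a 1565 band) on the jittered one.

## 5. Band statistics

Per matched band, one-way ANOVA (classic between/within decomposition) and
Tukey HSD at the 5% level compare relative areas and centers across groups;
unequal group sizes use the Tukey–Kramer rule (via `stats::TukeyHSD`).
Letters are assigned by a greedy clique cover of the
"not significantly different" graph in descending-mean order, the standard
compact-letter-display behaviour; two-group comparisons stay under the Tukey
interface for uniform reporting. Bands with no cross-group partner within
10 cm⁻¹ are flagged group-unique — the logic that singles out the
FM-specific 1565 cm⁻¹ band. Each band is tested separately with no
cross-band multiplicity correction (whether the source analysis corrected
across bands is unstated); this is a known limitation.

## 6. Reproducibility

`run_pipeline()` chains simulate → split → train → cross-validate →
external-validate → deconvolve → compare, writes every table as CSV with a
JSON manifest (seed, config, version), and is bit-deterministic under a
fixed master seed: the seed fans out to the simulation and split stages by
fixed offsets, and per-sample substream seeds are drawn up front so a
sample's draws do not depend on cohort size. All randomness in the test
suite and the acceptance script flows from explicit seeds.

## 7. Known limitations

* Relative areas from noisy samples carry substantial per-sample variance
  (the derivative-domain SNR of the weakest FM band is ~2 at the default
  noise level); group means remain accurate but per-sample tables should be
  read with their sds.
* The single-linkage band matching chains overlapping clusters under strong
  center jitter (see §4).
* No Lorentzian/Voigt profiles, no full-range global fitting, no
  scatter-correction variants beyond unit-vector normalization, no
  multi-class (> 2) discrimination.
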