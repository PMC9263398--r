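---
title: "Methods: sliding-window dynamic ALFF and seed-based dynamic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window dynamic ALFF and seed-based dynamic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## What the package computes

`dynfc` analyses resting-state fMRI at the region-of-interest (ROI) level.
Its target population is a case/control cohort of older adults — subjective
cognitive decline (SCD) versus normal controls (NC) — but nothing in the
machinery is specific to that contrast. The analysis chain is:

1. **Signal conditioning.** Per subject, the ROI × time matrix is trimmed of
   its first 10 volumes (steady-state), linearly detrended, residualized
   against an optional nuisance matrix, and band-pass filtered to
   0.01–0.1 Hz.
2. **Local dynamics (mdALFF).** A sliding window (50 TRs long, stepped by
   10 TRs) runs over the conditioned series. Within each window, the
   amplitude of low-frequency fluctuation (ALFF) of every unit is the mean
   square-root power over 0.01–0.08 Hz; dividing by the window's global
   mean ALFF gives mALFF, and unit values are averaged into ROI values.
   The mean and sample variance of ROI-wise mALFF across windows are
   `mdalff_mean` and `mdalff_var` — the level and (in)stability of local
   spontaneous activity.
3. **Extended dynamics (dFC).** ROIs whose mdALFF differs between groups at
   the primary threshold become seeds. Per window, the Pearson correlation
   of the seed with every other ROI is Fisher-Z transformed; the mean and
   variance across windows are `dfc_mean` and `dfc_var`.
4. **Inference.** Each metric is tested per ROI (or per edge) with a
   Gaussian-identity GLM — ordinary least squares — on group plus age,
   sex, education and mean frame displacement, with a two-sided Wald t on
   the group coefficient. Multiplicity is handled twice: Benjamini–Hochberg
   over all 273 analysis ROIs (whole-brain family) and independently within
   each functional network (network families). Edge-level contrasts feed a
   network-based statistic (NBS) permutation test. Clinical scores are
   related to the metrics by covariate-adjusted partial correlations, and
   per-group correlations are compared with Fisher's Z.

With two groups, a Tukey post hoc step collapses onto the same group
t-test, so the package implements it as such.

## Parcellation and frame

The parcellation atlas is a table of 300 ROIs carrying a network label (13
named resting-state networks plus `undefined`), an anatomical label,
hemisphere, and MNI coordinates. The 27 `undefined` ROIs are excluded
before any analysis, leaving 273. ROI ids are 1-based and stable; all
tables report them as such. The package operates at ROI grain: a voxel- or
unit-level matrix can be supplied together with a unit-to-ROI map
(`aggregate_units_to_roi()`), but NIfTI-level preprocessing (registration,
segmentation, smoothing, slice timing, despiking) is out of scope and is
recorded as "not applied" in the conditioning report.

## Numerical choices

* **DFT scaling.** The one-sided amplitude spectrum is calibrated so that a
  pure in-band sinusoid of amplitude $A$ contributes exactly $A$ at its bin
  ($2|X_k|/N$ for interior bins, $|X_k|/N$ at DC/Nyquist); no taper, FFT
  length equal to the segment length. Any fixed scaling cancels in the
  mALFF normalization; this one makes the sinusoid oracle exact. Band
  endpoints are inclusive.
* **Band-pass realization.** The filter is an ideal (rectangular)
  zero-phase projection on the DFT grid — the convention of the
  dynamic-connectivity toolboxes this pipeline mirrors. A projection is
  exactly linear and exactly idempotent, which the conditioning-chain
  contracts rely on; a squared IIR response would fail the idempotence
  tolerance on 190-point series because transition-band bins near the
  0.1 Hz edge are numerous on so coarse a grid. The preprocessing band
  (0.01–0.1 Hz) and the ALFF band (0.01–0.08 Hz) are independent settings.
* **Windows.** `n = floor((T - length)/step) + 1` windows; the trailing
  partial window is discarded. With 200 acquired volumes, 10 trimmed,
  window 50 and step 10 this gives exactly 15 windows.
* **Per-window normalization.** mALFF is renormalized within each window
  (`window_norm = TRUE`), keeping `mdalff_mean` centred at 1; dividing all
  windows by the full-series global mean is available as a config switch.
* **Variance estimator.** Sample variance (denominator `n_windows - 1`);
  a single window yields zero variance by definition.
* **Fisher-Z clipping.** Window correlations are clipped to
  `|r| <= 1 - 1e-7` before `atanh`, so coincident series produce a large
  finite Z rather than infinity.
* **Frame displacement.** Power-style scalar FD: the sum of absolute
  backward differences of the six rigid-body parameters, rotations
  converted to arc length on a 50 mm sphere. Exclusion applies at
  translation > 2 mm, rotation > 2°, or mean FD > 0.5 mm.
* **Degenerate fits.** A metric lying exactly in the design span has a
  numerically zero residual; the group t is reported as 0 (p = 1) rather
  than 0/0. Constant series detrend to zero without error; zero-variance
  window segments in dFC are a hard error naming the ROI and window.
* **NBS.** The primary edge threshold is two-sided p < 0.005 on the edge
  GLM (matching the ROI-level reporting threshold; configurable). Group
  labels are permuted with covariates kept attached to subjects — the
  simplest exchangeable scheme, a documented limitation versus
  Freedman–Lane. Family-wise p-values use the +1-corrected permutation
  formula, so the smallest attainable p is `1/(n_perm + 1)` and an
  identity-only permutation set yields p = 1.
* **Correlation comparison.** The Fisher variance uses `n - 3 - k` per
  group, discounting the `k` adjustment covariates. The group comparison
  is two-sided by default; the scientific convention is contested enough
  that a one-sided switch (`one_sided_group_diff`) is exposed rather than
  silently resolved.
* **Partial-correlation FDR family.** The full metric × score grid is one
  family (per-score columns would be an alternative; the grid is the more
  conservative and simpler default).

## The synthetic cohort generator

No human data ships with the package; every statistical claim is exercised
on synthetic cohorts whose structure matches what the analysis assumes.
The default spec generates 40 SCD and 45 NC subjects, 200 timepoints at
TR = 2.5 s, and 273 ROIs.

For subject $i$ and ROI $r$:

$$x(t) = a_0\,[1 + m\,\sin(2\pi f_{slow} t + \varphi)]\,s(t)
        + \sum_k L_{rk}\, g_k(t) + \sigma_\varepsilon\,\varepsilon(t)$$

where $s$ and the per-network factors $g_k$ are independent unit-variance
processes band-limited to 0.01–0.08 Hz, $L$ loads each ROI on its own
network (loading 0.5, giving within-network correlations around 0.2), and
$\varepsilon$ is white. The slow sinusoidal envelope
($f_{slow} = 0.004$ Hz) makes the window-to-window amplitude variance
analytically controllable, and keeps amplitude-mean and amplitude-variance
effects separable: baseline amplitude $a_0 \sim 1 + N(0, 0.2^2)$ carries
mean effects, modulation depth $m \sim 0.3 + N(0, 0.1^2)$ carries variance
effects. Group effects shift the relevant parameter by $d$ between-subject
standard deviations for SCD subjects. Coupling effects add a shared factor
to a seed/target pair, constant for NC and slowly gated on/off (variance
effects) or rescaled (mean effects) for SCD. Covariates are independent of
group by default so that power analyses are clean; confounded designs can
be built by editing the phenotype table.

Clinical scores are drawn from per-group normal distributions matching the
summary statistics of the cohort being emulated (see
`score_distributions()` in the source), clipped to each scale's range (AD8
additionally rounded, separating the groups by construction). When a
correlation target $(\text{ROI}, \text{metric}, \text{score}, \rho)$ is
requested, the score is rebuilt as
$\rho\,z + \sqrt{1-\rho^2}\,\eta$ from the covariate-residualized,
standardized metric $z$, then rescaled and clipped — so the
covariate-adjusted partial correlation targets $\rho$. Clipping attenuates
extreme targets; the construction is intended for $|\rho| \le 0.6$, and
mid-range scales (e.g. digit symbol coding) realize targets with the least
attenuation.

**What the generator does not emulate:** hemodynamic response shapes,
scanner drift and physiological noise spectra, motion artifacts, spatial
autocorrelation beyond network-block structure, and non-Gaussian score
distributions. Passing tests therefore demonstrate that the pipeline's
statistics are calibrated and its effects recoverable under the assumed
generative structure — not that any particular real-data finding would
replicate.

## Effect sizes in the recovery simulations

A parameter-level shift is not a metric-level shift. For the mean metric
the mapping is nearly one-to-one: `mdalff_mean` tracks $a_0$ (normalized),
so $d = 1.2$ on $a_0$ yields a standardized metric effect near 1.2, and
the recovery simulations detect it at p < 0.005 in essentially every
cohort. For the variance metric the package's power analysis (8 cohorts
per candidate $d$) measured a noncentrality of roughly $0.9\,d$: the
between-subject variance of `mdalff_var` is dominated by window-sampling
noise (15 windows) and baseline-amplitude spread, attenuating
modulation-depth shifts about fourfold. The variance-effect recovery
simulations therefore inject $d = 4$ (depth 0.3 → 0.7, within the
physical $|m| < 1$ range), a metric-level effect comparable to the mean
effect's $d = 1.2$. At that magnitude the amplitude-mean metric shifts by
about 2% through the envelope's RMS contribution — effect orthogonality is
exact only to first order, and the orthogonality check is run at the
canonical $d = 1.2$.

## Problem sizes used by the test suite

The suite favours a few deep, parameterised checks: oracle comparisons at
`1e-10` on brute-force DFT sums, straight-line reimplementations of mdALFF
and dFC on a 5-ROI toy cohort, and calibration/recovery simulations at the
full cohort scale (40 null cohorts for the 0.5% primary-threshold
calibration; 50 cohorts for effect recovery; 20 × 200-permutation NBS runs
for family-wise error and component recovery; 100 cohorts at reduced ROI
count for partial-correlation targeting). These sizes were chosen to make
binomial error bars small relative to the margins being asserted.

## Known limitations

* ROI grain only; no voxel-level preprocessing or NIfTI ingestion.
* The permutation scheme assumes exchangeability of group labels given
  covariates; strong group/covariate confounding would call for
  Freedman–Lane.
* The generator's envelope model is sinusoidal, not regime-switching;
  state-modelling analyses (HMM dFC, flexibility/metastability) are out of
  scope.
* fALFF, ReHo and graph-theoretic dynamics are not implemented.
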