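---
title: "Estimating axon radius from intra-axonal relaxation times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating axon radius from intra-axonal relaxation times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonrelax)
```

## The problem

Most axons in the human brain have an inner radius below one micrometre,
under the sensitivity floor of diffusion-MRI radius estimators even on
Connectom-class gradients. `axonrelax` implements an alternative contrast
mechanism: *surface relaxation*. Water near the axonal membrane is more
ordered than axoplasmic water and relaxes faster; in fast exchange the
observed intra-axonal rate is a volume-weighted blend of the two pools.
For a cylinder, the surface-to-volume ratio is $S/V = 2/r$, so

$$\frac{1}{T_{2a}} = \frac{1}{T_{2c}} + \frac{2\rho_2}{r}, \qquad
  \frac{1}{T_{1a}} = \frac{1}{T_{1c}} + \frac{2\rho_1}{r},$$

where $T_{2c}, T_{1c}$ are cytoplasmic relaxation times (ms), $\rho$ is
the surface relaxivity (µm/ms; reported as nm/ms in figures), and $r$ is
the inner radius (µm). Inverting gives the radius estimator

$$r \approx \frac{2\rho}{1/T_a - 1/T_c}.$$

Smaller axons therefore have shorter intra-axonal relaxation times, a
signal that does not depend on gradient strength at all.

## Isolating the intra-axonal signal

At $b = 6000\,$s/mm² in vivo, extra-axonal and free-water spins are
strongly attenuated, and averaging the signal over gradient directions
(the spherical mean) removes the fibre-orientation dependence. The
spherical-mean signal of the joint diffusion–T1–T2 acquisition is
modelled as

$$\bar M(TE, TI) = K e^{-TE/T_{2a}}
  \left|1 - 2 e^{-TI/T_{1a}} + e^{-TR/T_{1a}}\right|,$$

and the T2-only variant as $\bar M(TE) = K e^{-TE/T_{2a}}$. $K$ absorbs
proton density, the intra-axonal volume fraction, the
orientation-averaged diffusion attenuation and scanner scaling; it is a
per-voxel nuisance parameter. The absolute value reflects magnitude
reconstruction of inversion-recovery data. The model assumes an ideal
inversion pulse, mono-exponential relaxation per axon and negligible
intra-/extra-axonal exchange over the measurement — reasonable for
myelinated white matter, invalid in grey matter, CSF or demyelinating
lesions.

Two acquisition presets ship with the package: `protocol_preset("t1t2-9pt")`,
nine (TE, TI) combinations at TR = 5000 ms, and
`protocol_preset("t2-4te")`, four echo times (73–150 ms) at TR = 4100 ms,
both at b = 6000 s/mm² with 48 directions.

## Fitting

`fit_t1t2()` and `fit_t2()` minimise the unweighted residual sum of
squares under box constraints $0 \le K$, $40 \le T_{2a} \le 2000$ ms,
$300 \le T_{1a} \le 5000$ ms (bracketing myelin-water and CSF times)
with a bounded quasi-Newton (L-BFGS-B) search. Numerical choices that
matter:

* **Objective weighting.** Residuals are unweighted: after Rician bias
  attenuation the noise on spherical means is approximately
  homoscedastic across (TE, TI) blocks.
* **Multi-start.** The magnitude inversion-recovery factor is non-smooth
  at the null point and creates local minima, so the joint fit runs a
  fixed 3×3 grid of starts (T2a ∈ {60, 100, 150} ms × T1a ∈ {500, 800,
  1200} ms, K at the signal maximum) and keeps the lowest-residual
  solution. The grid is deterministic — no RNG anywhere in fitting — and
  makes noiseless round trips accurate to ≤ 0.1 % over a wide parameter
  grid (verified in the test suite).
* **Convergence.** Objective tolerance 1e-10, at most 500 iterations per
  start. The T2-only fit is initialised from the log-linear regression
  of log-signal on TE and polished with the same bounded search; on
  noiseless data the two coincide.
* **Degenerate voxels.** All-zero signals, parameters at bounds and
  nonpositive log-init inputs return *flagged* fits rather than errors,
  so voxelwise maps stay total; ROI aggregation drops flagged voxels.

Preprocessing implemented here is deliberately minimal: shell extraction
(default tolerance 100 s/mm²), elementwise Rician bias attenuation
$\sqrt{\max(m^2-\sigma^2, 0)}$ with a user-supplied noise level, and the
spherical mean. b = 0 volumes are never used in the spherical mean —
$K$ is fitted directly, avoiding division noise. Denoising,
distortion/motion correction and registration belong to upstream tools
and are out of scope; grids must already match. The quadrature
correction is one published reading of magnitude-bias attenuation and is
kept as a named, swappable step; at spherical-mean SNR ≥ 20 its residual
bias is below 2 %.

## Effective radius

A voxel holds a distribution of radii, not one radius. Each axon
contributes spins in proportion to its cross-section ($r_i^2$), and the
surface term enters the exponent as $1/r_i$. Writing the voxel signal as
the $r^2$-weighted mixture of mono-exponentials and expanding to first
order in $2\,TE\,\rho/r_i$ shows that a single-time fit reports

$$r_{\mathrm{eff}} \approx \frac{\langle r^2\rangle}{\langle r\rangle},$$

implemented by `effective_radius()`. This moment ratio is only mildly
tail-weighted — unlike the $(\langle r^6\rangle/\langle
r^2\rangle)^{1/4}$ form of purely diffusion-based estimators — which is
why relaxation-based radii can track histology below the diffusion
resolution limit. The expansion is accurate while
$\max_i 2\,TE\,\rho/r_i \lesssim 0.5$; the test suite verifies sub-5 %
agreement inside that regime and that the error grows monotonically as
the condition is violated. With per-ROI summaries instead of full radius
lists, $\langle r^2\rangle$ is recovered from the mean axon area
assuming circular cross-sections.

## Calibration

$T_c$ and $\rho$ cannot be estimated per voxel, so they are calibrated
against histology: `calibrate()` regresses $y = 1/T$ (inverse ROI-mean
relaxation time) on $x = 2/r_{\mathrm{eff}}$ and reads off $\rho$ as the
slope and $T_c$ as the inverse intercept. Choices made here:

* ROI relaxation times are arithmetic means of voxel times, and the
  inverse of that mean enters the regression; averaging rates instead is
  available via `aggregate = "rate"` but off by default.
* The regressor is $2/r$; using $1/r$ would simply halve the reported
  $\rho$ and leave every prediction unchanged if applied consistently.
* A nonpositive intercept (nonpositive cytoplasmic time) is an error; a
  negative slope is warned about and clamped to $\rho = 0$.
* No shrinkage correction is applied to histological radii by default;
  `read_histology()` accepts a scalar shrinkage factor.
* $T_c$ is treated as radius-independent. If the cytoplasmic time in
  fact varies linearly with radius, the same linear form holds with
  reinterpreted coefficients, so the calibration remains usable for
  prediction even then — only the physical reading of the parameters
  changes.
* In validation regressions the predicted radius is the response and the
  histological radius the regressor; with `n = 2` calibration points the
  slope p-value is undefined and reported as `NA`. Raw p-values are
  reported throughout (a `bonferroni()` helper exists for stringent
  summaries).

## What the synthetic generator emulates — and what it does not

`sample_radii()`, `mixture_signal_t2()`/`mixture_signal_t1()` and
`make_phantom_dwi()` simulate voxels as $r^2$-weighted mixtures of
mono-exponential decays under the surface model, with Rician noise
applied per direction volume. Defaults encode the study conditions the
package targets: gamma-distributed radii (shape 3, scale 0.2 µm; mean
0.6 µm, right-skewed like corpus-callosum histology), b = 6000 s/mm²
with 48 directions, the two protocol presets above, and phantom SNR
defined as $K/\sigma$. Phantom ROI layouts for the end-to-end
experiments use narrower gamma distributions (shape 16) whose means span
0.55–1.15 µm, keeping the mixtures near the first-order regime the model
itself assumes — matching the condition value (< 0.5) observed in the
targeted acquisitions.

Phantom signals are direction-independent by construction (the model is
fitted to spherical means), so the simulator does not probe orientation
dispersion, orientation-susceptibility effects, isotropically-restricted
compartments (cell nuclei, vacuoles), exchange, or non-mono-exponential
relaxation. Passing phantom tests therefore demonstrates correctness of
the estimation chain under the model's own assumptions — not robustness
to those real-data confounds, which the package deliberately does not
model.

Problem sizes were chosen to keep experiments comfortable on a laptop:
the end-to-end phantom uses a 16×16×2 grid (352 fitted voxels), 11 ROIs
of 2000 axons each, and SNR 50; the forward/inverse round-trip property
is checked on a 5×5×5 parameter grid. All generator entry points take a
mandatory seed, and every stage of the pipeline is deterministic given
one.

## Worked example

```{r phantom, eval = FALSE}
params_t2 <- surface_params("T2", Tc = 126.97, rho = 0.00116)
prot <- protocol_preset("t2-4te")
rois <- phantom_rois(c(16, 16, 2), 11)
mu <- seq(0.55, 1.15, length.out = 11)
specs <- setNames(lapply(mu, function(m)
  list(n = 2000, family = "gamma", shape = 16, scale = m / 16)),
  names(rois))

ph <- make_phantom_dwi(rois, specs, params_t2, protocol = prot,
                       K = 500, sigma = 10, seed = 1)
fits <- run_fit(ph$blocks, prot, mask = Reduce(`|`, rois),
                model = "t2", sigma = 10)
times <- roi_mean_times(fits, rois)
res <- run_calibrate_predict(times, ph$truth[c("roi", "r_eff_um")],
                             calib_rois = c("roi1", "roi4", "roi8", "roi11"))
res$comparison  # predicted-vs-true slope ~ 1
```

The packaged corpus-callosum table and its comparison regressions are
available without any simulation:

```{r table1}
reproduce_table1()
```

## Known limitations

* The calibration transfers only to tissue with comparable axoplasmic
  composition and myelination; iron accumulation or demyelination break
  the model.
* Predicted radii are relative to the histological sample used for
  calibration (shrinkage, sampling density).
* A single relaxation time per voxel is fitted; broad radius
  distributions would require modelling a distribution of relaxation
  times.
* The estimated times can retain B0-orientation dependence; the
  midsagittal corpus callosum, where fibre orientation is nearly
  constant, is the validated use case.
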