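---
title: "Models and methods in gradmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gradmodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradmodes)
```

`gradmodes` analyzes how regional gray-matter atrophy relates to
brain-wide functional connectivity (FC) through a low-dimensional space of
activity gradients, and explains FC alterations with a coupled-oscillator
eigenmode model. This vignette is the package's own account of the models,
their assumptions, the tunable parameters, and the design choices made
where the design was genuinely open. Empirical claims here are limited to
what the test suite and `scripts/acceptance.R` themselves compute.

## Normative W-scores

Atrophy is quantified per region as a deviation from a covariate-adjusted
normative prediction. For region $r$ with normative OLS fit
$\hat v_r(x) = x^\top \hat\beta_r$ and residual standard deviation
$\hat\sigma_r$ (denominator $n - p - 1$),

$$W_{ir} = \frac{\hat v_r(x_i) - v_{ir}}{\hat\sigma_r}.$$

**Sign convention.** We store W atrophy-positive (prediction minus
observation), so tissue loss gives positive scores and the affected-region
rule "more than `min_patients` subjects with $W > 1.5$" reads naturally.
The opposite (observation-minus-prediction) convention is available via
the `convention` argument of `compute_w_scores()` and is recorded in the
output, because the two conventions coexist in the literature.

A fresh draw from the normative population should score near mean 0, SD 1.
With 500 held-out subjects and a 397-subject training model, the
*per-region* mean W has standard deviation
$\sqrt{1/500 + 1/397}\,\sigma \approx 0.067$: individual regions routinely
show |mean W| near 0.1 by sampling alone, so calibration is asserted in
aggregate — the pooled mean and SD, and the across-region averages of
|mean| and |SD − 1|, must sit within ±0.1.

## Scanner harmonization

Multi-scanner features are adjusted with a location–scale batch model:
per feature, an OLS fit with intercept, biological covariates, and
sum-to-zero batch contrasts; the batch location effect is removed,
residuals are rescaled so every batch has the pooled (df-weighted)
residual SD, and the covariate-predicted part is restored. This is the
non-empirical-Bayes estimator: deterministic, transparent, and adequate at
the feature counts used here; the EB shrinkage refinement used by ComBat
is deliberately out of scope. One pass is only approximately idempotent
when covariates correlate with batch, so the estimator iterates to its
fixed point (tolerance 1e-10), making repeated application exactly
neutral. The same transform applies to W-score vectors and to vectorized
covariance/FC features.

## Gradients and the FC identity

The gradient basis is the PCA of per-scan column-centered, temporally
concatenated regional timeseries from a reference cohort. Two choices
matter:

- **No per-region variance scaling** (covariance PCA): the loadings must
  preserve amplitude information, because the dominant unipolar gradient's
  temporal variance is interpreted as global signal amplitude.
- **Projection uses bare eigenvectors**; displayed weight maps are
  eigenvectors scaled by component SDs. Scores are therefore independent
  of the display convention. Component signs are fixed by making the
  largest-magnitude region weight positive. We do not alter eigenvector
  entries to force exact unipolarity — that would break orthonormality and
  the exactness guarantees below.

With all $R$ components retained, the gradient covariance $C$ reconstructs
the scan's FC exactly: the region covariance is $V C V^\top$ and its
correlation equals the direct Pearson FC to machine precision (an
algebraic identity, since $VV^\top = I$). Truncated bases give the
low-rank approximation carried by the retained gradients. Scan QC applies
two fixed-order rules: mean framewise displacement strictly above 0.55 mm,
then a PCA screen over vectorized FC matrices removing scans more than 1
SD above the mean on PC1 (PC1 oriented so its largest-magnitude score is
positive, putting outliers on the upper tail).

## PLSR structure–function components

`fit_plsr()` is a NIPALS PLS2 with Y-deflation: X (atrophy W-scores) is
centered but not variance-scaled — regional W-scores share units, and
scaling would dilute the interpretation of component 1 as overall mean
atrophy — while Y (FC edges) is centered only. Components maximize the
covariance of X- and Y-scores under deflation; explained X-variance and
in-sample score correlations are reported. Signs are fixed so S1
correlates positively with mean atrophy and later components put their
largest-|weight| region positive. The implementation is cross-checked in
the test suite against an independent PLS implementation (mixOmics) on a
planted cohort.

Out-of-sample function scores use ridge regression of training Y-scores
on edges, the penalty chosen on an inner 3-fold grid over
$10^{-2}\ldots10^4$ (the outer scheme is 4-fold); the reported statistic
is the per-fold correlation between held-out structure scores and
predicted function scores. Per-term attribution of a function component to
gradient variance/covariance features uses squared semi-partial
correlations computed as direct $R^2$ drops — numerically exact even in
the perfect-fit limit — with both raw and adjusted $R^2$ reported (under
the null the raw $R^2$ of a 21-predictor model at $n = 300$ is about
0.07 by construction; adjusted $R^2$ is the calibrated null quantity).

## The coupled-oscillator model and eigenmodes

Each gradient's acceleration is modeled as linear in all gradients' levels
and velocities: $G_g'' = \beta_{g,0} + \sum_h \beta_{G_h,g} G_h + \sum_h
\beta_{G_h',g} G_h'$, fitted by K independent OLS regressions with
derivatives from the standard central-difference stencil (one-sided at the
ends; `pracma::gradient`). The companion form $dY/dt = AY$ (states blocked
as positions then velocities) is eigendecomposed; conjugate pairs are
reduced to one representative with $\beta > 0$, modes are ordered by
ascending frequency, and $\beta$ converts to hertz as
$\beta / (2\pi\,\mathrm{TR})$. Real eigenvalues yield flagged
zero-frequency modes excluded from phase statistics. Near-defective
companion matrices (eigenvector condition number above 1e8, e.g. critical
damping) are rejected with diagnostics.

Per-gradient cumulative amplitude is $\sum_m \sqrt{(-a+b)^2 + (a+b)^2}$
over modes, where $a + ib$ is the gradient's complex eigenvector component
(position block); this equals $\sqrt2 \sum_m |a+ib|$. Pair angles are the
circular means of per-mode argument differences, weighted per mode by the
product of the two gradients' moduli, folded to a magnitude in
$(0°, 180°]$ — 90° means temporal orthogonality and the rotation direction
is not interpreted. Angle differences are invariant to the arbitrary
complex scale of each eigenvector.

**Estimation caveats, stated as measured.** Two biases are inherent to
fitting a second-order system to discretely sampled stationary data.
First, central differencing attenuates frequencies: a pure oscillation at
$\omega$ rad/sample is recovered near $\sin\omega$, a relative bias of
$\omega^2/6$ — about 1% at $\omega = 0.24$. Second, damping is
structurally underestimated: in a stationary process velocity and
acceleration are uncorrelated, and the central-difference stencil straddles
the forcing step, so the damping coefficient shrinks toward zero
regardless of forcing strength. The package's recovery checks therefore
use lightly damped systems (|α| ≤ 0.01/sample), frequencies at or below
0.24 rad/sample, and median estimates over replicate simulations.

**Simulation from modes.** `simulate_from_model()` reconstructs
trajectories analytically as $Y(t) = \mathrm{Re}(V e^{\Lambda t} k)$. The
default damping policy zeroes $\alpha$ (damped modes otherwise decay and
give degenerate long-horizon covariance); `"fitted"` keeps estimated
dampings for short-horizon reconstruction. Mode constants $k$ default to
unit weight per mode; `estimate_mode_weights()` instead sets $|k_m|$ to
the RMS modulus of the data's modal coordinates, which makes the simulated
gradient covariance mirror the empirical excitation of each mode —
recommended whenever simulated FC is compared with a subject's observed FC.

## The synthetic cohort generator

The generator defines the study conditions under which every pipeline
stage is validated. It emulates: three planted atrophy components
(unit-norm, component 1 unipolar = overall mean atrophy, components 2–3
bipolar), per-subject component scores (patients
$s_1 \sim N(0.8, 1.2^2)$, $s_2 \sim N(0, 1)$, $s_3 \sim N(0, 0.8^2)$,
so component 1 dominates; cognitively normal subjects have exactly zero
scores and sit at the center of the spectrum), atrophy maps
$8 \sum_k s_{ik} p_k + N(0, 0.1^2)$ per region (the factor 8 carries the
W-score units so severely affected subjects peak near W ≈ 3 while the
scores stay on the unit scale that parameterizes the oscillator links), a
two-scanner batch structure with location/scale effects, BOLD rendered
through a known orthonormal basis with Gaussian regional noise, and noisy
linear/quadratic cognition.

**Base dynamics.** K = 6 oscillators with natural frequencies
0.15–0.30 rad/sample (0.012–0.024 Hz at TR = 2 s, inside the task-free
band), damping 0.06/sample, and antisymmetric velocity ("gyroscopic")
coupling 0.04 between all pairs. The gyroscopic coupling serves two
purposes: it makes every gradient participate in every mode (so pair
angles are defined with nonzero weight), and it is what makes per-subject
eigenmode features identifiable from fitted models — in weakly mixed
systems the cross-participations are so small that estimated angles are
near-chance. Exact per-step integration uses the matrix exponential of
the companion matrix with Gaussian forcing injected into the velocity
block (no Euler instability; noise-free trajectories match analytic
solutions to machine precision; forced runs discard a 200-sample burn-in).

**Angle planting.** There is no closed-form map from coupling parameters
to the measured weighted circular-mean angle, so targets are hit
numerically: symmetric stiffness between a pair is swept on a grid
(stability-checked; the usable range is the maximal monotone stretch
around zero), giving an invertible calibration curve from stiffness to
measured angle. The gradient 1–4 baseline is calibrated to 90°
(orthogonality at zero atrophy). For gradient pair 1–2 the achievable
range under strong mixing tops out near 80°, so its baseline sits at the
midpoint of its achievable range and the bidirectional s2/s3 link
(±10°/unit) operates around that value. Planting both pairs perturbs each
other's angle by up to ~5°, within the ±10° realization tolerance the
links promise; jitter or targeted stiffness that destabilizes a subject's
system is shrunk geometrically until stable.

**Links.** Higher overall atrophy ($s_1$) multiplies gradient 1's forcing
amplitude by $e^{-0.35 s_1}$ and lowers the 1–4 angle target by 15°/unit;
$s_3$ raises gradient 2's amplitude ($e^{0.25 s_3}$) and, with $s_2$,
shifts the 1–2 angle in opposite directions. Lognormal amplitude jitter
(SD 0.2) and stiffness jitter (SD 0.08·$\omega_i\omega_j$) on all pairs
give every amplitude and angle idiosyncratic variation, which is what the
amplitude/angle ↔ variance/covariance correspondence analysis consumes.

**What the generator does not emulate:** voxel-level structure,
hemodynamic convolution, scanner-specific temporal artifacts,
autocorrelated physiological noise, non-stationary dynamics, and
nonlinear or state-dependent coupling. Passing tests demonstrate that the
pipeline recovers the planted structure under these idealized conditions;
they do not certify behavior under real-data violations of linearity or
stationarity.

## Brain–behavior models

Cognition is regressed on standardized S1–S3 and F1–F3 with cubic
regression-spline terms capped at basis dimension 3, plus strictly linear
covariates; tests with fewer than 120 non-missing responses are skipped.
By default the spline basis is *unpenalized* (fixed df), so each term's F
statistic is an exact linear-model test: in 400-replicate null
simulations at $n = 300$ the penalized variants (GCV or REML) showed
per-term type-I rates near 0.06, while the fixed-df test is calibrated at
0.05 — and with only 2 df per smooth there is little to gain from
penalization. Penalized smooths remain available via `penalized = TRUE`.
With `basis_dim = 1` the model reduces exactly to OLS. FDR control is
Benjamini–Hochberg at $q = 0.05$ over the pooled (test × brain-term)
family, with NA p-values excluded and flagged.

## Problem sizes and numerical choices

Validation runs use desk-scale conditions chosen once: 40–60 regions, 6
gradients, 150–200 patients plus normals, 400–1500 timepoints per scan
(8000 for system-identification recovery, where long series are needed to
pin frequencies within 2%), 4-fold outer / 3-fold inner cross-validation,
and 200-replicate calibration experiments. Exact identities are asserted
at 1e-10; iterative fixed points at 1e-10 relative; eigenvector condition
numbers above 1e8 are treated as defective. All generators are pure
functions of (configuration, seed): the RNG state is saved and restored
around every draw, and child seeds are derived arithmetically below
$2^{31}$.

## Known limitations

- Damping estimates from stationary data shrink toward zero (see above);
  fitted $\alpha$ values should be read as qualitative.
- The angle calibration is model-specific: curves must be recomputed for a
  new base model, and strongly coupled pairs have bounded achievable
  ranges.
- The location–scale harmonization does not pool information across
  features (no empirical-Bayes shrinkage), so it is not recommended for
  very small batches.
- PLSR component order follows covariance with Y; on cohorts with
  near-equal planted effects the order can permute, which is why
  recovery checks match components before scoring.
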