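---
title: "Separating timing and amplitude variation in repeated movement curves"
author: "warpmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating timing and amplitude variation in repeated movement curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpmix)
```

## The model

Repeated recordings of the same movement differ in two qualitatively
different ways: *when* things happen (timing, or phase) and *how large*
they are (amplitude). Treating one as the other biases every downstream
summary — a pointwise mean across misaligned curves smears out peaks, and
aligning curves under a white-noise model overfits the warps. `warpmix`
implements a hierarchical nonlinear mixed-effects model that estimates the
separation of timing and amplitude variation by maximum likelihood, so the
trade-off between "warp more" and "absorb more amplitude variation" is
resolved by the data rather than by preprocessing.

The observed signal of participant $i$, repetition $j$, at times
$t_k \in [0,1]$, is modelled as

$$ y_{ij}(t) = (\theta + \varphi_i)\circ(\nu_i + v_{ij})(t)
   + x_{ij}(t) + \varepsilon_{ij}(t), $$

where

* $\theta = \Phi c$ is a common template in a cubic B-spline basis with
  $K$ equidistant knots on $[0,1]$ (boundaries included, giving $K + 2$
  basis functions);
* $\varphi_i = \Phi d_i$ is participant $i$'s systematic deviation, with
  $\sum_i d_i = 0$ and a ridge penalty $\eta\|d_i\|^2$,
  $\eta = \lambda/(1+\tau^2)$, that is normalized by the amplitude
  variance so one $\lambda$ transfers across conditions;
* $\nu_i$ is a participant-specific fixed time warp: an increasing
  piecewise-linear homeomorphism of $[0,1]$ parametrized by its values at
  $n_w$ equidistant anchor points;
* $v_{ij}(t) = t + E_{ij}(t)$ is a repetition-specific random warp, with
  $E_{ij}$ the linear interpolation of $n_w$ anchor deviations
  $w_{ij} \sim N(0, \sigma^2\gamma^2 C)$, $C$ the Brownian-bridge
  covariance $C(t,t') = t(1-t')$ for $t \le t'$ — pinned at both
  endpoints, so timing varies most mid-movement;
* $x_{ij}$ is serially correlated amplitude variation, a stationary
  Gaussian process with Matérn covariance (smoothness $\mu$, relative
  scale $\tau^2$, inverse range $\alpha$) indexed by *observed* time;
* $\varepsilon_{ij}$ is white observation noise with variance $\sigma^2$.

All random-effect covariances are scaled by $\sigma^2$, which lets the
noise variance be profiled out of the likelihood in closed form.

### Maximum likelihood on three levels

Joint likelihood estimation is intractable, so estimation alternates over
three views of the same model:

1. **Fixed-warp level.** With all warps held fixed, the model is linear
   mixed, and $c$ and $d_i$ have closed-form generalized-least-squares
   and ridge-GLS updates with per-curve weight matrices $(I + S_{ij})^{-1}$
   (`estimate_template()`, `estimate_deviations()`).
2. **Nonlinear level.** With templates fixed, the fixed warps $\nu_i$ are
   estimated and the random warps $w_{ij}$ predicted jointly from the
   posterior criterion
   $\sum_j \|y_{ij} - (\hat\theta + \hat\varphi_i)\circ(\nu_i + v_{ij})\|^2_{I+S_{ij}}
   + \sum_j \|w_{ij}\|^2_C$ (`warp_posterior()`, `predict_warps()`),
   restricted to valid homeomorphisms.
3. **Linearized level.** The model is linearized in $w$ around the current
   predictions; the resulting linear mixed model has an explicit marginal
   likelihood $m\log\sigma^2 + \log\det V + \sigma^{-2}\|y - \vartheta +
   Zw^0\|^2_V$ with $V = S + Z(I \otimes C)Z^\top + I$, which is a
   Laplace-type approximation of the true marginal likelihood and is
   minimized over the variance parameters (`linearize_model()`,
   `linearized_nll()`, `estimate_variances()`).

`fit_warping_model()` wires these together: initialize templates under
identity warps; inner iterations alternate warp prediction and template
updates (breaking early when no anchor moves by more than `warp_tol`,
default $10^{-4}$); outer iterations re-estimate
$(\sigma^2, \tau^2, \alpha, \gamma^2)$ and re-derive
$\eta = \lambda/(1+\tau^2)$ from the updated $\tau^2$. The Matérn
smoothness $\mu$ is a grid hyperparameter, never optimized continuously.

## Numerical choices

* **Warp family and barrier.** Both $\nu_i$ and $w_{ij}$ live on the same
  $n_w$ equidistant anchors. Monotonicity is enforced by rejection (an
  inadmissible proposal scores $+\infty$; the optimizer's line search
  backtracks), not by reparametrization, which keeps the Gaussian prior on
  $w$ interpretable. With the fitted anchor scales the truncation effect
  of the rejection is negligible.
* **Optimizer.** Per participant, $(\nu_i, \{w_{ij}\})$ are optimized
  jointly by BFGS with analytic gradients assembled from the hat-function
  weights of the anchors and the analytic spline derivative of the
  template. The identity warp is used as a second start in the first inner
  pass of each outer iteration; later passes warm-start from the previous
  iterate. Inside the optimizer the template is evaluated through its
  exact piecewise-cubic Taylor representation, which avoids repeated
  basis-matrix construction.
* **Clamping.** Warped times are clamped to $[0,1]$ before basis
  evaluation; valid homeomorphisms cannot leave the interval, so clamping
  only guards floating-point rounding.
* **Block structure.** $S$, $V$ and all solves are handled per curve with
  triangular (Cholesky) factorizations; the full $m \times m$ covariance
  is only ever formed inside test oracles. Curves observed on identical
  grids share one Matérn block and one factorization.
* **Matérn convention.** We use
  $\tau^2\, 2^{1-\mu}/\Gamma(\mu)\,(\alpha d)^\mu K_\mu(\alpha d)$ — the
  plain $\alpha d$ convention, so at $\mu = 1/2$ the covariance is
  $\tau^2 e^{-\alpha d}$ and $1/\alpha$ is the e-folding range. Smoothness
  values tuned under the $\sqrt{2\mu}$ convention do not transfer.
* **Amplitude index.** $S$ is evaluated at observed-time lags (the
  amplitude process rides on the recording, not on warped time).
* **Centering of deviations.** The per-participant ridge estimators do not
  themselves enforce $\sum_i d_i = 0$; after each pass the mean deviation
  is subtracted and absorbed into the template, which leaves all fitted
  values unchanged.
* **Identifiability of** $\nu_i$. No additional constraint (such as
  mean-identity across participants) is imposed on the fixed warps; a
  common timing shift is therefore absorbed by the $\nu_i$ rather than
  split off into a global warp. This matches the per-participant role the
  fixed warps play in classification.
* **Degenerate settings.** `n_w = 0` disables warping entirely and the
  model reduces to a linear mixed model whose "linearized" likelihood is
  exact — this limit is tested against a dense mixed-model oracle.

## Classification and cross-validation

`classify_participant()` implements posterior-distance (timing and motion
separation) classification: for each candidate participant the posterior
criterion is minimized over the *test repetition's* warp anchors only,
with the candidate's fixed warp $\hat\nu_i$ frozen — a participant's
timing habit is a trait learned from training data, so the test sample
does not get to re-estimate it. Ties break to the lowest participant id.
`chronological_cv_folds()` builds the chronological folds (fold 1 tests
the earliest repetitions, and so on), reflecting how such experiments
accumulate data over a session, and `classification_cv()` runs the full
fit-and-classify pipeline per fold. A deliberately naive unwarped
nearest-template baseline (`classify_nearest_template()`) is included for
comparisons: it wins when participants differ mainly in mean timing, and
loses badly when large repetition-level timing variation smears the
pointwise mean templates — which is exactly the regime the warping model
is built for.

## The factor model for aligned paths

After alignment, each repetition's spatial path is summarized as 30
equidistant points (in warped time) in three Cartesian coordinates
(`resample_path()`: a least-squares cubic spline with 10 equidistant
knots per coordinate, evaluated on the warped-time grid). For paths
recorded at three obstacle heights, `fit_factor_model()` fits

$$ y_{ijh} = \theta + \Big(X_h\beta + \sum_{l=1}^{3} Z_{i,g_l(j,h),l}\Big)
   W^\top + \varepsilon_{ij}, $$

with $\theta$ fixed at the pointwise mean path of the reference (lowest)
height, orthonormal loadings $W \in \mathbb{R}^{90\times q}$, a height
design $X_h$ (ANOVA coding $(0,0), (1,0), (0,1)$, or a one-parameter
regression in height increase $0, 7.5, 15$ cm), and three nested Gaussian
random-effect levels — participant, participant-by-height reaction, and
repetition — each with a $q \times q$ covariance. Noise has one variance
per spatial coordinate ("per dimension" is read as per coordinate, the
natural interpretation for tracking error); trajectories are vectorized
time-major with the coordinate index fastest.

Fitting is ECM: the E-step computes joint posterior moments of all latent
level effects per participant (through the latent-space precision, so the
$90 n_c$-dimensional marginal covariance is never formed); the CM-steps
update $\beta$, the level covariances, $\Lambda$, and $W$, in that order,
each in closed form given the posterior moments. $\beta$ is a pure fixed
effect (it receives no latent treatment). $\theta$ is not re-estimated
inside ECM — it is the stated reference. SQUAREM squared extrapolation
accelerates the fixed-point iteration, with safeguards: extrapolated
covariance candidates are projected back to the PSD cone, and a candidate
whose likelihood falls below the plain double-ECM step is rejected in
favor of that step, so the accepted log-likelihood trace is nondecreasing.
Convergence is declared when the relative log-likelihood change across
cycle boundaries falls below `tol` (default $10^{-9}$, at most 500 ECM map
applications).

**Identification.** $W$ is only determined up to invertible
transformations, so `identify_loadings()` (applied automatically after
fitting) first orthonormalizes $W$ symmetrically — an already-orthonormal
$W$ is left exactly unchanged, making the map idempotent — and then
rotates so that the *total* latent covariance
$\sum_l \Sigma_l$ is diagonal with decreasing diagonal; ties in the
eigenvalues are resolved deterministically by the eigensolver and by
fixing each column's sign so its largest-magnitude entry is positive.
$\beta$ and the $\Sigma_l$ are co-transformed, leaving the likelihood
unchanged to numerical precision.

`lrt_height_design()` compares the two height designs by a likelihood
ratio referred to $\chi^2_q$ (the designs differ by $q$ mean parameters).
Because both fits are local optimizations, the ANOVA model is restarted
from the converged regression solution — which it nests exactly — and
(with `restarts = TRUE`) the regression model from the projected ANOVA
solution, so the statistic is nonnegative up to tolerance and neither
model receives more optimization effort. `level_ellipsoids()` reports the
marginal 3-D covariance $W_t \Sigma_l W_t^\top$ of one random-effect
level at one path point with coverage radii from the $\chi^2_3$ quantile,
and `variance_explained()` decomposes the total fitted variance per
loading (covariate-driven plus summed level variances) with the remainder
attributed to noise.

## What the simulators emulate

`simulate_curves()` draws from the generative warping model exactly:
spline template (default a smooth double bump, stored as basis weights so
GLS can represent the truth exactly), centered participant deviations,
participant fixed-warp anchors jittered around the identity, Brownian-
bridge repetition anchors redrawn on the rare monotonicity violation,
exact Matérn amplitude draws via covariance factorization, and white
noise. Defaults mirror a single experimental condition of a desk-scale
movement study: 10 participants, 10 repetitions, 50 time points,
$\sigma^2 = 10^{-4}$, $\tau^2 = 1$, $\alpha = 5$, $\mu = 1$,
$\gamma^2 = 0.25$, $n_w = 2$, on data rescaled to unit value span — i.e.
a noise floor of 1% of the signal span, amplitude variation of the same
order, and timing jitter of a fraction of a percent of movement duration.
Participant-level timing spread (`nu_sd = 0.02`, about 2% of movement
duration) and template deviations (`phi_sd = 0.05` on the coefficient
scale) are chosen as what a movement scientist would call clear but not
dominant individual differences. `simulate_trajectories()` draws from the
factor model with the stated nesting and returns every latent draw.

What the simulators deliberately do *not* emulate: marker dropout
patterns, non-Gaussian or heteroscedastic noise, physiologically
constrained kinematics, or model misspecification of any kind. Passing
recovery tests on these data therefore demonstrates the correctness of
the estimation machinery under the model's own assumptions, not
robustness on real recordings.

## Study sizes used in the validation suite

The test-suite simulation studies run at sizes chosen to exercise the
relevant asymptotics on a single CPU:

* Parameter recovery: 20 replicates of the default 10 participants × 10
  repetitions × 50 points, fitted with `i_max = 8`, `j_max = 5` and a
  50-iteration cap per warp optimization — settings at which the
  alternation has visibly settled on this design (the default
  `i_max = j_max = 5` is kept for interactive use, where a few percent of
  residual drift in the variance parameters is immaterial).
* Factor subspace recovery: 20 replicates of 10 × 10 × 3 heights at
  $q = 3$.
* Likelihood-ratio null calibration: 200 replicates at 50 participants ×
  3 repetitions × 3 heights, $q = 3$. The participant count matters: in
  our null simulations the empirical 5%-level rejection rate was about
  17% with 4 participants, 11% with 12, 9% with 20 and 7% with 30–40 —
  the fixed-effect LRT in a mixed model is anti-conservative when the
  number of groups is small (the loading matrix and level covariances
  are high-dimensional nuisance parameters), a caveat that applies
  equally to applied use on few-participant datasets, where a
  small-sample correction or a parametric bootstrap would be advisable.
* The variance-share recovery check spreads the latent variance across
  levels in proportion to how many groups inform each level, so that all
  three covariance estimates contribute comparable Monte-Carlo error.

## Known limitations

* The alternating scheme maximizes a Laplace-type approximation, not the
  exact marginal likelihood; its quality is second order in the warp
  nonlinearity and is verified against adaptive quadrature on a one-anchor
  model at high signal-to-noise.
* The Matérn pair $(\tau^2, \alpha)$ is weakly identified on a bounded
  interval (only their microergodic combination is well determined at
  fixed $\mu$); expect slow, ridge-shaped convergence of these two
  parameters, and prefer fixing $\mu$ on a small grid.
* Monotonicity by rejection means the implied prior on warps is a
  truncated Gaussian; at realistic anchor scales the truncation mass is
  negligible, but with very large $\gamma^2$ and many anchors the warp
  optimizer will spend most of its time at the barrier.
* The factor model's LRT relies on first-order asymptotics; see the
  calibration caveat above.
* Missing values are handled by dropping masked points curve-wise; there
  is no imputation.
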