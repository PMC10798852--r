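---
title: "Methods: canonical-correlation coding subspaces and CC1 decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical-correlation coding subspaces and CC1 decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cc1decode)
```

## The model

The analytic track works with a dual-population Gaussian stimulus-response
model: an upstream population $X$ ($m$ neurons, e.g. LGN or olfactory bulb)
and a cortical population $Y$ ($n$ neurons, e.g. V1 or piriform cortex)
respond to two stimuli $A$ and $B$. Responses are multivariate Gaussian with
stimulus-independent covariance $\Sigma_A = \Sigma_B = \Sigma$; centering on
the stimulus-$A$ mean leaves 11 free parameters in the $2\times2$ case: the
stimulus-$B$ means $\mu_{X1}, \mu_{X2}, \mu_{Y1}, \mu_{Y2}$, per-neuron SDs
$\sigma$, and three uniform correlation parameters — within-$X$ ($c_x$),
within-$Y$ ($c_y$), and a single cross-population noise correlation $c_{xy}$
shared by every cross pair. `assemble_covariance()` builds
$\Sigma = \Lambda C \Lambda$ with $\Lambda = \mathrm{diag}(\sigma)$.

Assumptions worth stating plainly: equal covariance across stimuli, equal
priors (both data styles use equal trial counts per stimulus; the
`prior_b = 0.5` default reflects that), Gaussian noise, and uniform
correlation structure. Real spike counts are approximately Poisson with
stimulus-dependent variance; the empirical track makes none of these
assumptions, which is exactly why both tracks exist.

### Positive definiteness

Random parameter sets can produce an invalid $\Sigma$.
`check_positive_definite()` uses a spectral test (smallest eigenvalue
$> 10^{-10}$), and the sampler redraws the entire 11-parameter set on
failure. For the $2\times2$ case with uniform correlations the exact
boundary is $c_{xy} < \sqrt{(1+c_x)(1+c_y)}/2$ (derived from the block
eigenstructure of the correlation matrix, and verified against the spectral
test on a $12^3$ grid in the test suite). We deliberately use the spectral
test rather than any closed-form inequality: it is unambiguous, generalizes
to arbitrary $m, n$, and is cheap at these sizes. Since
$\Lambda C \Lambda \succ 0 \iff C \succ 0$ when all $\sigma_i > 0$,
rejection touches only the correlation triple; the $\mu$ and $\sigma$
marginals of accepted draws are exactly the sampling laws (the test suite
KS-tests them), while the correlation marginals are mildly truncated
(roughly a quarter of raw draws are rejected).

### Survey distributions

`sample_model_parameters()` draws $\sigma \sim |N(0,2)|$ (folded normal),
$\mu_{X1},\mu_{Y1} \sim N(0,1)$, $\mu_{X2},\mu_{Y2} \sim |N(0,1)|$,
$c_x, c_y \sim U(0,1)$, and $c_{xy} = \max(\tilde c - 0.01, 0)$ with
$\tilde c \sim U(0,1)$, giving $c_{xy}$ an atom of mass $\approx 1\%$ at
exactly zero. These are the survey conditions; the full survey uses 50,000
draws (`run_sweep()`'s default), while tests and examples use 300–5,000,
which is ample for every qualitative and sign-level property checked.

## Decoding

For a linear readout $w$ (stored unit-norm — accuracy is invariant to
positive rescaling), the equal-prior two-Gaussian problem projected onto
$w$ has best-threshold (midpoint) accuracy
$\Phi\!\left(|w^\top\mu| / (2\sqrt{w^\top \Sigma w})\right)$
(`analytic_accuracy()`), maximized over $w$ by the Fisher direction
$\Sigma^{-1}\mu$ (`fisher_direction()`), giving
$D_\mathrm{opt} = \Phi(\sqrt{\mu^\top\Sigma^{-1}\mu}/2)$.

Empirically (`empirical_accuracy()`), responses projected to 1D are
classified by the best threshold: candidates are midpoints between
consecutive distinct sorted values plus the two extremes — midpoints
realize every achievable classification — and both class orientations are
tried, so reported accuracy is always $\ge 0.5$ and a multiple of
$1/T_\mathrm{total}$. Accuracy ties across thresholds are broken toward the
largest margin (half-gap to the nearest point), a stability choice under
noise; ties across angles in the 2D search go to the smallest angle, for
determinism.

`brute_force_optimal_2d()` scans 200 projection angles in steps of
$\pi/200$, the resolution appropriate for Poisson-scale spike counts. One
documented limitation: for populations with extreme per-neuron SD ratios
(order 100:1, which the folded-normal survey occasionally produces) the
true optimum can fall *between* grid points and no on-grid direction
attains it; the suite therefore validates the search against the best
on-grid direction under the noise-free analytic accuracy. For $k > 2$
neurons, exhaustive search is impossible and `optimal_accuracy_nd()`
reports an explicit *lower bound*: the best pairwise brute-force accuracy
(the bound used when growing $3\times3$/$4\times4$ populations from
qualifying pairs) improved by the sample-LDA direction with ridge
$10^{-6}\,\mathrm{tr}(S_w)/k$. It is flagged as a bound, never as a
certified optimum.

## CCA, two ways

`analytic_cca()` solves
$\Sigma_{xx}^{-1}\Sigma_{xy}\Sigma_{yy}^{-1}\Sigma_{yx}v = \rho^2 v$ on a
model covariance; the test suite checks its $\rho$ against the singular
values of $\Sigma_{xx}^{-1/2}\Sigma_{xy}\Sigma_{yy}^{-1/2}$, an independent
route. `sample_cca()` works on centered trial matrices through QR
factorizations and an SVD of $Q_x^\top Q_y$ — no explicit covariance
inverses — which stays stable when the trial count is comparable to the
neuron count; it matches `stats::cancor()` to $10^{-10}$ on well-posed
inputs and ridge-stabilizes (ridge $10^{-8}$, with a warning) when a neuron
is constant. Components are sign-fixed (first nonzero weight positive, per
region); since CCA determines paired signs only jointly, the summary
statistic $R_\mathrm{CC1}$ is reported as $|r|$.

CCA is always fitted on trials pooled across the two stimuli being decoded
(the stimulus-*unconditioned* covariance
$\Sigma + p(1-p)\mu\mu^\top$ in the analytic track). For the analytic track
this is forced by the theory; for the empirical track it is the natural
counterpart and is what makes the method unsupervised — per-stimulus
centering would smuggle in labels. This pooling convention is an
implementation decision we apply uniformly.

Why CC1 is exactly optimal at $c_{xy}=0$: the cross-block of the
unconditioned covariance reduces to $p(1-p)\mu_X\mu_Y^\top$, a rank-one
signal term, and by the Sherman–Morrison structure the leading canonical
direction in each region becomes proportional to that region's
$\Sigma^{-1}\mu$ — the Fisher direction. The suite verifies this to
$\sin\theta < 10^{-8}$ and $\Delta < 10^{-8}$ (the tolerance appropriate to
double-precision eigensolvers).

## Summary statistics and regression

$C_{xy}$ (`noise_correlation_cxy()`) subtracts each neuron's per-stimulus
mean and averages the Pearson correlation over all cross-region pairs on
pooled trials — by construction invariant to stimulus-locked mean shifts,
so signal cannot leak into the noise estimate. The decoding error is
normalized as $\Delta = (D_\mathrm{opt} - D_\mathrm{CC1}) /
(D_\mathrm{opt} - 0.5)$ with $\Delta = 0$ when $D_\mathrm{opt} = 0.5$:
chance is the natural zero of accuracy, so $\Delta$ reads as "fraction of
the achievable headroom lost". An unnormalized variant
(`normalize = FALSE`) exists for sensitivity checks; all trend and
regression sign conclusions in the suite are stable under both.

`gls_regression()` fits $\Delta = \beta_1 C_{xy} + \beta_2 R_\mathrm{CC1} +
\varepsilon$ with *no intercept* (the headline model; an intercept variant
sits behind a flag). With no specified heteroscedasticity structure the
default weighting is identity — equivalent to OLS, which the suite verifies
against the closed-form normal equations — and a `weights` argument
provides the hook for heteroscedastic structure when one is known. Trend
curves (`binned_trend()`) are centered moving averages of points sorted by
the abscissa, truncated at the ends; the default window of 500 points suits
surveys of thousands of records and is configurable. Cutoff presets
(`cutoff_presets()`): analytic $R_\mathrm{CC1} > 0.75$, $C_{xy} < 0.1$;
visual $R > 0.3$, $C < 0.06$; olfactory $R > 0.4$, $C < 0.1$; all strict
inequalities.

## The synthetic session generator

`generate_session()` emulates what matters for testing the pipeline:
two simultaneously recorded regions at realistic sizes (presets: 27/48
neurons with 6 stimuli × 15 trials, olfactory-style; 61/245 with a
6-orientation × 5-frequency grid × 42 trials, visual-style), 250 ms
spike-count responses, stimulus-tuned rates, and separately controllable
within- and cross-region shared noise. Per trial, each neuron's log firing
rate is baseline + tuning(stimulus) + shared-latent loading $\times z_t$ +
local-latent loading $\times u_t$; counts are Poisson at that rate over the
window. The log-linear link keeps rates positive and makes loadings compose
additively; log-rates are clipped to $[-10, 6]$ as an overflow guard.
Upstream tuning is rank-one across stimuli (a 1D signal axis); cortical
tuning mixes that axis with independent tuning in proportion
`signal_coupling` : 1 − `signal_coupling`, so a 1D signal genuinely
propagates between regions — which is what lets tests assert that CC2
decoding of such data sits at chance. A single scalar cross-region latent
is the default "noise channel"; per-neuron loading vectors allow
heterogeneous (including sparse) noise coupling.

What the generator does *not* emulate: temporal structure within the
window, refractoriness, stimulus-dependent variance beyond what the
log-link induces, behavioral covariates, and electrode-style neuron
dropout. Passing tests on synthetic sessions therefore demonstrate that the
pipeline recovers planted signal/noise structure under Poisson variability
and realistic trial counts — not that any particular real dataset meets the
theory's conditions.

Generator defaults are fixed study conditions, chosen once: baseline 10
spikes/s (a typical cortical rate; 2.5 expected counts per 250 ms window),
tuning strength 0.8–1 in log-rate units (moderate, clearly suprathreshold
tuning), local noise loadings 0.2–0.3 (trial-to-trial variability of the
size seen in awake recordings), preset signal coupling 0.7.

## Numerical choices, degenerate inputs, problem sizes

* PD tolerance $10^{-10}$; "exactly optimal" means $\Delta < 10^{-8}$.
* Constant neurons: excluded before population sampling; a constant neuron
  inside an evaluated population flags the record `degenerate`, which
  summaries drop.
* Accuracies below 0.5 never occur: orientation flipping folds them.
* Cross-validation (`crossvalidate_cc1()`) stratifies folds by stimulus and
  refits the CCA directions, the projection centering, *and* the decision
  threshold on training folds only.
* Test problem sizes: sweeps of 300–5,000 configurations, sessions of
  12–40 neurons per region with 42 trials per stimulus, 100–500 sampled
  populations, Monte-Carlo oracles at $10^4$–$10^6$ draws. These sizes were
  chosen so each property is measured with comfortable statistical margin;
  the full-survey defaults (50,000 draws, 10,000 populations, 200 upstream
  redraws × top-50) remain the function defaults.

## Known limitations

* The $k>2$ "optimal" is a lower bound; reported comparisons for
  $3\times3$/$4\times4$ populations inherit that.
* The $\pi/200$ grid under-resolves optimal directions for extreme
  per-neuron variance ratios (see above).
* The GLS hook defaults to identity weighting; substantive
  heteroscedasticity modeling is the caller's responsibility.
* In-sample $D_\mathrm{CC1}$ is optimistic at small trial counts — that is
  why `crossvalidate_cc1()` exists; the suite quantifies the optimism and
  checks that label-shuffled data cross-validate to chance.
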