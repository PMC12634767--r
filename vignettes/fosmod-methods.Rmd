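---
title: "Pointwise function-on-scalar regression with moderated variances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pointwise function-on-scalar regression with moderated variances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosmod)
```

## The problem

Cyclic neck flexion-extension produces, for each person, three kinematic
curves on a normalized cycle time $s \in [0,1]$: the angle (deg), angular
velocity (deg/s) and angular acceleration (deg/s²). The scientific question
is which *portions* of these curves are associated with scalar subject
characteristics — a disability score (NDI, 0–50), age, neck length and sex —
rather than whether a single scalar summary (range of motion, peak velocity)
is. Keeping the curves whole preserves the temporal structure of the
movement; the price is a multiple-testing problem across time and unstable
variance estimates at each single time point. This package implements the
full inferential chain and a synthetic generator with known ground truth to
validate it.

## The pointwise model

At each grid time $t_k$, $k = 1,\dots,K$ (default $K = 100$, equally spaced
on $[0,1]$ inclusive of both endpoints so the landmarks $0, 0.5, 1$ are
addressable exactly),

$$Y_i(t_k) = x_i^\top \beta(t_k) + \varepsilon_i(t_k), \qquad
\varepsilon_i(t_k) \overset{iid}{\sim} N(0, \sigma^2(t_k)),$$

with $x_i = (1, \mathrm{ndi}_i, \mathrm{age}_i, \mathrm{neck}_i,
\mathrm{sex}_i)$ shared across all times. `fit_pointwise()` solves the $K$
least-squares problems through one QR decomposition of the common design
(`build_design()`); the rank-revealing solve matters because age, neck
length and sex are correlated in realistic samples. Coefficients are the
OLS estimates $\hat\beta(t_k)$ and the variance estimate is the unbiased
$s^2(t_k) = \mathrm{RSS}(t_k)/(n-p)$ with $d = n - p$ degrees of freedom.
Ordinary inference is the usual two-sided $t$ test,
$T_j(t_k) = \hat\beta_j(t_k)/(s(t_k)\sqrt{v_{jj}})$ with $v_{jj}$ the
$j$-th diagonal entry of $(X^\top X)^{-1}$.

Covariates enter on their raw scales; an optional centering flag exists for
numerical hygiene and provably leaves every $t$ and $p$ unchanged (this is
asserted in the tests). The intercept is always estimated but excluded from
the p-value functions: the scientific questions concern the predictors.

A modelling fidelity note: samples of this kind often contain repeated
measurements per subject (e.g. before/after a treatment session). The
pointwise model treats errors as independent across observations and we
implement it exactly as stated — no random effects. This is a deliberate
fidelity choice, documented rather than "fixed", and a known limitation.

## Empirical Bayes variance moderation

With $n$ a few dozen and $K$ a hundred, each $s^2(t_k)$ is noisy while the
collection $\{s^2(t_1),\dots,s^2(t_K)\}$ is highly informative. The
moderation layer assumes a scaled-inverse-chi-square prior on the error
variance,

$$\frac{1}{\sigma^2(t_k)} \sim \frac{1}{d_0 s_0^2}\,\chi^2_{d_0},$$

under which the posterior-mean variance is the *squeezed*

$$\tilde s^2(t_k) = \frac{d_0 s_0^2 + d\, s^2(t_k)}{d_0 + d},$$

a convex combination with weight $d/(d_0+d)$ on the data
(`squeeze_variances()`). The moderated statistic
$\tilde T_j(t_k) = \hat\beta_j(t_k)/(\tilde s(t_k)\sqrt{v_{jj}})$ is, under
the null, $t$-distributed with $d + d_0$ degrees of freedom — the extra
$d_0$ degrees of freedom are the payoff for borrowing strength across time
points. Moderation touches only variances: $\hat\beta$ and every effect
curve are bitwise identical with and without it (asserted in the tests).

Note the statistic divides by $\tilde s \sqrt{v_{jj}}$, the *square root*
of the squeezed variance; this is the form that reduces exactly to the
ordinary $t$ when $d_0 = 0$, a reduction property the tests pin down to
1e-12.

### Hyperparameter estimation

$(d_0, s_0^2)$ are estimated once per fitted response model by moment
matching on $z_k = \log s^2(t_k)$ (`estimate_hyperparameters()`): with
$e = \bar z$ and $v = \widehat{\mathrm{Var}}(z)$,

$$\psi'(d_0/2) = v - \psi'(d/2), \qquad
s_0^2 = \exp\!\big(e - \psi(d/2) + \log(d/2) + \psi(d_0/2) - \log(d_0/2)\big),$$

where $\psi, \psi'$ are the digamma and trigamma functions. The trigamma
equation is inverted by a Newton iteration (`trigamma_inverse()`, start
$x = 0.5 + 1/y$, relative tolerance 1e-8, at most 50 iterations; the
iteration is monotone on this convex problem and converges in a handful of
steps). When $v \le \psi'(d/2)$ the observed spread of the log-variances is
no larger than sampling noise alone explains; the prior is then degenerate
and we set $d_0 = +\infty$ explicitly (not capped at a large number), with
$\tilde s^2 \equiv s_0^2$ and the standard normal as the null law
downstream. Non-positive $s^2$ values (possible with degenerate synthetic
data) are excluded from estimation with a warning and squeezed normally.

Hyperparameters are estimated per response model (angle, velocity,
acceleration separately), never pooled across responses: the three
responses live on variance scales three orders of magnitude apart. Our
implementation of the estimator agrees with an independent implementation
of the same moment-matching scheme to machine precision (cross-checked in
the test suite), and recovers known $(d_0, s_0^2)$ from data simulated
under the prior to a few percent at $K = 2000$, $d = 50$.

No robustified or trend variant of the estimator is provided; that is a
documented extension point, not an oversight.

## FDR adjustment of p-value functions

Each coefficient's raw p-value function $p_j(\cdot)$ is adjusted across
the $K$ times of that coefficient only — never pooled across coefficients
or responses. This per-family scope is the single most consequential
scoping choice in the chain and is locked by a regression test: pooling
families would let a strong NDI effect buy significance for neck-length
times (or vice versa), which is not the question being asked.

Two step-up adjustments are always computed (`adjust_bh()`, `adjust_by()`,
thin validated wrappers over `stats::p.adjust`): Benjamini–Hochberg, exact
under independence, and Benjamini–Yekutieli, whose harmonic-sum penalty
$c(K) = \sum_{i=1}^K 1/i$ remains valid under the strong positive
dependence that adjacent time points necessarily exhibit. BY is therefore
the theoretically safer choice here, at a substantial power cost; the
defaults display BH, and both are stored in every result table. Significance
regions (`significant_regions()`) are maximal runs of consecutive grid
times with adjusted $p \le \alpha$ (default 0.05), snapped to grid points —
no sub-grid interpolation of the crossing, since the analysis is
grid-resolution anyway.

### Grid-resolution stability

Fitting the same smooth curves at $K = 100$ and $K = 1000$ changes the raw
p-value functions by only ~1e-3 sup-norm in our simulations: the fits are
pointwise, so refining the grid adds tests without changing any existing
one. The step-up *adjustment*, however, depends on the family size $K$
through its $K/\mathrm{rank}$ factor, so adjusted functions computed at
family sizes 100 and 1000 can differ by several hundredths in mid-range
p-values regardless of implementation. The stability test therefore
compares (a) raw functions across resolutions and (b) BH adjustments at
matched family size — the fine fit's raw function evaluated at the 100
coarse times, then adjusted over those 100 values. Both agree within 0.02
sup-norm, with the raw agreement near 1e-3. The cross-family-size BH
difference is also computed and reported by the acceptance script, without
a pass threshold, as an intrinsic property of step-up adjustment rather
than of this implementation.

## Effect curves

`predict_effect_curves()` evaluates $x(v)^\top \hat\beta(t)$ at a base
covariate profile (typically `mean_profile()`, with sex entering as the
sample proportion) while one covariate takes a series of levels. By
linearity, curves at two levels differ by exactly
$(v_1 - v_2)\hat\beta_j(t)$, and the prediction at the covariate-mean
profile equals the pointwise mean of the observed curves — both asserted at
1e-10 in the tests. A significance mask from the varied coefficient's
adjusted p-value function (default: moderated, BH, $\alpha = 0.05$) drives
the shading in `plot_effect_curves()`. Display levels default to the sample
range of the varied covariate in four steps and are configuration, not
science. Confidence bands for effect curves are out of scope.

## Preprocessing raw recordings

Raw input is one continuous angle signal per observation. The chain is:

1. **Cycle segmentation** (`segment_cycles()`): cycles are delimited
   minimum-to-minimum (maximum flexion as the boundary), using local minima
   with prominence of at least 20% of the recording's angle range by
   default. The prominence filter rejects jitter minima without any
   smoothing of the signal.
2. **Edge discard** (`discard_edge_cycles()`): the first and last cycles
   contain movement onset and stopping transients and are dropped; at
   least three detected cycles are required so at least one survives.
3. **Time normalization** (`normalize_cycle()`): each cycle is
   interpolated by a cubic spline and resampled at the grid mapped
   linearly onto the cycle's time span.
4. **Averaging** (`average_cycles()`): the pointwise mean of the retained
   normalized cycles is the observation's curve.
5. **Differentiation** (`differentiate_curves()`): velocity and
   acceleration come from the analytic derivative of the spline
   representation, divided by the observation's mean cycle duration
   (chain rule $d/dt = (1/T)\, d/ds$), so units advance deg → deg/s →
   deg/s². Finite differences on 100 points would amplify noise;
   acceleration needs a twice-differentiable representation.

Splines use Forsythe–Malcolm–Moler (FMM) end conditions rather than
natural ones: a natural spline forces zero second derivative at the
segment ends, but min-to-min segmentation places the ends exactly at
curvature maxima (peak flexion), so natural end conditions would introduce
an $O(h^2)$ boundary error that visibly corrupts acceleration at the
movement extremes. With FMM ends, resampling a densely sampled harmonic
cycle is accurate to better than 1e-6 and the velocity of $A\sin(2\pi s)$
over duration $T$ is recovered within 0.1% of $2\pi A/T$ at $K = 100$.

Two points the data cannot settle are fixed by choice and documented:
time normalization is per cycle (not over the whole record), and
derivatives may be taken per cycle before averaging or on the averaged
curve — for splines on a common grid the two commute exactly, so the
default (differentiate the averaged curve) is a convenience, not a
modelling decision.

## The synthetic generator

`simulate_study()` draws data from *exactly* the model the inference
assumes, so every pipeline stage faces a correctly specified problem with
known truth. Defaults are fixed once to emulate a realistic non-specific
neck-pain cohort and are not tuning knobs:

| quantity | default | units | why |
|---|---|---|---|
| n | 55 | observations | typical cohort size at which moderation matters |
| K | 100 | grid points | default analysis resolution |
| NDI | mean 10.11, sd 4.76 | 0–50 score | mild-to-moderate disability, integer-rounded, truncated to scale |
| age | mean 34.67, sd 12.45 | years | truncated positive |
| neck length | mean 14.98, sd 1.81 | cm | truncated positive |
| sex | Bernoulli(0.364) | 1 = male | female-majority cohort; female is the reference level 0 |
| amplitude | 52.1 | deg | mean-curve range of motion ≈ 104 deg |
| duration | 3.7 | s | template range of velocity ≈ 177 deg/s |
| variance prior | $d_0 = 4$, $s_0^2 = 64$ | deg² | heavy-tailed heterogeneity, residual sd ≈ 8 deg |

The cycle template is $w(s) = -\cos(2\pi s)$ (flexion → extension →
flexion, range 2), so the intercept function is $52.1\,w(s)$. True
predictor effects are configured per coefficient: null, constant,
proportional to the template (a covariate that scales movement amplitude),
or a raised-cosine bump
$a\,\tfrac12(1 + \cos(2\pi (s - c)/w))$ on a window — the shape used by
the power and FDR simulations (window $[0.35, 0.65]$, 30% of the grid).
All defaults are null: the default study is a calibration object, and
effect scenarios are explicit configurations.

Two noise modes exist. The default draws $\sigma^2(t_k)$ independently
from the prior and then iid Gaussian errors — the exact moderation model,
ideal for calibration checks but nowhere differentiable. The `smooth`
mode draws each observation's error curve from a finite Fourier basis
(8 harmonics, $1/m^2$ weights), modulated by a deterministic smooth
variance envelope $1 + 0.6\cos(4\pi s)$ that peaks at the movement
extremes, where kinematic variability is genuinely largest. Smooth noise
is the mode to use when curves will be differentiated or fitted at several
grid resolutions: the random draws do not depend on $K$, so one seed
defines the same curves on any grid.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: subject-specific phase variability (cycles are
phase-locked; registration is assumed upstream), correlation between
covariates (men have longer necks in real cohorts; a hook exists for
injecting this in robustness experiments), repeated-measures dependence
between observations from the same subject, and harmonic content beyond
the pure-cosine template. The last point means the template's range of
acceleration (~300 deg/s² at the default amplitude and duration)
underestimates observed cohorts, whose sharper movement reversals add
higher harmonics; the angle and velocity scales are matched, acceleration
is conservative.

## Problem sizes and numerical tolerances

The validation suite uses problem sizes chosen to make each check sharp at
desk scale: 100 random instances ($n \le 30$, $p \le 5$, $K \le 20$) for
the OLS-vs-normal-equations oracle at 1e-8; 20 replicates of $K = 2000$
variance draws for hyperparameter recovery (median relative error under
10%); 10⁴ pooled p-values for null uniformity (Kolmogorov–Smirnov
$p > 0.01$); 200 replicates for realized FDR of BH at $\alpha = 0.05$
(mean ≤ 0.07 with the effect covering 30% of the grid, BY below BH); and
20 replicates for effect-window recovery (Jaccard ≥ 0.5 at a peak effect
of 2 deg per NDI unit, about 2.4 residual sd at the covariate scale). The
exact reduction, ordering, linearity and bit-reproducibility properties
are asserted at 1e-10 to 1e-15 — they are identities, not approximations.

## Known limitations

- Pointwise inference only: no basis expansion, no penalization, no
  interval-wise or cluster-based functional testing.
- Independence across observations is assumed; repeated measures are not
  modelled.
- The coefficient-prior layer of the moderation framework (point mass at
  zero plus Gaussian slab, posterior odds) is intentionally not
  implemented; only variance moderation is used.
- Bonferroni is intentionally absent: with $K = 100$ strongly dependent
  tests it is far too conservative to be useful here.
- Cycle segmentation assumes reasonably prominent minima; pathological
  recordings (drift exceeding the movement range) need upstream detrending.
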