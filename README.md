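# fosmod

Function-on-scalar regression with empirical Bayes variance moderation,
for cyclic kinematic curves.

## What this is for

In movement analysis, each observation is a whole curve: the neck
flexion-extension angle (and its velocity and acceleration) over one
normalized movement cycle. The question is *where along the cycle* scalar
subject characteristics — a disability score (NDI), age, neck length, sex —
are associated with the movement, not just whether a scalar summary like
range of motion is. `fosmod` implements the full inferential chain for
this setting:

1. **Pointwise regression.** At every grid time $t_k$ the same linear
   model is fitted:
   $Y_i(t_k) = x_i^\top \beta(t_k) + \varepsilon_i(t_k)$,
   $\varepsilon_i(t_k) \sim N(0, \sigma^2(t_k))$, giving coefficient
   functions $\hat\beta_j(t)$ and residual variances $s^2(t_k)$ on
   $d = n - p$ degrees of freedom.
2. **Variance moderation.** A scaled-inverse-chi-square prior
   $1/\sigma^2(t_k) \sim \chi^2_{d_0} / (d_0 s_0^2)$, with $(d_0, s_0^2)$
   estimated from the spread of the $K$ log-variances by moment matching,
   yields the squeezed variance
   $\tilde s^2(t_k) = (d_0 s_0^2 + d\,s^2(t_k)) / (d_0 + d)$ and the
   moderated statistic
   $\tilde T_j(t_k) = \hat\beta_j(t_k) / (\tilde s(t_k) \sqrt{v_{jj}})$,
   $t$-distributed with $d + d_0$ df under the null — pooling information
   across time points exactly as moderated statistics pool across genes in
   omics.
3. **FDR-adjusted p-value functions.** Each coefficient's K raw p-values
   are adjusted by Benjamini-Hochberg and Benjamini-Yekutieli step-up
   corrections (per coefficient, per method, per response — never pooled),
   and maximal significant time regions are extracted at a chosen FDR
   level.
4. **Effect curves.** Predicted mean curves at fixed covariate profiles
   (vary NDI or age, hold the rest at sample means), with significance
   shading.

Supporting modules preprocess raw cyclic recordings (cycle segmentation by
prominent minima, edge-cycle discard, spline time normalization, cycle
averaging, spline differentiation to velocity/acceleration) and generate
synthetic studies with known ground truth for calibration, power and FDR
experiments.

## Worked example

```r
library(fosmod)

# a synthetic study: 55 subjects, 100 grid points, a true NDI effect of
# 2 deg per NDI unit on the middle 30% of the cycle, all else null
cfg <- generator_config(
  n = 55, K = 100, seed = 42,
  effects = list(ndi = effect_bump(2, center = 0.5, width = 0.3),
                 age = effect_null(), neck_length = effect_null(),
                 sex = effect_null()))
study <- simulate_study(cfg)

analysis <- fos_pipeline(study$curves, study$covariates)
analysis
#> fos_analysis: angle response, n = 55 , p = 5 , K = 100
#>   moderation: d0 = 3.822 , s0^2 = 65.52
#>   significant regions ( BH , alpha = 0.05 ):
#>      ndi.ols : 3 region(s)
#>      age.ols : 0 region(s)
#>      neck_length.ols : 0 region(s)
#>      sex.ols : 0 region(s)
#>      ndi.moderated : 2 region(s)
#>      age.moderated : 0 region(s)
#>      neck_length.moderated : 0 region(s)
#>      sex.moderated : 0 region(s)

analysis$regions[["ndi.moderated"]]
#>     t_start     t_end k_start k_end
#> 1 0.4040404 0.4040404      41    41
#> 2 0.4242424 0.5858586      43    59
```

Reading this: the estimated prior has $d_0 = 3.8$ extra degrees of freedom
and scale $s_0^2 = 65.5\ \mathrm{deg}^2$ (the generator's truth is 4 and
64). Only the NDI coefficient has BH-significant regions at FDR 0.05, and
the detected moderated region essentially covers the true effect window
$[0.35, 0.65]$; the three null predictors are clean. Moderation changes
variances only — `analysis$fit$beta` is identical with and without it.

## The analysis workflow

Numbered scripts under `analysis/` run the whole study on a simulated
dataset, writing tables and figures under `results/`:

```sh
Rscript analysis/01_simulate.R                  # synthetic study -> CSVs
Rscript analysis/02_fit.R                       # fits + moderation per response
Rscript analysis/03_significance.R              # p-value functions, regions, plots
Rscript analysis/04_effects.R                   # effect curves for NDI and age
Rscript analysis/05_operating_characteristics.R # calibration, FDR, power
```

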