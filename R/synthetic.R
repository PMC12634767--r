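#' Effect specifications for the synthetic generator
#'
#' True coefficient functions beta_j(t) for the generator: identically
#' zero (`effect_null`), constant (`effect_constant`), a smooth
#' raised-cosine bump supported on a window (`effect_bump`), or
#' proportional to the cycle waveform template (`effect_template`,
#' modelling a covariate that scales movement amplitude).
#'
#' @param value constant effect value (response units per covariate unit).
#' @param amplitude bump peak value, reached at `center`.
#' @param center bump center on normalized time.
#' @param width full bump width; the support `[center - width/2,
#'   center + width/2]` must lie inside \[0, 1\].
#' @param slope template scaling (response units per covariate unit).
#' @return a list describing the effect, of class `"effect_spec"`.
#' @name effect_spec
NULL

#' @rdname effect_spec
#' @export
effect_null <- function() structure(list(type = "null"), class = "effect_spec")

#' @rdname effect_spec
#' @export
effect_constant <- function(value)
  structure(list(type = "constant", value = value), class = "effect_spec")

#' @rdname effect_spec
#' @export
effect_bump <- function(amplitude, center = 0.5, width = 0.3) {
  if (center - width / 2 < 0 || center + width / 2 > 1)
    stop("bump window [", center - width / 2, ", ", center + width / 2,
         "] outside [0, 1]")
  structure(list(type = "bump", amplitude = amplitude, center = center,
                 width = width), class = "effect_spec")
}

#' @rdname effect_spec
#' @export
effect_template <- function(slope)
  structure(list(type = "template", slope = slope), class = "effect_spec")

eval_effect <- function(spec, tt, template) {
  switch(spec$type,
         null = rep(0, length(tt)),
         constant = rep(spec$value, length(tt)),
         bump = {
           u <- (tt - spec$center) / spec$width
           ifelse(abs(u) <= 0.5,
                  spec$amplitude * 0.5 * (1 + cos(2 * pi * u)), 0)
         },
         template = spec$slope * template,
         stop("unknown effect type: ", spec$type))
}

#' Synthetic-study generator configuration
#'
#' Defaults emulate the observed study conditions: n = 55 observations,
#' K = 100 grid points; covariate distributions with NDI mean 10.11
#' (sd 4.76, integer-rounded, truncated to the 0-50 scale), age 34.67
#' (12.45) years, neck length 14.98 (1.81) cm, sex Bernoulli(0.364) for
#' male; a flexion-extension cycle template of amplitude 52.1 deg (mean
#' range of motion 104.2 deg) and cycle duration 3.7 s (range of velocity
#' of the template about 177 deg/s); residual noise with a
#' scaled-inverse-chi-square variance prior d0 = 4, s0^2 = 64 (prior
#' residual sd 8 deg).  All predictor effects default to null.
#'
#' @param n number of observations.
#' @param K grid size.
#' @param seed integer seed used by every simulation entry point.
#' @param covariates list with elements `ndi`, `age`, `neck_length` (each
#'   `c(mean, sd)`) and `sex_p` (probability of male).
#' @param effects named list of [effect_spec] objects for `ndi`, `age`,
#'   `neck_length`, `sex`.
#' @param variance list `list(d0 = , s02 = )` for the variance prior, or
#'   `list(profile = )` giving a fixed length-K sigma^2(t) profile.  For
#'   smooth noise an optional `envelope` entry (default 0.6, in \[0, 1))
#'   sets the amplitude of the deterministic smooth variance modulation
#'   `1 + envelope * cos(4 pi t)`, which peaks at the movement extremes.
#' @param waveform list `list(amplitude = , duration = )`: cycle template
#'   amplitude (deg) and cycle duration (s).
#' @param noise `"iid"` (independent across time points, heteroscedastic
#'   via the variance field) or `"smooth"` (finite Fourier-basis Gaussian
#'   process, smooth in t, variance s02 at every t).
#' @param n_basis number of Fourier harmonics for smooth noise.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n = 55L, K = 100L, seed = 1L,
                             covariates = list(ndi = c(10.11, 4.76),
                                               age = c(34.67, 12.45),
                                               neck_length = c(14.98, 1.81),
                                               sex_p = 0.364),
                             effects = list(ndi = effect_null(),
                                            age = effect_null(),
                                            neck_length = effect_null(),
                                            sex = effect_null()),
                             variance = list(d0 = 4, s02 = 64),
                             waveform = list(amplitude = 52.1, duration = 3.7),
                             noise = c("iid", "smooth"),
                             n_basis = 8L) {
  noise <- match.arg(noise)
  n <- as.integer(n); K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  need <- c("ndi", "age", "neck_length", "sex")
  miss <- setdiff(need, names(effects))
  if (length(miss))
    stop("effect_spec missing for coefficient(s): ",
         paste(miss, collapse = ", "))
  if (is.null(variance$profile)) {
    if (variance$d0 <= 0 || variance$s02 <= 0)
      stop("variance prior needs d0 > 0 and s02 > 0")
  }
  structure(list(n = n, K = K, seed = as.integer(seed),
                 covariates = covariates, effects = effects[need],
                 variance = variance, waveform = waveform, noise = noise,
                 n_basis = as.integer(n_basis)),
            class = "generator_config")
}

# inverse-CDF truncated normal; degenerate sd gives the mean exactly
rtruncnorm_icdf <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

sim_covariates_ <- function(config) {
  cv <- config$covariates
  n <- config$n
  ndi <- round(rtruncnorm_icdf(n, cv$ndi[1L], cv$ndi[2L], 0, 50))
  age <- rtruncnorm_icdf(n, cv$age[1L], cv$age[2L], 0, Inf)
  neck <- rtruncnorm_icdf(n, cv$neck_length[1L], cv$neck_length[2L], 0, Inf)
  sex <- stats::rbinom(n, 1L, cv$sex_p)
  covariate_table(data.frame(id = sprintf("obs_%03d", seq_len(n)),
                             ndi = ndi, age = age, neck_length = neck,
                             sex = sex))
}

#' Simulate a covariate table
#'
#' Draws NDI (truncated normal on \[0, 50\], rounded to integers), age and
#' neck length (positive truncated normals) and sex (Bernoulli) from the
#' configured distributions, using the configured seed.
#'
#' @param config a [generator_config()].
#' @return a covariate table.
#' @export
simulate_covariates <- function(config) {
  set.seed(config$seed)
  sim_covariates_(config)
}

sim_variance_field_ <- function(config) {
  v <- config$variance
  if (!is.null(v$profile)) {
    prof <- rep_len(as.numeric(v$profile), config$K)
    if (any(prof < 0)) stop("fixed variance profile must be non-negative")
    return(prof)
  }
  v$d0 * v$s02 / stats::rchisq(config$K, df = v$d0)
}

#' Simulate the per-time error variance field
#'
#' Draws sigma^2(t_k) independently from the scaled-inverse-chi-square
#' prior: 1/sigma^2 ~ chi^2_d0 / (d0 s0^2), or returns the configured
#' fixed profile.
#'
#' @param config a [generator_config()].
#' @return numeric vector of K positive variances.
#' @export
simulate_variance_field <- function(config) {
  set.seed(config$seed)
  sim_variance_field_(config)
}

#' True coefficient functions on a grid
#'
#' The intercept row is the cycle template amplitude * w(t) with
#' w(t) = -cos(2 pi t): the observation starts and ends at maximum
#' flexion, peaks at mid-cycle, and spans a range of twice the amplitude.
#' Predictor rows follow their [effect_spec].
#'
#' @param config a [generator_config()].
#' @param grid a [time_grid()]; defaults to the config's K-point grid.
#' @return p x K matrix with rows `(Intercept)`, `ndi`, `age`,
#'   `neck_length`, `sex`.
#' @export
make_coefficient_functions <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- time_grid(config$K)
  tt <- as.numeric(grid)
  template <- -cos(2 * pi * tt)
  beta <- rbind(config$waveform$amplitude * template,
                t(vapply(config$effects,
                         function(sp) eval_effect(sp, tt, template),
                         numeric(length(tt)))))
  rownames(beta) <- c("(Intercept)", names(config$effects))
  beta
}

sim_noise_ <- function(config, tt, sigma2) {
  n <- config$n
  if (config$noise == "iid") {
    matrix(stats::rnorm(n * length(tt), sd = rep(sqrt(sigma2), each = n)),
           nrow = n)
  } else {
    # finite Fourier series with 1/m^2 harmonic weights, average variance
    # s02; a deterministic smooth envelope makes the error variance
    # time-varying (largest at the flexion/extension extremes) while the
    # random draws stay independent of the grid resolution
    M <- config$n_basis
    s02 <- if (!is.null(config$variance$s02)) config$variance$s02 else
      mean(sigma2)
    w <- (1 / (1:M)^2); w <- w / sum(w)
    a <- matrix(stats::rnorm(n * M), n, M)
    b <- matrix(stats::rnorm(n * M), n, M)
    eps <- matrix(0, n, length(tt))
    for (m in seq_len(M)) {
      sc <- sqrt(s02 * w[m])
      eps <- eps + sc * (a[, m] %o% cos(2 * pi * m * tt) +
                           b[, m] %o% sin(2 * pi * m * tt))
    }
    eps * rep(sqrt(smooth_variance_envelope(config, tt)), each = n)
  }
}

# relative variance profile of the smooth-noise option: mean 1 over the
# cycle, peaking at t = 0, 0.5, 1 (maximum flexion/extension)
smooth_variance_envelope <- function(config, tt) {
  amp <- config$variance$envelope
  if (is.null(amp)) amp <- 0.6
  if (amp < 0 || amp >= 1) stop("variance envelope amplitude must be in [0, 1)")
  1 + amp * cos(4 * pi * tt)
}

#' Simulate a complete synthetic study
#'
#' Draws covariates, the variance field and curve noise from the seeded
#' generator and composes the angle curves exactly as the pointwise model
#' assumes: y_i(t_k) = x_i' beta(t_k) + e_i(t_k) with independent
#' Gaussian errors of variance sigma^2(t_k).  Smooth noise replaces the
#' iid draw with a finite Fourier-basis Gaussian process whose draws do
#' not depend on the grid, so the same seed defines the same smooth
#' curves on any grid resolution.
#'
#' @param config a [generator_config()].
#' @param derivatives if `TRUE`, also return spline-differentiated
#'   velocity and acceleration curve sets (cycle duration from the
#'   waveform config).
#' @return list of class `"synthetic_study"`: `covariates`, `curves`
#'   (angle [curve_set()]), optional `velocity` and `acceleration`,
#'   `durations`, and `truth` (list with `beta`, `sigma2`, `grid`,
#'   `config`).
#' @export
simulate_study <- function(config, derivatives = FALSE) {
  p <- 1L + length(config$effects)
  if (config$n <= p)
    stop("n = ", config$n, " must exceed p = ", p)
  set.seed(config$seed)
  cov <- sim_covariates_(config)
  grid <- time_grid(config$K)
  tt <- as.numeric(grid)
  beta <- make_coefficient_functions(config, grid)
  sigma2 <- if (config$noise == "iid") sim_variance_field_(config) else {
    s02 <- if (!is.null(config$variance$s02)) config$variance$s02 else
      mean(sim_variance_field_(config))
    s02 * smooth_variance_envelope(config, tt)
  }
  X <- cbind(1, cov$ndi, cov$age, cov$neck_length, cov$sex)
  eps <- sim_noise_(config, tt, sigma2)
  Y <- X %*% beta + eps
  curves <- curve_set(Y, grid, "angle", ids = cov$id)
  durations <- stats::setNames(rep(config$waveform$duration, config$n),
                               cov$id)
  out <- list(covariates = cov, curves = curves, durations = durations,
              truth = list(beta = beta, sigma2 = sigma2, grid = grid,
                           config = config))
  if (derivatives) {
    out$velocity <- differentiate_curves(curves, durations)
    out$acceleration <- differentiate_curves(out$velocity, durations)
  }
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: n =", nrow(x$curves$values),
      ", K =", length(x$curves$grid),
      ", seed =", x$truth$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic study to CSV files
#'
#' Writes the angle curve matrix (and velocity/acceleration if present),
#' the covariate table, a long-format truth table (coefficient, time,
#' beta_true plus the sigma2_true field) and a key-value sidecar echoing
#' the scalar configuration, into `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(angle = file.path(dir, "curves_angle.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.txt"))
  write_curve_matrix(study$curves, files[["angle"]])
  for (resp in c("velocity", "acceleration")) {
    if (!is.null(study[[resp]])) {
      files[[resp]] <- file.path(dir, paste0("curves_", resp, ".csv"))
      write_curve_matrix(study[[resp]], files[[resp]])
    }
  }
  write_covariate_table(study$covariates, files[["covariates"]])
  tt <- as.numeric(study$truth$grid)
  truth <- do.call(rbind, lapply(rownames(study$truth$beta), function(cf) {
    data.frame(coefficient = cf, time = tt,
               beta_true = study$truth$beta[cf, ],
               sigma2_true = study$truth$sigma2)
  }))
  write_full_precision(truth, files[["truth"]])
  cfg <- study$truth$config
  writeLines(c(paste0("n=", cfg$n), paste0("K=", cfg$K),
               paste0("seed=", cfg$seed), paste0("noise=", cfg$noise),
               paste0("amplitude=", cfg$waveform$amplitude),
               paste0("duration=", cfg$waveform$duration)),
             files[["config"]])
  invisible(files)
}
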