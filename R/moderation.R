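#' Inverse of the trigamma function
#'
#' Solves psi'(x) = y for x > 0 by Newton iteration on the monotone
#' transform, started at x = 0.5 + 1/y.  Converges to a relative tolerance
#' of 1e-8 in a handful of iterations for any positive y.
#'
#' @param y positive numeric (vectorized).
#' @return numeric vector x with `trigamma(x) == y` to relative 1e-8.
#' @export
trigamma_inverse <- function(y) {
  if (any(!is.finite(y) | y <= 0))
    stop("trigamma_inverse needs positive finite input")
  x <- 0.5 + 1 / y
  for (iter in seq_len(50L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  x
}

#' Moderation hyperparameters
#'
#' The prior on the error precision is scaled chi-square:
#' 1/sigma^2(t_k) ~ chi^2_d0 / (d0 * s0^2).  `d0` is the prior degrees of
#' freedom (may be `Inf`, meaning all time points share the variance s0^2)
#' and `s02` the prior variance scale.
#'
#' @param d0 prior degrees of freedom, `>= 0` (0 is allowed as an explicit
#'   no-moderation limit; the estimator never returns 0) or `Inf`.
#' @param s02 prior variance scale, positive.
#' @return object of class `"moderation_params"`.
#' @export
moderation_params <- function(d0, s02) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0)
    stop("d0 must be a single non-negative number (possibly Inf)")
  if (!is.numeric(s02) || length(s02) != 1L || is.na(s02) || s02 <= 0)
    stop("s02 must be a single positive number")
  structure(list(d0 = as.numeric(d0), s02 = as.numeric(s02)),
            class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat("moderation_params: d0 =", x$d0, ", s0^2 =", x$s02, "\n")
  invisible(x)
}

#' Estimate the variance-prior hyperparameters from the fitted variances
#'
#' Moment matching on z_k = log s2(t_k).  Under the model, z has mean
#' log(sigma^2) + psi(d/2) - log(d/2) and, integrating the prior, variance
#' psi'(d/2) + psi'(d0/2).  With e = mean(z) and v = var(z):
#' psi'(d0/2) = v - psi'(d/2) is inverted by [trigamma_inverse()] to give
#' d0, and s0^2 = exp(e - psi(d/2) + log(d/2) + psi(d0/2) - log(d0/2)).
#' If v <= psi'(d/2) the log-variances show no more spread than sampling
#' alone explains and the prior is degenerate: d0 = Inf,
#' s0^2 = exp(e - psi(d/2) + log(d/2)).
#'
#' @param s2 numeric vector of K pointwise residual variances (K >= 2).
#' @param df residual degrees of freedom d of each fit.
#' @return a [moderation_params()] object.
#' @export
estimate_hyperparameters <- function(s2, df) {
  if (length(s2) < 2L) stop("need at least 2 variances to pool")
  if (df < 1L) stop("residual df must be >= 1")
  pos <- is.finite(s2) & s2 > 0
  if (sum(pos) < 2L)
    stop("need at least 2 strictly positive variances (got ", sum(pos), ")")
  if (!all(pos))
    warning(sum(!pos), " non-positive variance(s) excluded from ",
            "hyperparameter estimation")
  z <- log(s2[pos])
  e <- mean(z)
  v <- stats::var(z)
  gap <- v - trigamma(df / 2)
  if (gap <= 0) {
    d0 <- Inf
    s02 <- exp(e - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(gap)
    s02 <- exp(e - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  moderation_params(d0, s02)
}

#' Squeeze pointwise variances toward the prior scale
#'
#' Posterior-mean variance under the scaled-inverse-chi-square prior:
#' s2_tilde(t_k) = (d0 * s0^2 + d * s2(t_k)) / (d0 + d), a convex
#' combination of the observed and prior variances with weight d/(d0+d)
#' on the data.  d0 = Inf returns s0^2 everywhere; d0 = 0 returns s2
#' unchanged.
#'
#' @param s2 numeric vector of pointwise variances.
#' @param df residual degrees of freedom d.
#' @param params a [moderation_params()] object.
#' @return numeric vector of squeezed variances, same length as `s2`.
#' @export
squeeze_variances <- function(s2, df, params) {
  stopifnot(inherits(params, "moderation_params"))
  if (is.infinite(params$d0)) return(rep(params$s02, length(s2)))
  (params$d0 * params$s02 + df * s2) / (params$d0 + df)
}

#' Moderated t-statistics and p-values
#'
#' Replaces each pointwise variance by its squeezed value and recomputes
#' the t-statistics: t_mod(j, t_k) = beta(j, t_k) / (s_tilde(t_k) sqrt(v_jj)).
#' Under the null the moderated statistic is t-distributed with d + d0
#' degrees of freedom (standard normal when d0 = Inf); two-sided p-values
#' are taken from that law.  Coefficient estimates are untouched:
#' moderation only changes the variance estimate, never beta.
#'
#' @param fit a [fit_pointwise()] result.
#' @param params a [moderation_params()] object; if `NULL` (default) the
#'   hyperparameters are estimated from `fit$s2` via
#'   [estimate_hyperparameters()].
#' @return object of class `"fos_moderation"`: `params`, `s2_tilde` (K),
#'   `df_total` (d + d0), `t` and `p` (p x K matrices).
#' @export
moderated_inference <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "fos_fit"))
  if (is.null(params)) params <- estimate_hyperparameters(fit$s2, fit$design$residual_df)
  d <- fit$design$residual_df
  s2t <- squeeze_variances(fit$s2, d, params)
  se <- sqrt(outer(fit$design$v_diag, s2t))
  tmod <- fit$beta / se
  tmod[fit$beta == 0] <- 0
  df_total <- d + params$d0
  pmod <- if (is.infinite(df_total)) {
    2 * stats::pnorm(abs(tmod), lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(tmod), df = df_total, lower.tail = FALSE)
  }
  dimnames(tmod) <- dimnames(pmod) <- dimnames(fit$beta)
  structure(
    list(params = params, s2_tilde = s2t, df_total = df_total,
         t = tmod, p = pmod, grid = fit$grid, response = fit$response),
    class = "fos_moderation")
}

#' @export
print.fos_moderation <- function(x, ...) {
  cat("fos_moderation:", x$response, "response; d0 =", x$params$d0,
      ", s0^2 =", signif(x$params$s02, 4L),
      ", total df =", x$df_total, "\n")
  invisible(x)
}
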