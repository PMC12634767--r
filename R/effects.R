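#' Mean covariate profile
#'
#' The arithmetic mean of each covariate over the sample; for sex this is
#' the proportion coded 1 (male), so the "mean subject" is a population
#' average, matching the convention of effect plots that hold the other
#' covariates at their means.
#'
#' @param cov a covariate table (see [covariate_table()]).
#' @return named numeric vector (`ndi`, `age`, `neck_length`, `sex`) of
#'   class `"covariate_profile"`.
#' @export
mean_profile <- function(cov) {
  if (nrow(cov) == 0L) stop("empty covariate table")
  covariate_profile(ndi = mean(cov$ndi), age = mean(cov$age),
                    neck_length = mean(cov$neck_length), sex = mean(cov$sex))
}

#' Construct a covariate profile
#'
#' @param ndi Neck Disability Index value, 0-50.
#' @param age years, positive.
#' @param neck_length centimeters, positive.
#' @param sex 0 (female), 1 (male), or a proportion in between.
#' @return named numeric vector of class `"covariate_profile"`.
#' @export
covariate_profile <- function(ndi, age, neck_length, sex) {
  if (ndi < 0 || ndi > 50) stop("ndi must be on the 0-50 scale")
  if (age <= 0) stop("age must be positive")
  if (neck_length <= 0) stop("neck_length must be positive")
  if (sex < 0 || sex > 1) stop("sex must lie in [0, 1]")
  structure(c(ndi = ndi, age = age, neck_length = neck_length, sex = sex),
            class = "covariate_profile")
}

#' Predicted effect curves at varied covariate levels
#'
#' For each requested level v of the varied covariate, predicts the mean
#' response curve x(v)' beta_hat(t) at the base profile with the varied
#' covariate replaced by v.  By linearity of the pointwise model, curves
#' at two levels v1, v2 differ by exactly (v1 - v2) * beta_hat_varied(t).
#' An optional adjusted p-value function attaches a per-time significance
#' mask (shared by all levels, since significance concerns the varied
#' coefficient, not the level).
#'
#' @param fit a [fit_pointwise()] result whose design used the standard
#'   predictors.
#' @param varied name of the covariate to vary (must be a design
#'   coefficient other than the intercept).
#' @param levels numeric vector of values for the varied covariate.
#' @param base a [covariate_profile()] supplying the fixed values of the
#'   other covariates (e.g. [mean_profile()]).
#' @param p_adjusted optional numeric vector (length K) of adjusted
#'   p-values for the varied coefficient, used with `alpha` to flag
#'   significant times.
#' @param alpha significance threshold for the mask; default 0.05.
#' @return data.frame of class `"effect_curves"` with columns `level`,
#'   `time`, `predicted`, `significant`.
#' @export
predict_effect_curves <- function(fit, varied, levels, base,
                                  p_adjusted = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "fos_fit"))
  cn <- rownames(fit$beta)
  if (!varied %in% setdiff(cn, "(Intercept)"))
    stop("unknown or non-varied coefficient: ", varied)
  if (!length(levels)) stop("need at least one level")
  pred_names <- setdiff(cn, "(Intercept)")
  miss <- setdiff(pred_names, names(base))
  if (length(miss))
    stop("base profile is missing: ", paste(miss, collapse = ", "))
  tt <- as.numeric(fit$grid)
  sig <- if (is.null(p_adjusted)) rep(NA, length(tt)) else {
    if (length(p_adjusted) != length(tt))
      stop("p_adjusted must have one value per grid time")
    p_adjusted <= alpha
  }
  out <- lapply(levels, function(v) {
    x <- c(1, as.numeric(base[pred_names]))
    names(x) <- c("(Intercept)", pred_names)
    x[varied] <- v
    data.frame(level = v, time = tt,
               predicted = drop(x[cn] %*% fit$beta),
               significant = sig)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("effect_curves", "data.frame")
  out
}
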