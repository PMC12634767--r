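#' Benjamini-Hochberg step-up adjustment of a p-value function
#'
#' Adjusts the K p-values of one coefficient's p-value function so that
#' rejecting every time point with adjusted p <= alpha controls the false
#' discovery rate at alpha under independence.  Thin validated wrapper
#' around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Benjamini-Yekutieli adjustment of a p-value function
#'
#' As [adjust_bh()] but multiplied by the harmonic-sum factor
#' c(K) = sum_{i=1..K} 1/i, valid under arbitrary positive dependence —
#' relevant here because p-values at nearby times are strongly correlated.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
adjust_by <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BY")
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || !length(p)) stop("p must be a non-empty numeric vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  invisible(p)
}

#' Assemble adjusted p-value functions for every predictor
#'
#' For each non-intercept coefficient and each method (ordinary `"ols"`
#' and `"moderated"`), the raw p-value function is adjusted across the K
#' time points of that coefficient only — never pooled across coefficients
#' or responses.  This per-coefficient scope is the consequential choice:
#' each predictor's K pointwise tests form one multiple-testing family.
#'
#' @param fit a [fit_pointwise()] result.
#' @param mod optional [moderated_inference()] result for the same fit.
#' @return data.frame of class `"pvalue_functions"` with columns
#'   `coefficient`, `method`, `time`, `p_raw`, `p_bh`, `p_by`.
#' @export
assemble_pvalue_functions <- function(fit, mod = NULL) {
  stopifnot(inherits(fit, "fos_fit"))
  coefs <- setdiff(rownames(fit$p), "(Intercept)")
  K <- ncol(fit$p)
  tt <- as.numeric(fit$grid)
  one <- function(pv, coefficient, method) {
    data.frame(coefficient = coefficient, method = method, time = tt,
               p_raw = pv, p_bh = adjust_bh(pv), p_by = adjust_by(pv))
  }
  out <- lapply(coefs, function(cf) one(fit$p[cf, ], cf, "ols"))
  if (!is.null(mod)) {
    stopifnot(inherits(mod, "fos_moderation"))
    if (ncol(mod$p) != K || !identical(rownames(mod$p), rownames(fit$p)))
      stop("moderation result does not match the fit (shape mismatch)")
    out <- c(out, lapply(coefs, function(cf) one(mod$p[cf, ], cf, "moderated")))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("pvalue_functions", "data.frame")
  out
}

#' Extract significance regions from an adjusted p-value function
#'
#' Finds the maximal runs of consecutive grid times where the chosen
#' adjusted p-value is at or below `alpha`, reported as closed intervals
#' snapped to grid points.
#'
#' @param p_adj numeric vector of adjusted p-values along the grid.
#' @param grid the matching [time_grid()] (or numeric vector).
#' @param alpha FDR threshold, in (0, 1); default 0.05.
#' @return data.frame with columns `t_start`, `t_end`, `k_start`, `k_end`
#'   (grid indices), zero rows when nothing is significant.
#' @export
significant_regions <- function(p_adj, grid, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tt <- as.numeric(grid)
  if (length(p_adj) != length(tt))
    stop("p-value function and grid have different lengths")
  sig <- p_adj <= alpha
  if (!any(sig))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      k_start = integer(0), k_end = integer(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(t_start = tt[starts[keep]], t_end = tt[ends[keep]],
             k_start = starts[keep], k_end = ends[keep])
}

#' Long-format result table for one fitted response
#'
#' Combines the pointwise estimates and both inference methods into the
#' serializable long format: one row per (coefficient, time, method) with
#' `beta`, `se`, `t`, `p_raw`, `p_bh`, `p_by`.  The coefficient estimates
#' are identical for the two methods at the same (coefficient, time) —
#' moderation changes only variances.
#'
#' @param fit a [fit_pointwise()] result.
#' @param mod optional [moderated_inference()] result.
#' @return data.frame with columns `response`, `coefficient`, `time`,
#'   `method`, `beta`, `se`, `t`, `p_raw`, `p_bh`, `p_by`.
#' @export
result_table <- function(fit, mod = NULL) {
  pf <- assemble_pvalue_functions(fit, mod)
  tt <- as.numeric(fit$grid)
  kidx <- match(pf$time, tt)
  ji <- cbind(match(pf$coefficient, rownames(fit$beta)), kidx)
  pf$beta <- fit$beta[ji]
  d <- fit$design$residual_df
  se_ols <- fit$se[ji]
  if (!is.null(mod)) {
    se_mod <- sqrt(outer(fit$design$v_diag, mod$s2_tilde))[ji]
    pf$se <- ifelse(pf$method == "ols", se_ols, se_mod)
    pf$t <- ifelse(pf$method == "ols", fit$t[ji], mod$t[ji])
  } else {
    pf$se <- se_ols
    pf$t <- fit$t[ji]
  }
  out <- data.frame(response = fit$response,
                    coefficient = pf$coefficient, time = pf$time,
                    method = pf$method, beta = pf$beta, se = pf$se,
                    t = pf$t, p_raw = pf$p_raw, p_bh = pf$p_bh,
                    p_by = pf$p_by)
  rownames(out) <- NULL
  out
}
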