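#' Build the shared design matrix
#'
#' The function-on-scalar model fits the same scalar design at every time
#' point, so the design — including the diagonal of (X'X)^-1 that scales
#' every coefficient's standard error — is computed once.
#'
#' @param cov a covariate table (see [covariate_table()]).
#' @param predictors ordered character vector of covariate columns to use;
#'   default `c("ndi", "age", "neck_length", "sex")`.
#' @param center logical; if `TRUE`, numeric predictors are mean-centered.
#'   Centering changes the intercept's meaning only: coefficient t- and
#'   p-values for the predictors are unchanged.
#' @return object of class `"fos_design"` with elements `X` (n x p, first
#'   column the intercept), `coefficient_names`, `v_diag` (diagonal of
#'   (X'X)^-1), `residual_df` (n - p) and the QR decomposition `qr`.
#' @export
build_design <- function(cov, predictors = c("ndi", "age", "neck_length", "sex"),
                         center = FALSE) {
  miss <- setdiff(predictors, names(cov))
  if (length(miss))
    stop("predictor(s) not in covariate table: ", paste(miss, collapse = ", "))
  n <- nrow(cov)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(cov)[, predictors, drop = FALSE]))
  if (center && length(predictors))
    X[, -1L] <- scale(X[, -1L, drop = FALSE], center = TRUE, scale = FALSE)
  p <- ncol(X)
  if (n <= p)
    stop("n = ", n, " observations cannot identify p = ", p,
         " coefficients with a positive residual df")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  ord <- order(qx$pivot)
  xtx_inv <- xtx_inv[ord, ord, drop = FALSE]
  structure(
    list(X = X, coefficient_names = colnames(X),
         v_diag = stats::setNames(diag(xtx_inv), colnames(X)),
         residual_df = n - p, qr = qx, n = n, p = p),
    class = "fos_design")
}

#' @export
print.fos_design <- function(x, ...) {
  cat("fos_design: n =", x$n, ", p =", x$p,
      "(", paste(x$coefficient_names, collapse = ", "), "), residual df =",
      x$residual_df, "\n")
  invisible(x)
}

#' Pointwise least-squares fit of curves on scalar predictors
#'
#' Fits the linear model y_i(t_k) = x_i' beta(t_k) + e_i(t_k) independently
#' at every grid time t_k by QR least squares, with the unbiased residual
#' variance s2(t_k) on n - p degrees of freedom, and ordinary two-sided
#' t-tests per coefficient per time.
#'
#' @param cs a [curve_set()] with n rows matching the design.
#' @param design a [build_design()] result.
#' @return object of class `"fos_fit"`: `beta` (p x K), `s2` (K), `se`,
#'   `t`, `p` (each p x K), plus `design`, `grid`, `response`.
#' @export
fit_pointwise <- function(cs, design) {
  stopifnot(is_curve_set(cs), inherits(design, "fos_design"))
  Y <- cs$values                        # n x K
  if (nrow(Y) != design$n)
    stop("curve set has ", nrow(Y), " observations but design has ", design$n)
  d <- design$residual_df
  if (d < 1L) stop("no residual degrees of freedom")
  beta <- qr.coef(design$qr, Y)         # p x K (pivot handled by qr.coef)
  beta <- beta[design$coefficient_names, , drop = FALSE]
  res <- qr.resid(design$qr, Y)
  s2 <- colSums(res^2) / d
  se <- sqrt(outer(design$v_diag, s2))  # p x K
  tstat <- beta / se
  tstat[beta == 0] <- 0                 # 0/0 at exact-fit points
  zero_se <- se == 0 & beta != 0
  if (any(zero_se))
    warning("zero residual variance with a nonzero coefficient at ",
            sum(zero_se), " (coefficient, time) cells; p set to 0")
  pval <- 2 * stats::pt(abs(tstat), df = d, lower.tail = FALSE)
  dimnames(beta) <- dimnames(se) <- dimnames(tstat) <- dimnames(pval) <-
    list(design$coefficient_names, NULL)
  structure(
    list(beta = beta, s2 = s2, se = se, t = tstat, p = pval,
         design = design, grid = cs$grid, response = cs$response),
    class = "fos_fit")
}

#' @export
print.fos_fit <- function(x, ...) {
  cat("fos_fit:", x$response, "response,", ncol(x$beta), "time points,",
      "coefficients:", paste(rownames(x$beta), collapse = ", "), "\n")
  invisible(x)
}

#' Ordinary t-inference for one coefficient
#'
#' Extracts the per-time ordinary (unmoderated) t-statistics and two-sided
#' p-values for one coefficient.  The intercept is excluded by default
#' because the scientific questions concern the predictors.
#'
#' @param fit a [fit_pointwise()] result.
#' @param coefficient coefficient name.
#' @param allow_intercept set `TRUE` to permit `"(Intercept)"`.
#' @return data.frame with columns `time`, `t`, `p`.
#' @export
ordinary_inference <- function(fit, coefficient, allow_intercept = FALSE) {
  stopifnot(inherits(fit, "fos_fit"))
  if (!coefficient %in% rownames(fit$beta))
    stop("unknown coefficient: ", coefficient)
  if (coefficient == "(Intercept)" && !allow_intercept)
    stop("the intercept is not tested by default; set allow_intercept = TRUE")
  data.frame(time = as.numeric(fit$grid),
             t = fit$t[coefficient, ],
             p = fit$p[coefficient, ])
}
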