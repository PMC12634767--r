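#' Fit one response end to end
#'
#' Runs the full analysis for one kinematic response: build the shared
#' design, fit the pointwise regressions, moderate the variances
#' (optional), assemble BH- and BY-adjusted p-value functions per
#' coefficient, extract significance regions, and collect everything in a
#' long-format result table.
#'
#' @param curves a [curve_set()].
#' @param covariates a covariate table with matching observation ids.
#' @param predictors ordered predictor names; default
#'   `c("ndi", "age", "neck_length", "sex")`.
#' @param moderation logical, apply empirical Bayes variance moderation.
#' @param params optional fixed [moderation_params()]; default estimates
#'   them from the fitted variances.
#' @param alpha significance threshold for region extraction.
#' @param region_correction which adjusted p-value drives the regions,
#'   `"bh"` (default) or `"by"`.
#' @return list of class `"fos_analysis"`: `fit`, `moderation` (or NULL),
#'   `pvalues` (see [assemble_pvalue_functions()]), `table` (see
#'   [result_table()]), `regions` (named list per coefficient x method),
#'   `alpha`.
#' @export
fos_pipeline <- function(curves, covariates,
                         predictors = c("ndi", "age", "neck_length", "sex"),
                         moderation = TRUE, params = NULL, alpha = 0.05,
                         region_correction = c("bh", "by")) {
  region_correction <- match.arg(region_correction)
  if (!identical(curves$ids, covariates$id))
    stop("curve set and covariate table ids do not match")
  design <- build_design(covariates, predictors)
  fit <- fit_pointwise(curves, design)
  mod <- if (moderation) moderated_inference(fit, params) else NULL
  pf <- assemble_pvalue_functions(fit, mod)
  padj_col <- paste0("p_", region_correction)
  keys <- unique(pf[, c("coefficient", "method")])
  regions <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- pf[pf$coefficient == keys$coefficient[r] &
                pf$method == keys$method[r], ]
    significant_regions(sub[[padj_col]], sub$time, alpha)
  })
  names(regions) <- paste(keys$coefficient, keys$method, sep = ".")
  structure(list(fit = fit, moderation = mod, pvalues = pf,
                 table = result_table(fit, mod), regions = regions,
                 alpha = alpha, region_correction = region_correction),
            class = "fos_analysis")
}

#' @export
print.fos_analysis <- function(x, ...) {
  cat("fos_analysis:", x$fit$response, "response, n =", x$fit$design$n,
      ", p =", x$fit$design$p, ", K =", ncol(x$fit$beta), "\n")
  if (!is.null(x$moderation))
    cat("  moderation: d0 =", signif(x$moderation$params$d0, 4L),
        ", s0^2 =", signif(x$moderation$params$s02, 4L), "\n")
  nsig <- vapply(x$regions, nrow, 1L)
  cat("  significant regions (", toupper(x$region_correction), ", alpha =",
      x$alpha, "):\n")
  for (nm in names(nsig))
    cat("    ", nm, ":", nsig[[nm]], "region(s)\n")
  invisible(x)
}

#' Plot raw and adjusted p-value functions for one coefficient
#'
#' Draws the ordinary raw p-value function (grey), its BH adjustment
#' (black) and the moderated BH-adjusted function (red) against
#' normalized time, with a dashed horizontal reference at `alpha`.
#'
#' @param pvalues the `pvalues` table of a [fos_pipeline()] result.
#' @param coefficient coefficient to plot.
#' @param alpha reference level; default 0.05.
#' @param correction `"bh"` or `"by"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_pvalue_functions <- function(pvalues, coefficient, alpha = 0.05,
                                  correction = c("bh", "by"), ...) {
  correction <- match.arg(correction)
  col <- paste0("p_", correction)
  ols <- pvalues[pvalues$coefficient == coefficient &
                   pvalues$method == "ols", ]
  if (!nrow(ols)) stop("no p-value function for coefficient ", coefficient)
  graphics::plot(ols$time, ols$p_raw, type = "l", col = "grey", ylim = c(0, 1),
                 xlab = "normalized time", ylab = "p-value",
                 main = coefficient, ...)
  graphics::lines(ols$time, ols[[col]], col = "black")
  mod <- pvalues[pvalues$coefficient == coefficient &
                   pvalues$method == "moderated", ]
  if (nrow(mod)) graphics::lines(mod$time, mod[[col]], col = "red")
  graphics::abline(h = alpha, lty = 2)
  invisible(NULL)
}

#' Plot effect curves with significance shading
#'
#' One line per level of the varied covariate; times where the varied
#' coefficient is significant (per the mask attached by
#' [predict_effect_curves()]) are shaded.
#'
#' @param effects an [predict_effect_curves()] result.
#' @param ylab y-axis label (response units).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, NULL.
#' @export
plot_effect_curves <- function(effects, ylab = "response", ...) {
  levs <- unique(effects$level)
  tt <- unique(effects$time)
  m <- vapply(levs, function(v) effects$predicted[effects$level == v],
              numeric(length(tt)))
  graphics::matplot(tt, m, type = "l", lty = 1L,
                    xlab = "normalized time", ylab = ylab, ...)
  sig <- effects$significant[effects$level == levs[1L]]
  if (!all(is.na(sig)) && any(sig, na.rm = TRUE)) {
    runs <- significant_regions(ifelse(is.na(sig), 1, ifelse(sig, 0, 1)),
                                tt, alpha = 0.5)
    usr <- graphics::par("usr")
    for (r in seq_len(nrow(runs)))
      graphics::rect(runs$t_start[r], usr[3L], runs$t_end[r], usr[4L],
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
  }
  graphics::legend("topright", legend = levs, col = seq_along(levs),
                   lty = 1L, cex = 0.8)
  invisible(NULL)
}
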