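test_that("design matrices carry the right leverage and df bookkeeping", {
  cov <- tiny_covariates(4)
  d0 <- build_design(cov, predictors = character(0))
  expect_equal(d0$p, 1L)
  expect_equal(unname(d0$v_diag), 0.25)   # (X'X)^-1 = 1/n for intercept only
  expect_equal(d0$residual_df, 3L)

  cov55 <- simulate_covariates(generator_config(n = 55, seed = 2))
  d55 <- build_design(cov55)
  expect_equal(d55$p, 5L)
  expect_equal(d55$residual_df, 50L)
  expect_true(all(d55$v_diag > 0))

  dup <- cov
  dup$age <- dup$ndi          # duplicated covariate column
  expect_error(build_design(dup, c("ndi", "age")), "rank deficient")
  expect_error(build_design(cov, "weight"), "weight")
})

test_that("intercept-only fit returns the mean and sample variance", {
  cov <- tiny_covariates(3)
  cs <- curve_set(cbind(c(1, 2, 3), c(1, 2, 3)), time_grid(2), "angle",
                  ids = cov$id)
  fit <- fit_pointwise(cs, build_design(cov, character(0)))
  expect_equal(unname(fit$beta[1, ]), c(2, 2))
  expect_equal(fit$s2, c(1, 1))
  expect_equal(fit$design$residual_df, 2L)
})

test_that("pointwise fits match brute-force normal equations", {
  inst <- random_instance(20, 2, 10, seed = 8)
  fit <- fit_pointwise(inst$curves, inst$design)
  expect_lt(max(abs(fit$beta - inst$beta_oracle)), 1e-8)
  # s2 from explicit residuals
  res <- inst$curves$values - inst$design$X %*% inst$beta_oracle
  expect_equal(fit$s2, colSums(res^2) / inst$design$residual_df,
               tolerance = 1e-10)
})

test_that("noise-free responses are recovered exactly with zero variance", {
  cov <- tiny_covariates(10)
  design <- build_design(cov, c("ndi", "sex"))
  K <- 6
  beta <- rbind(seq(1, 2, length.out = K), rep(0.5, K), seq(-1, 1, length.out = K))
  cs <- curve_set(design$X %*% beta, time_grid(K), "angle", ids = cov$id)
  suppressWarnings(fit <- fit_pointwise(cs, design))
  expect_lt(max(abs(fit$beta - beta)), 1e-10)
  expect_lt(max(fit$s2), 1e-20)

  # an exactly reproduced constant column: s2 = 0 with beta != 0 flags a
  # warning and a zero p-value
  cov4 <- tiny_covariates(4)
  cs4 <- curve_set(cbind(rep(8, 4), 1:4), time_grid(2), "angle",
                   ids = cov4$id)
  expect_warning(fit4 <- fit_pointwise(cs4, build_design(cov4, character(0))),
                 "zero residual variance")
  expect_equal(unname(fit4$p[1, 1]), 0)
})

test_that("ordinary t and p follow the t-distribution oracle", {
  beta <- rbind(c(0, 1), c(2, -3))
  rownames(beta) <- c("(Intercept)", "ndi")
  fit <- fake_fit(beta, s2 = c(0.25, 0.25), v_diag = c(1, 1), d = 10)
  inf <- ordinary_inference(fit, "ndi")
  expect_equal(inf$t, c(4, -6))
  expect_equal(inf$p, 2 * (1 - pt(c(4, 6), 10)))
  # beta = 0 gives t = 0, p = 1
  expect_equal(unname(fit$t[1, 1]), 0)
  expect_equal(unname(fit$p[1, 1]), 1)
  expect_error(ordinary_inference(fit, "(Intercept)"), "intercept")
  expect_silent(ordinary_inference(fit, "(Intercept)", allow_intercept = TRUE))
  expect_error(ordinary_inference(fit, "nope"), "unknown")
})

test_that("fits are scale equivariant and centering-invariant in t and p", {
  inst <- random_instance(18, 3, 7, seed = 9)
  fit1 <- fit_pointwise(inst$curves, inst$design)
  c_scale <- 3.7
  cs2 <- curve_set(inst$curves$values * c_scale, inst$curves$grid, "angle",
                   ids = inst$curves$ids)
  fit2 <- fit_pointwise(cs2, inst$design)
  expect_equal(fit2$beta, fit1$beta * c_scale, tolerance = 1e-10)
  expect_equal(fit2$s2, fit1$s2 * c_scale^2, tolerance = 1e-10)
  expect_equal(fit2$t, fit1$t, tolerance = 1e-10)
  expect_equal(fit2$p, fit1$p, tolerance = 1e-10)

  centered <- build_design(inst$cov, c("ndi", "age", "neck_length"),
                           center = TRUE)
  fit3 <- fit_pointwise(inst$curves, centered)
  expect_equal(fit3$t[-1, ], fit1$t[-1, ], tolerance = 1e-10)
  expect_equal(fit3$p[-1, ], fit1$p[-1, ], tolerance = 1e-10)
})

test_that("the fitted curve at the covariate means is the pointwise mean", {
  inst <- random_instance(25, 4, 8, seed = 10)
  fit <- fit_pointwise(inst$curves, inst$design)
  xbar <- c(1, colMeans(inst$design$X[, -1, drop = FALSE]))
  expect_equal(drop(xbar %*% fit$beta), colMeans(inst$curves$values),
               tolerance = 1e-10)
})

test_that("raw ordinary p-values are uniform under the global null", {
  set.seed(77)
  pooled <- c()
  for (r in 1:10) {
    cfg <- generator_config(n = 30, K = 100, seed = 1000 + r,
                            waveform = list(amplitude = 0, duration = 3.7))
    st <- simulate_study(cfg)
    fit <- fit_pointwise(st$curves, build_design(st$covariates))
    pooled <- c(pooled, as.numeric(fit$p[-1, ]))
  }
  expect_gt(suppressWarnings(ks.test(pooled, "punif"))$p.value, 0.01)
})
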