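test_that("trigamma inverse hits known values and is monotone", {
  expect_equal(trigamma_inverse(pi^2 / 6), 1, tolerance = 1e-8)
  for (x in c(0.3, 1, 5, 20, 200))
    expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-6)
  set.seed(31)
  y <- sort(runif(20, 0.01, 10))
  inv <- trigamma_inverse(y)
  expect_true(all(diff(inv) < 0))      # psi' is strictly decreasing
  expect_error(trigamma_inverse(-1), "positive")
  expect_error(trigamma_inverse(0), "positive")
})

test_that("constant variances hit the degenerate-prior branch", {
  d <- 12
  s2 <- rep(3.5, 40)
  par <- estimate_hyperparameters(s2, d)
  expect_equal(par$d0, Inf)
  expect_equal(par$s02, 3.5 * exp(-digamma(d / 2) + log(d / 2)),
               tolerance = 1e-12)
  expect_error(estimate_hyperparameters(rep(0, 10), d), "positive")
  expect_error(estimate_hyperparameters(2, d), "at least 2")
})

test_that("hyperparameters are recovered from the generating process", {
  # oracle = the stated prior itself: sigma2 ~ d0 s0^2 / chisq(d0), then
  # s2 ~ sigma2 * chisq(d) / d
  set.seed(42)
  d0_true <- 4; s02_true <- 2; d <- 50; K <- 1e4
  sigma2 <- d0_true * s02_true / rchisq(K, d0_true)
  s2 <- sigma2 * rchisq(K, d) / d
  par <- estimate_hyperparameters(s2, d)
  expect_lt(abs(par$d0 - d0_true) / d0_true, 0.15)
  expect_lt(abs(par$s02 - s02_true) / s02_true, 0.15)
})

test_that("the log-variance moment formula matches simulation", {
  # closed form used by the estimator:
  # E[log s2] = log(s02) + log(d0/2) - psi(d0/2) + psi(d/2) - log(d/2)
  d0 <- 6; s02 <- 1; d <- 20
  closed <- log(s02) + log(d0 / 2) - digamma(d0 / 2) +
    digamma(d / 2) - log(d / 2)
  set.seed(43)
  sigma2 <- d0 * s02 / rchisq(1e6, d0)
  z <- log(sigma2 * rchisq(1e6, d) / d)
  expect_lt(abs(mean(z) - closed), 3e-3)
})

test_that("limma's independent implementation agrees", {
  set.seed(44)
  d <- 30
  s2 <- (2 / rchisq(300, 5)) * rchisq(300, d) / d * 5
  ours <- estimate_hyperparameters(s2, d)
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-8)
  expect_equal(ours$s02, ref$scale, tolerance = 1e-8)
  sq <- squeeze_variances(s2, d, ours)
  expect_equal(sq, limma::squeezeVar(s2, df = d)$var.post, tolerance = 1e-10)
  expect_equal(trigamma_inverse(0.37), limma::trigammaInverse(0.37),
               tolerance = 1e-8)
})

test_that("variance squeezing obeys its closed-form limits", {
  s2 <- c(0.5, 2, 8)
  d <- 10
  expect_equal(squeeze_variances(s2, d, moderation_params(0, 1)), s2)
  expect_equal(squeeze_variances(s2, d, moderation_params(d, 3)),
               (3 + s2) / 2)
  expect_equal(squeeze_variances(s2, d, moderation_params(Inf, 3)),
               rep(3, 3))
  # strict convex combination with weight d / (d0 + d) on the data
  set.seed(45)
  for (r in 1:20) {
    d0 <- runif(1, 0.5, 30); s02 <- runif(1, 0.1, 5)
    s2r <- runif(5, 0.01, 10)
    sq <- squeeze_variances(s2r, d, moderation_params(d0, s02))
    expect_equal(sq, (d / (d0 + d)) * s2r + (d0 / (d0 + d)) * s02,
                 tolerance = 1e-12)
    expect_true(all(sq >= pmin(s2r, s02) - 1e-12 &
                      sq <= pmax(s2r, s02) + 1e-12))
  }
})

test_that("d0 = 0 moderation reduces exactly to the ordinary analysis", {
  inst <- random_instance(16, 3, 20, seed = 46)
  fit <- fit_pointwise(inst$curves, inst$design)
  mod <- moderated_inference(fit, moderation_params(0, 1))
  expect_equal(mod$t, fit$t, tolerance = 1e-12)
  expect_equal(mod$p, fit$p, tolerance = 1e-12)
  expect_equal(mod$df_total, fit$design$residual_df)
})

test_that("moderated t and p follow the augmented-df t oracle", {
  beta <- rbind(c(1, 0), c(-1, 2))
  rownames(beta) <- c("(Intercept)", "ndi")
  # s2 = s02 = 0.25 so the squeezed variance is 0.25 for any d0
  fit <- fake_fit(beta, s2 = c(0.25, 0.25), v_diag = c(1, 1), d = 10)
  mod <- moderated_inference(fit, moderation_params(5, 0.25))
  expect_equal(mod$s2_tilde, c(0.25, 0.25))
  expect_equal(mod$df_total, 15)
  expect_equal(mod$t["ndi", ], c(-2, 4))
  expect_equal(unname(mod$p["ndi", 1]), 2 * (1 - pt(2, 15)))
  expect_equal(unname(mod$t["(Intercept)", 2]), 0)
  expect_equal(unname(mod$p["(Intercept)", 2]), 1)
})

test_that("infinite prior df switches the null law to the standard normal", {
  inst <- random_instance(14, 2, 15, seed = 47)
  fit <- fit_pointwise(inst$curves, inst$design)
  mod <- moderated_inference(fit, moderation_params(Inf, 2))
  expect_equal(mod$s2_tilde, rep(2, 15))
  expect_equal(mod$p, 2 * pnorm(abs(mod$t), lower.tail = FALSE),
               tolerance = 1e-14)
})

test_that("moderation never touches the coefficient estimates", {
  inst <- random_instance(22, 4, 30, seed = 48)
  fit <- fit_pointwise(inst$curves, inst$design)
  beta_before <- fit$beta
  mod <- moderated_inference(fit)
  expect_identical(fit$beta, beta_before)
  expect_false("beta" %in% names(mod))   # moderation carries no beta at all
})

test_that("moderation gains power on truly affected time points", {
  set.seed(49)
  hits <- 0L
  for (r in 1:10) {
    cfg <- generator_config(
      n = 20, K = 100, seed = 500 + r,
      effects = list(ndi = effect_bump(1.0, 0.5, 0.3), age = effect_null(),
                     neck_length = effect_null(), sex = effect_null()),
      waveform = list(amplitude = 52.1, duration = 3.7))
    st <- simulate_study(cfg)
    fit <- fit_pointwise(st$curves, build_design(st$covariates))
    mod <- moderated_inference(fit)
    affected <- st$truth$beta["ndi", ] != 0
    if (mean(mod$p["ndi", affected]) <= mean(fit$p["ndi", affected]))
      hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})
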