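test_that("simulated covariates match the configured distributions", {
  cfg <- generator_config(n = 55, seed = 81)
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov), 55L)
  expect_true(all(cov$ndi >= 0 & cov$ndi <= 50 & cov$ndi == round(cov$ndi)))
  expect_true(all(cov$age > 0) && all(cov$neck_length > 0))
  expect_true(all(cov$sex %in% c(0, 1)))
  # sample means within 3 standard errors of the configured means
  expect_lt(abs(mean(cov$ndi) - 10.11), 3 * 4.76 / sqrt(55) + 0.5)
  expect_lt(abs(mean(cov$age) - 34.67), 3 * 12.45 / sqrt(55))
  expect_lt(abs(mean(cov$neck_length) - 14.98), 3 * 1.81 / sqrt(55))

  degen <- generator_config(
    n = 20, seed = 82,
    covariates = list(ndi = c(10, 0), age = c(35, 0),
                      neck_length = c(15, 0), sex_p = 0.4))
  cd <- simulate_covariates(degen)
  expect_true(all(cd$ndi == 10 & cd$age == 35 & cd$neck_length == 15))

  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
})

test_that("the variance field follows the scaled-inverse-chi-square prior", {
  conc <- generator_config(K = 100, seed = 83,
                           variance = list(d0 = 1e6, s02 = 2))
  f <- simulate_variance_field(conc)
  expect_true(all(abs(f - 2) / 2 < 0.01))

  big <- generator_config(K = 1e5, seed = 84, variance = list(d0 = 4, s02 = 2))
  fb <- simulate_variance_field(big)
  expect_lt(abs(mean(1 / fb) - 1 / 2) * 2, 0.01)   # E[1/sigma2] = 1/s02

  expect_identical(simulate_variance_field(big), simulate_variance_field(big))
})

test_that("coefficient functions realize the configured effect shapes", {
  g <- time_grid(101)   # contains t = 0.5 exactly
  cfg <- generator_config(K = 101, seed = 85)
  beta <- make_coefficient_functions(cfg, g)
  expect_equal(rownames(beta),
               c("(Intercept)", "ndi", "age", "neck_length", "sex"))
  expect_true(all(beta[-1, ] == 0))
  expect_equal(diff(range(beta["(Intercept)", ])), 2 * 52.1,
               tolerance = 1e-10)

  cfg2 <- generator_config(
    K = 101, seed = 85,
    effects = list(ndi = effect_bump(0.9, 0.5, 0.2), age = effect_null(),
                   neck_length = effect_null(), sex = effect_null()))
  b2 <- make_coefficient_functions(cfg2, g)
  tt <- as.numeric(g)
  expect_equal(unname(b2["ndi", tt == 0.5]), 0.9)
  expect_true(all(b2["ndi", abs(tt - 0.5) > 0.1] == 0))
  expect_error(effect_bump(1, center = 0.05, width = 0.3), "outside")
})

test_that("zero-noise studies are interpolated exactly by the fit", {
  cfg <- generator_config(n = 30, K = 40, seed = 86,
                          effects = list(ndi = effect_bump(1, 0.5, 0.3),
                                         age = effect_constant(-0.3),
                                         neck_length = effect_null(),
                                         sex = effect_constant(2)),
                          variance = list(profile = 0))
  st <- simulate_study(cfg)
  suppressWarnings(fit <- fit_pointwise(st$curves, build_design(st$covariates)))
  expect_lt(max(abs(fit$beta - st$truth$beta)), 1e-8)
})

test_that("pointwise confidence intervals achieve nominal coverage", {
  covered <- 0L; total <- 0L
  for (r in 1:50) {
    cfg <- generator_config(n = 55, K = 100, seed = 8600 + r,
                            effects = list(ndi = effect_bump(1, 0.5, 0.3),
                                           age = effect_null(),
                                           neck_length = effect_null(),
                                           sex = effect_null()))
    st <- simulate_study(cfg)
    fit <- fit_pointwise(st$curves, build_design(st$covariates))
    d <- fit$design$residual_df
    half <- qt(0.975, d) * fit$se["ndi", ]
    hit <- abs(fit$beta["ndi", ] - st$truth$beta["ndi", ]) <= half
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gt(covered / total, 0.93)
  expect_lt(covered / total, 0.97)
})

test_that("default study magnitudes sit on the observed kinematic scale", {
  st <- simulate_study(generator_config(seed = 87))
  rom <- diff(range(colMeans(st$curves$values)))
  expect_lt(abs(rom - 104.19), 10)
})

test_that("identical configurations reproduce bit-identical studies", {
  cfg <- generator_config(seed = 88)
  s1 <- simulate_study(cfg); s2 <- simulate_study(cfg)
  expect_identical(s1$curves$values, s2$curves$values)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$truth$beta, s2$truth$beta)
  s3 <- simulate_study(generator_config(seed = 89))
  expect_false(identical(s1$curves$values, s3$curves$values))
})

test_that("n must exceed the number of coefficients", {
  expect_error(simulate_study(generator_config(n = 5, seed = 90)), "exceed")
})

test_that("a study round trips through its CSV files", {
  dir <- withr::local_tempdir()
  st <- simulate_study(generator_config(n = 12, K = 20, seed = 91),
                       derivatives = TRUE)
  files <- write_synthetic_study(st, dir)
  expect_true(all(file.exists(files)))
  back <- read_curve_matrix(files[["angle"]], "angle")
  expect_identical(back$values, st$curves$values)
  cov <- read_covariate_table(files[["covariates"]])
  expect_equal(cov$ndi, st$covariates$ndi)
  truth <- utils::read.csv(files[["truth"]])
  expect_equal(nrow(truth), 5L * 20L)
})

test_that("smooth noise defines the same curves on any grid", {
  mk <- function(K) generator_config(
    n = 15, K = K, seed = 92, noise = "smooth",
    effects = list(ndi = effect_bump(1, 0.5, 0.4), age = effect_null(),
                   neck_length = effect_null(), sex = effect_null()))
  coarse <- simulate_study(mk(100L))
  fine <- simulate_study(mk(1000L))
  # curves agree where evaluated: interpolate the fine grid at coarse times
  tt <- as.numeric(coarse$curves$grid)
  for (i in c(1, 8, 15)) {
    fine_at <- approx(as.numeric(fine$curves$grid), fine$curves$values[i, ],
                      xout = tt)$y
    expect_lt(max(abs(fine_at - coarse$curves$values[i, ])), 0.05)
  }
})
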