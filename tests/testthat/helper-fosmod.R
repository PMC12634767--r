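# Shared fixtures, all built in code.

# small covariate table with hand-set values
tiny_covariates <- function(n = 8L) {
  covariate_table(data.frame(
    id = sprintf("s%02d", seq_len(n)),
    ndi = rep(c(5L, 10L, 15L, 20L), length.out = n),
    age = seq(25, 60, length.out = n),
    neck_length = seq(13, 17, length.out = n),
    sex = rep(c(0L, 1L), length.out = n)))
}

# random regression instance: design + curve set + the brute-force
# normal-equations solution computed independently of fit_pointwise
random_instance <- function(n, p_extra, K, seed) {
  set.seed(seed)
  df <- data.frame(id = sprintf("r%03d", seq_len(n)),
                   ndi = sample(0:50, n, replace = TRUE),
                   age = runif(n, 20, 70),
                   neck_length = runif(n, 12, 18),
                   sex = rbinom(n, 1, 0.4))
  cov <- covariate_table(df)
  predictors <- c("ndi", "age", "neck_length", "sex")[seq_len(p_extra)]
  design <- build_design(cov, predictors)
  Y <- matrix(rnorm(n * K), n, K)
  cs <- curve_set(Y, time_grid(K), "angle", ids = cov$id)
  X <- design$X
  beta_oracle <- solve(crossprod(X), crossprod(X, Y))
  list(cov = cov, design = design, curves = cs, beta_oracle = beta_oracle)
}

# minimal fos_fit object with prescribed inference inputs, for checking
# the t/p formulas directly against distribution-function oracles
fake_fit <- function(beta, s2, v_diag, d, K = length(s2)) {
  p <- nrow(beta)
  se <- sqrt(outer(v_diag, s2))
  tstat <- beta / se
  design <- structure(list(X = NULL, coefficient_names = rownames(beta),
                           v_diag = v_diag, residual_df = d,
                           n = d + p, p = p),
                      class = "fos_design")
  structure(list(beta = beta, s2 = s2, se = se, t = tstat,
                 p = 2 * stats::pt(abs(tstat), d, lower.tail = FALSE),
                 design = design, grid = time_grid(K), response = "angle"),
            class = "fos_fit")
}

# independent step-up FDR decision oracle: reject H_(i) for all
# i <= max{ i : p_(i) <= i * alpha / (c * K) } (c = 1 for BH,
# c = sum(1/i) for BY)
stepup_reject <- function(p, alpha, harmonic = FALSE) {
  K <- length(p)
  cK <- if (harmonic) sum(1 / seq_len(K)) else 1
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(K) * alpha / (cK * K))
  rej <- logical(K)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# one synthetic flexion-extension recording: m cycles of a template
# cycle function f (on [0,1]) of given duration, sampled at `hz`
synthetic_recording <- function(f, m = 5L, duration = 1, hz = 200,
                                id = "synth") {
  tt <- seq(0, m * duration, by = 1 / hz)
  raw_recording(tt, f((tt / duration) %% 1), id = id)
}
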