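test_that("MML recovers generating parameters from a large 2PL sample", {
  beta <- five_item_beta()
  param <- item_parametrization("two_pl", 5)
  data <- simulate_responses(beta, param, n = 100000, seed = 11)
  fit <- fit_mml(data, param)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta_hat - beta)), 0.05)
  expect_lt(fit$grad_norm, 1e-6)
  td <- tidy(fit)
  expect_equal(td$a, fit$beta_hat[seq(1, 10, 2)])
  expect_identical(glance(fit)$n, 100000L)
})

test_that("constrained fits satisfy the constraint and are nested in likelihood", {
  param <- item_parametrization("two_pl", 5)
  data <- simulate_responses(five_item_beta(), param, n = 2000, seed = 3)
  h <- rasch_vs_2pl(5)
  fit <- fit_mml(data, param)
  fit_r <- fit_mml(data, param, constraint = h, start = fit$beta_hat)
  slopes <- fit_r$beta_hat[seq(1, 10, 2)]
  expect_lt(diff(range(slopes)), 1e-10)
  expect_gte(fit$loglik, fit_r$loglik)
  expect_gte(observed_lr(fit, fit_r), 0)
})

test_that("pattern-collapsed likelihood equals the row-wise likelihood", {
  param <- item_parametrization("two_pl", 4)
  beta <- c(1, 0.2, 0.8, -0.5, 1.2, 0.4, 0.9, 0)
  data <- simulate_responses(beta, param, n = 200, seed = 9)
  fit <- fit_mml(data, param, maxit = 1)
  m <- marginal_model(fit$beta_hat, param = param)
  logg <- pattern_logprob(m)
  rowwise <- sum(logg[apply(data$responses, 1, function(x) {
    mmlpower:::pattern_row_index(m, x)
  })])
  collapsed <- sum(fit$patterns$counts *
    mmlpower:::pattern_stats_raw(param, fit$patterns$X, NULL, fit$beta_hat,
      fit$latent,
      want_grad = FALSE
    )$logg)
  expect_equal(collapsed, rowwise, tolerance = 1e-12)
})

test_that("observed statistics vanish in the degenerate exact-null cases", {
  param <- item_parametrization("two_pl", 4)
  beta0 <- as.vector(rbind(rep(1, 4), c(0.3, -0.2, 0.5, 0)))
  data <- simulate_responses(beta0, param, n = 1500, seed = 21)
  h <- rasch_vs_2pl(4)
  fit_r <- fit_mml(data, param, constraint = h)
  # the restricted fit satisfies its own constraint: Wald on it is zero
  expect_equal(observed_wald(fit_r, h), 0, tolerance = 1e-12)
  expect_equal(observed_lr(fit_r, fit_r), 0)
  # at the unconstrained optimum the total score vanishes: score and
  # gradient statistics built from it are zero up to convergence error
  fit <- fit_mml(data, param)
  fit$constraint <- h
  expect_lt(observed_score(fit, h), 1e-6)
  expect_lt(abs(observed_gradient(fit, fit, h)), 1e-6)
})

test_that("the observed Wald statistic is invariant to row transformations", {
  set.seed(31)
  param <- item_parametrization("two_pl", 5)
  data <- simulate_responses(five_item_beta(), param, n = 1000, seed = 31)
  h <- rasch_vs_2pl(5)
  fit <- fit_mml(data, param)
  info <- mmlpower:::fit_information(fit, fit$beta_hat)
  w0 <- observed_wald(fit, h, information = info)
  C <- matrix(rnorm(16), 4) + 4 * diag(4)
  h2 <- linear_hypothesis(C %*% h$A, as.vector(C %*% h$c))
  expect_equal(observed_wald(fit, h2, information = info), w0, tolerance = 1e-8)
})

test_that("null-generated batches have statistic means near the degrees of freedom", {
  set.seed(41)
  param <- item_parametrization("two_pl", 5)
  h <- rasch_vs_2pl(5)
  beta0 <- as.vector(rbind(rep(1, 5), rnorm(5)))
  reps <- 300
  vals <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    data <- simulate_responses(beta0, param, n = 1000)
    vals[r, ] <- observed_statistics(data, param, h)$value
  }
  means <- colMeans(vals)
  se <- apply(vals, 2, sd) / sqrt(reps)
  # chi-square_4 moments: mean df, within 3 standard errors per statistic
  for (j in 1:4) {
    expect_lt(abs(means[j] - 4), 3 * se[j])
  }
})

test_that("two-group fits share anchors and detect the group difference structure", {
  beta <- c(1.0, 0.3, 1.4, -0.3, rep(c(1, 0.2), 4))
  param <- item_parametrization("dif_two_group", 5)
  data <- simulate_responses(beta, param, n = 60000, seed = 13)
  fit <- fit_mml(data, param)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta_hat - beta)), 0.08)
  h <- dif_first_item(5)
  fit_r <- fit_mml(data, param, constraint = h, start = fit$beta_hat)
  expect_equal(fit_r$beta_hat[1], fit_r$beta_hat[3], tolerance = 1e-10)
  expect_gte(observed_lr(fit, fit_r), 0)
})

test_that("sampling-based noncentralities approach the analytical values", {
  beta <- five_item_beta()
  param <- item_parametrization("two_pl", 5)
  h <- rasch_vs_2pl(5)
  lam_an <- ncp(marginal_model(beta, param = param), h)$lambda

  # under the null the estimate is clamped near zero
  beta0 <- as.vector(rbind(rep(1, 5), beta[seq(2, 10, 2)]))
  lam0 <- sampling_ncp(beta0, param, h, n_artificial = 1e5, seed = 2)$lambda
  expect_true(all(lam0 >= 0 & lam0 <= 3 * h$df / 1e5))

  # Monte Carlo error shrinks with the artificial sample size
  lam_small <- sampling_ncp(beta, param, h, n_artificial = 1e3, seed = 5)$lambda
  lam_large <- sampling_ncp(beta, param, h, n_artificial = 1e5, seed = 5)$lambda
  err_small <- max(abs(lam_small - lam_an))
  err_large <- max(abs(lam_large - lam_an))
  expect_lt(err_large, err_small)
  expect_lt(max(abs(lam_large / lam_an - 1)), 0.2)
})

test_that("response matrices round-trip through CSV, with and without groups", {
  param <- item_parametrization("two_pl", 3)
  d <- simulate_responses(c(1, 0, 1, 0.5, 0.8, -0.3), param, n = 50, seed = 8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_response_csv(d, tmp)
  d2 <- read_response_csv(tmp)
  expect_equal(unname(d2$responses), unname(d$responses))

  dd <- simulate_responses(c(1, 0, 1.2, 0.4, rep(c(1, 0), 2)),
    item_parametrization("dif_two_group", 3),
    n = 50, seed = 8
  )
  write_response_csv(dd, tmp)
  dd2 <- read_response_csv(tmp)
  expect_equal(dd2$group, dd$group)
})
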