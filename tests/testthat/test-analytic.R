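test_that("all four noncentrality parameters match the brute-force oracle (I = 3)", {
  a <- c(0.8, 1.3, 1.05)
  d <- c(0.4, -0.2, 0.1)
  m <- marginal_model(as.vector(rbind(a, d)), param = item_parametrization("two_pl", 3))
  res <- ncp(m, rasch_vs_2pl(3))
  orc <- oracle_ncp(a, d)
  expect_equal(res$lambda[names(orc)], orc, tolerance = 1e-6)
})

test_that("the information-free statistics match the four-term oracle (I = 2)", {
  a <- c(0.85, 1.25)
  d <- c(0.3, -0.5)
  m <- two_item_model(a, d)
  h <- rasch_vs_2pl(2)
  r <- restricted_parameters(m, h)
  orc <- oracle_ncp(a, d, statistics = c("lr", "gradient"))
  expect_equal(ncp_lr(m, h, restricted = r), orc[["lr"]], tolerance = 1e-6)
  expect_equal(ncp_gradient(m, h, restricted = r), orc[["gradient"]], tolerance = 1e-6)
})

test_that("all four noncentrality parameters vanish under the null", {
  beta0 <- as.vector(rbind(rep(1.1, 4), c(0.5, -0.2, 0, 0.8)))
  m <- marginal_model(beta0, param = item_parametrization("two_pl", 4))
  res <- ncp(m, rasch_vs_2pl(4))
  expect_true(all(abs(res$lambda) < 1e-8))
  expect_equal(res$restricted$beta_r, beta0)
})

test_that("nonnegativity of the LR noncentrality over random alternatives", {
  set.seed(11)
  param <- item_parametrization("two_pl", 3)
  h <- rasch_vs_2pl(3)
  for (rep in 1:25) {
    beta <- as.vector(rbind(exp(rnorm(3, 0, 0.2)), rnorm(3)))
    m <- marginal_model(beta, param = param)
    expect_gte(ncp_lr(m, h), 0)
  }
})

test_that("restricted parameters solve the constrained expected-likelihood problem", {
  # beta already in the null set is returned unchanged
  beta0 <- as.vector(rbind(rep(0.9, 3), c(0.1, -0.4, 0.6)))
  m0 <- marginal_model(beta0, param = item_parametrization("two_pl", 3))
  r0 <- restricted_parameters(m0, rasch_vs_2pl(3))
  expect_equal(r0$beta_r, beta0, tolerance = 1e-6)

  # equal intercepts, slopes (0.8, 1.2): the common slope lies strictly
  # between, and matches a grid-search oracle over the common slope
  m <- two_item_model(a = c(0.8, 1.2), d = c(0.3, 0.3))
  h <- rasch_vs_2pl(2)
  r <- restricted_parameters(m, h)
  expect_true(r$converged)
  expect_lt(max(abs(h$A %*% r$beta_r)), 1e-8)
  common <- r$beta_r[1]
  expect_gt(common, 0.8)
  expect_lt(common, 1.2)
  g_alt <- exp(pattern_logprob(m))
  obj_of <- function(slope) {
    mr <- marginal_model(c(slope, r$beta_r[2], slope, r$beta_r[4]), param = m$param)
    sum(g_alt * pattern_logprob(mr))
  }
  grid <- seq(0.8, 1.2, by = 0.002)
  expect_equal(common, grid[which.max(vapply(grid, obj_of, 0))], tolerance = 0.002)

  # DIF restricted parameters satisfy the equality constraints exactly
  md <- marginal_model(pisa_m1_dif())
  rd <- restricted_parameters(md, dif_first_item(10))
  expect_equal(rd$beta_r[1], rd$beta_r[3], tolerance = 1e-10)
  expect_equal(rd$beta_r[2], rd$beta_r[4], tolerance = 1e-10)
})

test_that("expected information matches a 1-D oracle and scales as 1/n", {
  # single marginally-observed item: one Bernoulli(g) observation, so the
  # intercept information is (dg/dd)^2 / (g (1 - g)) with g and dg/dd
  # independent scalar integrals
  m <- marginal_model(c(1, 0), param = item_parametrization("two_pl", 1))
  info <- suppressWarnings(expected_fisher(m, method = "hessian"))$matrix
  g <- stats::integrate(function(th) stats::plogis(th) * stats::dnorm(th), -Inf, Inf,
    rel.tol = 1e-12
  )$value
  dg <- stats::integrate(function(th) {
    p <- stats::plogis(th)
    p * (1 - p) * stats::dnorm(th)
  }, -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(info[2, 2], dg^2 / (g * (1 - g)), tolerance = 1e-6)

  # the covariance at sample size n is the unit covariance over n
  m3 <- marginal_model(c(0.8, 0.4, 1.3, -0.2, 1.0, 0.1),
    param = item_parametrization("two_pl", 3)
  )
  Sigma1 <- solve(expected_fisher(m3, method = "outer")$matrix)
  expect_equal(diag(Sigma1 / 1000) * 1000, diag(Sigma1))
})

test_that("Wald and gradient noncentralities are invariant to row transformations", {
  set.seed(4)
  m <- marginal_model(five_item_beta(), param = item_parametrization("two_pl", 5))
  h <- rasch_vs_2pl(5)
  res <- ncp(m, h)
  for (rep in 1:3) {
    C <- matrix(rnorm(16), 4) + 4 * diag(4)
    h2 <- linear_hypothesis(C %*% h$A, as.vector(C %*% h$c))
    expect_equal(ncp_wald(m, h2), res$lambda[["wald"]], tolerance = 1e-8)
    expect_equal(
      ncp_gradient(m, h2, restricted = res$restricted),
      res$lambda[["gradient"]],
      tolerance = 1e-8
    )
  }
})

test_that("the four statistics agree to first order in the effect size", {
  I <- 3
  beta_r <- as.vector(rbind(rep(1, I), c(0.2, -0.3, 0.5)))
  delta <- as.vector(rbind(c(0.5, -0.2, -0.3), rep(0, I)))
  eps <- 0.05
  m <- marginal_model(beta_r + eps * delta, param = item_parametrization("two_pl", I))
  lam <- ncp(m, rasch_vs_2pl(I))$lambda
  ratios <- outer(lam, lam, "/")
  expect_lt(max(abs(ratios - 1)), 0.05)
})

test_that("doubling the constraint violation quadruples the Wald noncentrality", {
  param <- item_parametrization("two_pl", 3)
  h <- rasch_vs_2pl(3)
  m <- marginal_model(c(1.05, 0.2, 0.95, -0.1, 1.0, 0.3), param = param)
  info <- expected_fisher(m, method = "outer")
  lam <- ncp_wald(m, h, info = info)
  # fixed covariance, doubled violation: pure quadratic-form scaling
  m2 <- marginal_model(c(1.1, 0.2, 0.9, -0.1, 1.0, 0.3), param = param)
  lam2 <- ncp_wald(m2, h, info = info)
  expect_equal(lam2 / lam, 4, tolerance = 1e-8)
})

test_that("tidy() lays the noncentrality parameters out per statistic", {
  m <- marginal_model(c(0.8, 0.4, 1.3, -0.2, 1.0, 0.1),
    param = item_parametrization("two_pl", 3)
  )
  td <- tidy(ncp(m, rasch_vs_2pl(3)))
  expect_equal(td$statistic, c("wald", "lr", "score", "gradient"))
  expect_true(all(td$lambda_unit >= 0))
  expect_equal(td$df, rep(2L, 4))
})
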