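test_that("pattern space size is K^I, including magnitudes beyond enumeration", {
  expect_equal(pattern_space_size(2, 2), 4)
  expect_equal(pattern_space_size(10, 2), 1024)
  expect_equal(pattern_space_size(100, 5), 7.888609e69, tolerance = 1e-6)
})

test_that("enumeration is refused beyond the analytical gate", {
  expect_error(
    marginal_model(rep(c(1, 0), 25), param = item_parametrization("two_pl", 25)),
    "sampling"
  )
})

test_that("marginal pattern probabilities normalize and match scalar oracles", {
  # symmetric single item: marginal success probability is exactly 1/2
  m1 <- marginal_model(c(1, 0), param = item_parametrization("two_pl", 1))
  expect_equal(exp(pattern_logprob(m1, 1)), 0.5, tolerance = 1e-10)

  # exchangeable items give exchangeable patterns
  m2 <- two_item_model(a = c(1, 1), d = c(0, 0))
  expect_equal(pattern_logprob(m2, c(0, 1)), pattern_logprob(m2, c(1, 0)))

  # full normalization for 2PL (PISA M2 items 1-5), GPCM, and DIF models
  m5 <- marginal_model(pisa_m2()[1:5, ])
  expect_equal(sum(exp(pattern_logprob(m5))), 1, tolerance = 1e-8)

  set.seed(2)
  K <- 3
  beta_g <- as.vector(vapply(1:4, function(i) c(runif(1, 0.5, 1.5), rnorm(K - 1)), numeric(K)))
  mg <- marginal_model(beta_g, param = item_parametrization("gpcm", 4, n_categories = K))
  expect_equal(sum(exp(pattern_logprob(mg))), 1, tolerance = 1e-8)

  md <- marginal_model(pisa_m1_dif())
  expect_equal(sum(exp(pattern_logprob(md))), 1, tolerance = 1e-8)

  # against the independent adaptive-integration oracle, pattern by pattern
  a <- c(0.9, 1.4)
  d <- c(0.3, -0.6)
  m <- two_item_model(a, d)
  for (x1 in 0:1) {
    for (x2 in 0:1) {
      expect_equal(
        exp(pattern_logprob(m, c(x1, x2))),
        integrate_pattern(a, d, c(x1, x2)),
        tolerance = 1e-9
      )
    }
  }
})

test_that("analytic pattern score matches finite differences of the log-probability", {
  m <- marginal_model(c(1.1, -0.3), param = item_parametrization("two_pl", 1))
  sh <- score_and_hessian(m, 1)
  step <- 1e-5
  fd <- vapply(1:2, function(j) {
    bp <- bm <- m$beta
    bp[j] <- bp[j] + step
    bm[j] <- bm[j] - step
    mp <- marginal_model(bp, param = m$param)
    mm <- marginal_model(bm, param = m$param)
    (pattern_logprob(mp, 1) - pattern_logprob(mm, 1)) / (2 * step)
  }, 0)
  expect_lt(max(abs(sh$gradient - fd)), 1e-5)
  expect_lt(max(abs(sh$hessian - t(sh$hessian))), 1e-8)
})

test_that("expected score vanishes and the information equality holds", {
  m <- two_item_model()
  ps <- mmlpower:::pattern_stats(m)
  expect_lt(max(abs(as.vector(t(ps$G) %*% ps$g))), 1e-9)

  # the information identity needs an identified model: 3 items (6
  # parameters) against 2^3 - 1 = 7 multinomial degrees of freedom
  m3 <- marginal_model(c(0.8, 0.4, 1.3, -0.2, 1.0, 0.1),
    param = item_parametrization("two_pl", 3)
  )
  info_h <- expected_fisher(m3, method = "hessian")$matrix
  info_o <- expected_fisher(m3, method = "outer")$matrix
  expect_lt(max(abs(info_h - info_o)) / max(abs(info_o)), 1e-4)
  expect_gt(expected_fisher(m3, method = "outer")$min_eigenvalue, 0)
})

test_that("a two-group model with identical groups collapses to the single-group model", {
  base <- pisa_m1()[1:5, ]
  single <- marginal_model(base)
  dif_items <- dplyr::bind_rows(
    tibble::tibble(item = 1L, group = c("A", "B"), a = base$a[1], d = base$d[1]),
    dplyr::mutate(base[-1, ], group = NA_character_)
  )
  both <- marginal_model(dif_items)
  g <- exp(pattern_logprob(both))
  P <- 2^5
  # each group's conditional pattern distribution equals the single-group g
  expect_equal(2 * g[1:P], exp(pattern_logprob(single)), tolerance = 1e-12)
  expect_equal(g[1:P], g[P + 1:P], tolerance = 1e-12)
})
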