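#' Power of a chi-square test at a given sample size
#'
#' Under the null hypothesis the Wald, likelihood-ratio, score, and gradient
#' statistics asymptotically follow a central chi-square distribution with
#' `df` degrees of freedom; under a local alternative they follow the
#' noncentral chi-square with noncentrality `n * lambda_unit`. The power at
#' level `alpha` is the mass of that noncentral distribution above the
#' `1 - alpha` central quantile.
#'
#' @param lambda_unit Noncentrality parameter per observation
#'   (\eqn{\lambda(\beta, 1) \ge 0}).
#' @param df Degrees of freedom (rows of the hypothesis matrix).
#' @param n Sample size(s); vectorized.
#' @param alpha Significance level.
#' @return Power value(s) in `[alpha, 1)`; exactly `alpha` when
#'   `lambda_unit` is 0.
#' @examples
#' power_at_n(0.02, df = 4, n = 500)
#' @export
power_at_n <- function(lambda_unit, df, n, alpha = 0.05) {
  stopifnot(lambda_unit >= 0, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n * lambda_unit, lower.tail = FALSE)
}

#' Smallest sample size reaching a target power
#'
#' Inverts the noncentral chi-square power function: first the noncentrality
#' `lambda_target` giving exactly the target power is found by root search,
#' then `n* = lambda_target / lambda_unit` is rounded up to an integer,
#' which is verified (and adjusted by at most one) against the power
#' function so that `required_n` is the smallest integer sample size with
#' power at or above the target.
#'
#' @inheritParams power_at_n
#' @param target_power Desired power (e.g. 0.9).
#' @return The required integer sample size, or `NA` when `lambda_unit <= 0`
#'   (no finite sample size can exceed the size of the test).
#' @examples
#' required_sample_size(0.05, df = 9)
#' @export
required_sample_size <- function(lambda_unit, df, target_power = 0.9, alpha = 0.05) {
  stopifnot(df >= 1, target_power > alpha, target_power < 1)
  if (lambda_unit <= 0) {
    return(NA_integer_)
  }
  lambda_target <- chisq_ncp_for_power(df, target_power, alpha)
  n <- ceiling(lambda_target / lambda_unit - 1e-9)
  # guard against CDF roundoff at the boundary
  while (n > 1 && power_at_n(lambda_unit, df, n - 1, alpha) >= target_power) n <- n - 1
  while (power_at_n(lambda_unit, df, n, alpha) < target_power) n <- n + 1
  as.integer(n)
}

# Noncentrality of a chi-square_df test with exactly the target power.
chisq_ncp_for_power <- function(df, target_power, alpha) {
  crit <- stats::qchisq(1 - alpha, df)
  f <- function(ncp) {
    stats::pchisq(crit, df, ncp = ncp, lower.tail = FALSE) - target_power
  }
  upper <- 10
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Half-width of the 99% Monte Carlo confidence envelope
#'
#' For a simulation with `n_runs` replications and an expected rejection rate
#' `expected_rate`, the 99% envelope around the expected rate has half-width
#' \eqn{2.576 \sqrt{n_r p_e (1 - p_e)} / n_r}. Observed rates within the
#' envelope are consistent with perfect agreement given Monte Carlo noise.
#'
#' @param n_runs Number of simulation runs.
#' @param expected_rate Expected rejection probability.
#' @return The envelope half-width.
#' @examples
#' confidence_envelope(5000, 0.05)
#' @export
confidence_envelope <- function(n_runs, expected_rate) {
  stopifnot(n_runs >= 1, expected_rate >= 0, expected_rate <= 1)
  2.576 * sqrt(n_runs * expected_rate * (1 - expected_rate)) / n_runs
}

#' Power analysis for the four test statistics
#'
#' Computes the analytical (or sampling-based) noncentrality parameters of
#' the Wald, likelihood-ratio, score, and gradient tests of a linear
#' hypothesis, then converts them into required sample sizes at a target
#' power and, optionally, a power curve over a sample-size grid.
#'
#' @param items Item parameters (data frame or `beta` vector; see
#'   [marginal_model()]).
#' @param h A [linear_hypothesis()].
#' @param alpha Significance level.
#' @param target_power Desired power for the sample-size calculation.
#' @param method `"analytical"` (full pattern-space evaluation) or
#'   `"sampling"` (large artificial dataset; see [sampling_ncp()]).
#' @param param,latent,group_weights Passed to [marginal_model()].
#' @param n_artificial,seed Sampling-path settings (see [sampling_ncp()]).
#' @return An object of class `power_analysis`; `tidy()` returns one row per
#'   statistic with `lambda_unit`, `df`, and `required_n`; `glance()` a
#'   one-row summary. `power_at()` evaluates the power curve on an integer
#'   grid.
#' @examples
#' pa <- power_analysis(pisa_m1()[1:4, ], rasch_vs_2pl(4))
#' tidy(pa)
#' @export
power_analysis <- function(items, h, alpha = 0.05, target_power = 0.9,
                           method = c("analytical", "sampling"),
                           param = NULL, latent = latent_normal(),
                           group_weights = c(0.5, 0.5),
                           n_artificial = 1e5, seed = 1) {
  method <- match.arg(method)
  model <- marginal_model(items, param = param, latent = latent,
                          group_weights = group_weights)
  res <- if (method == "analytical") {
    ncp(model, h)
  } else {
    sampling_ncp(model$beta, model$param, h, latent = latent,
                 n_artificial = n_artificial, seed = seed,
                 group_weights = group_weights)
  }
  required_n <- vapply(
    res$lambda, required_sample_size,
    integer(1), df = h$df, target_power = target_power, alpha = alpha
  )
  structure(
    list(
      ncp = res, alpha = alpha, target_power = target_power,
      method = method, required_n = required_n, df = h$df,
      hypothesis = h
    ),
    class = "power_analysis"
  )
}

#' @rdname power_analysis
#' @param x,object A `power_analysis`.
#' @param n Integer sample-size grid.
#' @param ... Unused.
#' @export
power_at <- function(x, n) {
  stopifnot(inherits(x, "power_analysis"))
  purrr::map_dfr(names(x$ncp$lambda), function(s) {
    tibble::tibble(
      statistic = s, n = as.integer(n),
      power = power_at_n(x$ncp$lambda[[s]], x$df, n, x$alpha)
    )
  })
}

#' @rdname power_analysis
#' @method tidy power_analysis
#' @export
tidy.power_analysis <- function(x, ...) {
  tibble::tibble(
    statistic = names(x$ncp$lambda),
    lambda_unit = unname(x$ncp$lambda),
    df = x$df,
    alpha = x$alpha,
    target_power = x$target_power,
    required_n = unname(x$required_n)
  )
}

#' @rdname power_analysis
#' @method glance power_analysis
#' @export
glance.power_analysis <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    df = x$df,
    alpha = x$alpha,
    target_power = x$target_power,
    min_required_n = min(x$required_n, na.rm = TRUE),
    max_required_n = max(x$required_n, na.rm = TRUE)
  )
}

#' @export
print.power_analysis <- function(x, ...) {
  cat("<power_analysis> ", x$hypothesis$description,
    " (", x$method, " method)\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' @rdname power_analysis
#' @importFrom ggplot2 autoplot
#' @method autoplot power_analysis
#' @export
autoplot.power_analysis <- function(object, n = NULL, ...) {
  if (is.null(n)) {
    hi <- max(object$required_n, na.rm = TRUE)
    n <- seq(10, max(hi * 1.5, 100), length.out = 200)
    n <- unique(as.integer(n))
  }
  dat <- power_at(object, n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$n, y = .data$power, colour = .data$statistic
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target_power, linetype = "dashed") +
    ggplot2::labs(
      x = "sample size n", y = "power",
      title = object$hypothesis$description
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
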