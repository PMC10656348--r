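#' Expected Fisher information of the marginal model
#'
#' The expected information at unit sample size is
#' \eqn{I_F(\beta, 1) = -\sum_x \ddot{l}_\beta(x) g_\beta(x)}, the negative
#' expectation of the per-pattern Hessian of the marginal log-likelihood over
#' the full pattern space. Two evaluation routes are provided: `"hessian"`
#' differentiates the analytic score by central finite differences and
#' averages the Hessians (the defining formula); `"outer"` uses the
#' information equality \eqn{-E[\ddot{l}] = E[\dot{l}\dot{l}']}, which holds
#' because the expectation is taken under the same `beta`, and is much
#' cheaper. The two agree to quadrature and finite-difference accuracy.
#'
#' @param model A [marginal_model()].
#' @param beta Parameter vector at which to evaluate (defaults to the
#'   model's); the expectation weights `g` are evaluated at this same vector.
#' @param method `"hessian"` (defining formula) or `"outer"` (score
#'   outer-product identity).
#' @return An object of class `expected_information`: list with `matrix`
#'   (`l` x `l`, symmetric positive definite for identified models),
#'   `at_beta`, and `min_eigenvalue`.
#' @export
expected_fisher <- function(model, beta = model$beta,
                            method = c("hessian", "outer")) {
  method <- match.arg(method)
  l <- model$param$length
  ps <- pattern_stats(model, beta)
  if (method == "outer") {
    info <- crossprod(ps$G * sqrt(ps$g))
  } else {
    info <- matrix(0, l, l)
    for (j in seq_len(l)) {
      h <- 1e-5 * max(1, abs(beta[j]))
      bp <- bm <- beta
      bp[j] <- bp[j] + h
      bm[j] <- bm[j] - h
      ddl_j <- (pattern_stats(model, bp)$G - pattern_stats(model, bm)$G) / (2 * h)
      info[, j] <- -colSums(ddl_j * ps$g)
    }
    info <- (info + t(info)) / 2
  }
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning(
      "expected information is singular (smallest eigenvalue ",
      format(min(ev)), "); the parametrization may be unidentified"
    )
  }
  structure(
    list(matrix = info, at_beta = beta, min_eigenvalue = min(ev)),
    class = "expected_information"
  )
}

# Null-space parametrization of the affine constraint set {beta: A beta = c}:
# beta(gamma) = beta0 + N gamma with N an orthonormal basis of null(A) and
# beta0 the projection of `start` onto the set.
null_space_param <- function(h, start) {
  A <- h$A
  AA <- A %*% t(A)
  beta0 <- start - as.vector(t(A) %*% solve(AA, A %*% start - h$c))
  ns <- svd(A, nu = 0, nv = ncol(A))$v[, -seq_len(nrow(A)), drop = FALSE]
  list(beta0 = beta0, N = ns)
}

#' Expected restricted parameters under a linear hypothesis
#'
#' Solves \eqn{\beta_r = \arg\max_{\beta_0: A\beta_0 = c} \sum_x
#' l_{\beta_0}(x)\, g_\beta(x)}: the null-constrained parameters that a
#' maximum likelihood estimator of the restricted model converges to when the
#' data are generated by the model's (alternative) `beta`. The constraint is
#' handled by a null-space reparametrization and the reduced problem is
#' solved by BFGS with analytic gradients, started at the projection of
#' `beta` onto the constraint set. When `beta` already satisfies the null
#' hypothesis, it is returned unchanged (the objective is then the negative
#' entropy of `g`).
#'
#' @param model A [marginal_model()]; its `beta` plays the role of the
#'   data-generating (alternative) parameters.
#' @param h A [linear_hypothesis()].
#' @param start Optional start vector in the full parameter space.
#' @param reltol,maxit Optimizer control.
#' @return An object of class `restricted_solution`: list with `beta_r`,
#'   `objective` (expected log-likelihood per observation), `converged`,
#'   `grad_norm` (projected gradient at the solution), and `counts`.
#' @export
restricted_parameters <- function(model, h, start = NULL,
                                  reltol = 1e-14, maxit = 2000) {
  stopifnot(inherits(model, "marginal_model"), inherits(h, "linear_hypothesis"))
  if (ncol(h$A) != model$param$length) {
    stop("hypothesis refers to a parameter vector of length ", ncol(h$A),
         ", model has length ", model$param$length)
  }
  gx <- pattern_stats(model, want_grad = FALSE)$g
  if (max(abs(h$A %*% model$beta - h$c)) < 1e-12) {
    return(structure(
      list(
        beta_r = model$beta,
        objective = sum(gx * pattern_stats(model, want_grad = FALSE)$logg),
        converged = TRUE, grad_norm = 0,
        counts = c(`function` = 0, gradient = 0)
      ),
      class = "restricted_solution"
    ))
  }
  if (is.null(start)) start <- model$beta
  nsp <- null_space_param(h, start)
  fn <- function(gamma) {
    b <- nsp$beta0 + as.vector(nsp$N %*% gamma)
    -sum(gx * pattern_stats(model, b, want_grad = FALSE)$logg)
  }
  gr <- function(gamma) {
    b <- nsp$beta0 + as.vector(nsp$N %*% gamma)
    ps <- pattern_stats(model, b)
    -as.vector(t(nsp$N) %*% (t(ps$G) %*% gx))
  }
  opt <- stats::optim(
    par = rep(0, ncol(nsp$N)), fn = fn, gr = gr, method = "BFGS",
    control = list(maxit = maxit, reltol = reltol)
  )
  beta_r <- nsp$beta0 + as.vector(nsp$N %*% opt$par)
  grad_norm <- max(abs(gr(opt$par)))
  structure(
    list(
      beta_r = beta_r, objective = -opt$value,
      converged = opt$convergence == 0 && grad_norm < 1e-6,
      grad_norm = grad_norm, counts = opt$counts
    ),
    class = "restricted_solution"
  )
}

# Expected score at beta_r under the alternative's pattern distribution:
# s_bar = sum_x ldot_{beta_r}(x) g_beta(x)
expected_score_at <- function(model, beta_r) {
  gx <- pattern_stats(model, want_grad = FALSE)$g
  G_r <- pattern_stats(model, beta_r)$G
  as.vector(t(G_r) %*% gx)
}

clamp_lambda <- function(lambda, label) {
  if (lambda < -1e-10) {
    warning("noncentrality parameter for ", label, " is negative (",
      format(lambda), "); check convergence", call. = FALSE)
  }
  max(lambda, 0)
}

#' Noncentrality parameters of the four test statistics
#'
#' Each statistic's asymptotic noncentrality at unit sample size is obtained
#' by evaluating the statistic at the population parameters, replacing
#' pattern frequencies by their expectations `n * g_beta(x)` and covariance
#' matrices by the inverse expected information; the noncentrality at sample
#' size `n` is then `n` times the unit value.
#'
#' \describe{
#' \item{`ncp_wald()`}{\eqn{(A\beta - c)' [A\Sigma(\beta,1)A']^{-1} (A\beta -
#'   c)} with \eqn{\Sigma(\beta,1)} the inverse expected information at the
#'   alternative `beta`.}
#' \item{`ncp_lr()`}{\eqn{2\sum_x (l_\beta(x) - l_{\beta_r}(x)) g_\beta(x)},
#'   twice the expected per-observation log-likelihood gap (a
#'   Kullback-Leibler-type divergence, hence nonnegative).}
#' \item{`ncp_score()`}{the quadratic form of the expected score at
#'   \eqn{\beta_r} in the metric \eqn{\Sigma(\beta_r, 1)}, the inverse
#'   expected information at the restricted parameters.}
#' \item{`ncp_gradient()`}{\eqn{k'(A\beta - c)} where the Lagrange
#'   multipliers `k` solve the stationarity system
#'   \eqn{\sum_x \dot{l}_{\beta_r}(x) g_\beta(x) = -A'k}; no information
#'   matrix is required.}
#' }
#'
#' `ncp()` computes all four at once (sharing the restricted solution and
#' information matrices) and returns an `ncp_result`.
#'
#' @param model A [marginal_model()] whose `beta` is the alternative.
#' @param h A [linear_hypothesis()].
#' @param info An [expected_fisher()] result at the alternative `beta`
#'   (computed if omitted).
#' @param restricted A [restricted_parameters()] result (computed if
#'   omitted).
#' @return Scalars for the individual functions; `ncp()` returns an
#'   `ncp_result` with fields `lambda` (named vector over wald/lr/score/
#'   gradient, per unit sample size), `df`, `beta`, `restricted`, and
#'   `hypothesis`.
#' @export
ncp_wald <- function(model, h, info = NULL) {
  if (is.null(info)) info <- expected_fisher(model, method = "outer")
  r <- as.vector(h$A %*% model$beta - h$c)
  Sigma <- solve(info$matrix)
  lambda <- as.numeric(t(r) %*% solve(h$A %*% Sigma %*% t(h$A), r))
  clamp_lambda(lambda, "wald")
}

#' @rdname ncp_wald
#' @export
ncp_lr <- function(model, h, restricted = NULL) {
  if (is.null(restricted)) restricted <- restricted_parameters(model, h)
  ps <- pattern_stats(model, want_grad = FALSE)
  logg_r <- pattern_stats(model, restricted$beta_r, want_grad = FALSE)$logg
  lambda <- 2 * sum(ps$g * (ps$logg - logg_r))
  clamp_lambda(lambda, "lr")
}

#' @rdname ncp_wald
#' @export
ncp_score <- function(model, h, restricted = NULL) {
  if (is.null(restricted)) restricted <- restricted_parameters(model, h)
  s_bar <- expected_score_at(model, restricted$beta_r)
  info_r <- expected_fisher(model, beta = restricted$beta_r, method = "outer")
  lambda <- as.numeric(t(s_bar) %*% solve(info_r$matrix, s_bar))
  clamp_lambda(lambda, "score")
}

#' @rdname ncp_wald
#' @export
ncp_gradient <- function(model, h, restricted = NULL) {
  if (is.null(restricted)) restricted <- restricted_parameters(model, h)
  s_bar <- expected_score_at(model, restricted$beta_r)
  k <- solve_lagrange(h$A, s_bar)
  if (k$residual > 1e-4 * max(1, max(abs(s_bar)))) {
    warning("expected score at the restricted parameters is not in the row ",
      "space of A (residual ", format(k$residual),
      "); the restricted solution may not have converged", call. = FALSE)
  }
  lambda <- as.numeric(t(k$k) %*% (h$A %*% model$beta - h$c))
  clamp_lambda(lambda, "gradient")
}

# Solve s = A'k in the least-squares sense; at an interior restricted
# optimum s lies in the row space of A' and the solution is exact. With
# this orientation k'(A beta - c) equals s'(beta - beta_r), the score at
# the restricted parameters times the parameter difference, which is the
# nonnegative form of the gradient statistic.
solve_lagrange <- function(A, s) {
  k <- solve(A %*% t(A), A %*% s)
  residual <- max(abs(s - as.vector(t(A) %*% k)))
  list(k = as.vector(k), residual = residual)
}

#' @rdname ncp_wald
#' @export
ncp <- function(model, h, restricted = NULL) {
  stopifnot(inherits(model, "marginal_model"), inherits(h, "linear_hypothesis"))
  # No effect: all four noncentralities are exactly zero, skip optimization
  if (max(abs(h$A %*% model$beta - h$c)) < 1e-12) {
    lambda <- c(wald = 0, lr = 0, score = 0, gradient = 0)
    restricted <- structure(
      list(beta_r = model$beta, objective = NA_real_, converged = TRUE,
           grad_norm = 0, counts = c(`function` = 0, gradient = 0)),
      class = "restricted_solution"
    )
    return(new_ncp_result(lambda, model, h, restricted))
  }
  if (is.null(restricted)) restricted <- restricted_parameters(model, h)
  info <- expected_fisher(model, method = "outer")
  lambda <- c(
    wald = ncp_wald(model, h, info = info),
    lr = ncp_lr(model, h, restricted = restricted),
    score = ncp_score(model, h, restricted = restricted),
    gradient = ncp_gradient(model, h, restricted = restricted)
  )
  new_ncp_result(lambda, model, h, restricted)
}

new_ncp_result <- function(lambda, model, h, restricted) {
  structure(
    list(
      lambda = lambda, df = h$df, beta = model$beta,
      restricted = restricted, hypothesis = h
    ),
    class = "ncp_result"
  )
}

#' @export
print.ncp_result <- function(x, ...) {
  cat("<ncp_result> ", x$hypothesis$description, " (df = ", x$df, ")\n", sep = "")
  print(round(x$lambda, 8))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a set of noncentrality parameters
#'
#' @param x An `ncp_result`.
#' @param ... Unused.
#' @return A tibble with one row per statistic: columns `statistic`,
#'   `lambda_unit` (noncentrality per observation), and `df`.
#' @method tidy ncp_result
#' @export
tidy.ncp_result <- function(x, ...) {
  tibble::tibble(
    statistic = names(x$lambda),
    lambda_unit = unname(x$lambda),
    df = x$df
  )
}
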