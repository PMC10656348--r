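#' Response data containers
#'
#' `response_data()` wraps an n x I integer matrix of responses (categories
#' coded 0..K-1) with optional group labels, and collapses it to unique
#' response patterns with frequencies. All likelihood computations work on
#' the collapsed form, which is exactly equal to the row-wise likelihood but
#' far cheaper when n greatly exceeds the number of distinct patterns.
#'
#' @param responses An n x I integer matrix or data frame (categories coded
#'   0..K-1).
#' @param group Optional length-n vector of group labels (1/2 or "A"/"B")
#'   for two-group models.
#' @return An object of class `response_data` with fields `responses`,
#'   `group`, `n`, `n_items`, `n_categories`.
#' @export
response_data <- function(responses, group = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (any(responses < 0)) stop("categories must be coded 0..K-1")
  if (!is.null(group)) {
    if (is.character(group) || is.factor(group)) {
      group <- match(as.character(group), c("A", "B"))
    }
    group <- as.integer(group)
    stopifnot(length(group) == nrow(responses), all(group %in% 1:2))
  }
  structure(
    list(
      responses = responses, group = group, n = nrow(responses),
      n_items = ncol(responses), n_categories = max(responses) + 1L
    ),
    class = "response_data"
  )
}

#' @export
print.response_data <- function(x, ...) {
  cat("<response_data> n = ", x$n, ", I = ", x$n_items,
    ", K >= ", x$n_categories,
    if (!is.null(x$group)) ", two groups", "\n",
    sep = ""
  )
  invisible(x)
}

# Frequencies of each enumerated pattern row of a model (h_X(x)), aligned
# with the model's pattern enumeration. Sum equals n.
pattern_frequencies <- function(data, model) {
  param <- model$param
  K <- param$n_categories
  I <- param$n_items
  X <- data$responses
  if (max(X) >= K) stop("data contain categories outside the model's range")
  idx <- as.vector(X %*% K^((I - 1):0)) + 1L
  P <- K^I
  if (param$family == "dif_two_group") {
    if (is.null(data$group)) stop("two-group model requires group labels")
    idx <- idx + (data$group - 1L) * P
    P <- 2L * P
  }
  tabulate(idx, nbins = P)
}

#' Read or write a response matrix as CSV
#'
#' Plain integer CSV, one row per person, one column per item (named
#' `item1`..`itemI`), with an optional leading `group` column for two-group
#' data.
#'
#' @param path File path.
#' @param data A [response_data()].
#' @export
read_response_csv <- function(path) {
  df <- utils::read.csv(path)
  group <- NULL
  if ("group" %in% names(df)) {
    group <- df$group
    df$group <- NULL
  }
  response_data(as.matrix(df), group = group)
}

#' @rdname read_response_csv
#' @export
write_response_csv <- function(data, path) {
  df <- as.data.frame(data$responses)
  names(df) <- paste0("item", seq_len(ncol(df)))
  if (!is.null(data$group)) df <- cbind(group = data$group, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Marginal maximum likelihood fit
#'
#' Maximizes the pattern-collapsed marginal log-likelihood
#' \eqn{\sum_x h(x) \log g_\beta(x)} by quasi-Newton (BFGS) iteration with
#' analytic gradients, integrating the latent trait out by quadrature. With
#' a `constraint`, the optimization runs in the null-space parametrization
#' of the constraint set, so restricted (e.g. Rasch) and unrestricted (2PL)
#' fits share one coordinate system. The iteration cap is 5000 cycles.
#'
#' @param data A [response_data()] (or a raw response matrix).
#' @param param An [item_parametrization()].
#' @param constraint Optional [linear_hypothesis()] to fit the restricted
#'   model.
#' @param latent Latent trait distribution.
#' @param group_weights Group weights for two-group models (informational;
#'   the fit conditions on the observed group sizes).
#' @param start Optional start vector.
#' @param maxit,reltol Optimizer control.
#' @return An object of class `mml_fit` with fields `beta_hat`, `loglik`,
#'   `converged`, `n_iterations`, `grad_norm`, plus the model pieces needed
#'   by the statistic functions.
#' @export
fit_mml <- function(data, param, constraint = NULL, latent = latent_normal(),
                    group_weights = NULL, start = NULL,
                    maxit = 5000, reltol = 1e-13) {
  if (!inherits(data, "response_data")) data <- response_data(data)
  stopifnot(inherits(param, "item_parametrization"))
  if (data$n_items != param$n_items) stop("data and parametrization disagree on I")
  if (param$family == "dif_two_group" && is.null(data$group)) {
    stop("two-group model requires group labels in the data")
  }
  if (is.null(group_weights)) {
    group_weights <- if (!is.null(data$group)) {
      tabulate(data$group, 2) / data$n
    } else {
      c(0.5, 0.5)
    }
  }
  cd <- collapse_patterns(data)
  if (is.null(start)) start <- default_start(data, param)
  empty <- category_gaps(data, param)
  if (length(empty)) {
    warning("categories never observed: ", paste(empty, collapse = ", "),
      "; their intercepts are weakly identified", call. = FALSE)
  }
  logg_at <- function(b) {
    pattern_stats_raw(param, cd$X, cd$group, b, latent, group_weights,
                      want_grad = FALSE)$logg
  }
  score_at <- function(b) {
    G <- pattern_stats_raw(param, cd$X, cd$group, b, latent, group_weights)$G
    as.vector(t(G) %*% cd$counts)
  }
  if (is.null(constraint)) {
    opt <- stats::optim(start,
      fn = function(b) -sum(cd$counts * logg_at(b)),
      gr = function(b) -score_at(b),
      method = "BFGS", control = list(maxit = maxit, reltol = reltol)
    )
    beta_hat <- opt$par
    grad_norm <- max(abs(score_at(beta_hat))) / data$n
  } else {
    nsp <- null_space_param(constraint, start)
    expand <- function(g_) nsp$beta0 + as.vector(nsp$N %*% g_)
    opt <- stats::optim(rep(0, ncol(nsp$N)),
      fn = function(g_) -sum(cd$counts * logg_at(expand(g_))),
      gr = function(g_) -as.vector(t(nsp$N) %*% score_at(expand(g_))),
      method = "BFGS", control = list(maxit = maxit, reltol = reltol)
    )
    beta_hat <- expand(opt$par)
    grad_norm <- max(abs(t(nsp$N) %*% score_at(beta_hat))) / data$n
  }
  structure(
    list(
      beta_hat = beta_hat, loglik = -opt$value,
      converged = opt$convergence == 0, n_iterations = unname(opt$counts[1]),
      grad_norm = grad_norm,
      param = param, latent = latent, constraint = constraint,
      group_weights = group_weights,
      patterns = cd, n = data$n
    ),
    class = "mml_fit"
  )
}

# Collapse a dataset to its unique (group, pattern) rows with frequencies.
# The collapsed marginal likelihood equals the row-wise likelihood exactly.
collapse_patterns <- function(data) {
  X <- data$responses
  key <- do.call(paste, c(as.data.frame(X), list(sep = ",")))
  if (!is.null(data$group)) key <- paste(data$group, key, sep = "|")
  first <- !duplicated(key)
  counts <- as.vector(table(factor(key, levels = key[first])))
  list(
    X = X[first, , drop = FALSE],
    group = if (!is.null(data$group)) data$group[first] else NULL,
    counts = counts
  )
}

# Neutral start values: unit slopes, intercepts from observed category
# proportions (logit of the mean for dichotomous items, zeros otherwise).
default_start <- function(data, param) {
  I <- param$n_items
  K <- param$n_categories
  if (param$family == "two_pl") {
    pbar <- pmin(pmax(colMeans(data$responses), 0.02), 0.98)
    as.vector(rbind(rep(1, I), stats::qlogis(pbar)))
  } else if (param$family == "dif_two_group") {
    pbar <- pmin(pmax(colMeans(data$responses), 0.02), 0.98)
    d <- stats::qlogis(pbar)
    c(1, d[1], 1, d[1], as.vector(rbind(rep(1, I - 1), d[-1])))
  } else {
    rep(as.vector(c(1, rep(0, K - 1))), I)
  }
}

category_gaps <- function(data, param) {
  K <- param$n_categories
  gaps <- character(0)
  for (i in seq_len(param$n_items)) {
    seen <- unique(data$responses[, i])
    miss <- setdiff(0:(K - 1), seen)
    if (length(miss)) gaps <- c(gaps, paste0("item ", i, ": ", paste(miss, collapse = "/")))
  }
  gaps
}

#' @export
print.mml_fit <- function(x, ...) {
  cat("<mml_fit> ", x$param$family,
    if (!is.null(x$constraint)) " (restricted)", ": loglik = ",
    format(x$loglik), ", converged = ", x$converged, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_mml
#' @param x,object An `mml_fit`.
#' @param ... Unused.
#' @method tidy mml_fit
#' @export
tidy.mml_fit <- function(x, ...) {
  out <- items_from_beta(x$beta_hat, x$param)
  tibble::as_tibble(out)
}

#' @rdname fit_mml
#' @method glance mml_fit
#' @export
glance.mml_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n = x$n, n_parameters = x$param$length,
    converged = x$converged, n_iterations = x$n_iterations,
    grad_norm = x$grad_norm
  )
}

# Information (unit n) at arbitrary beta for a fitted model's structure.
# When the pattern space is small enough, the expected Fisher information is
# computed exactly over the enumerated space; otherwise the empirical
# cross-product of per-pattern scores weighted by observed frequencies is
# used. Both converge to the expected Fisher information in large samples.
.info_gate <- 32768

fit_information <- function(fit, beta) {
  param <- fit$param
  size <- pattern_space_size(param$n_items, param$n_categories) *
    if (param$family == "dif_two_group") 2 else 1
  if (size <= .info_gate) {
    model <- marginal_model(beta, param = param, latent = fit$latent,
                            group_weights = fit$group_weights)
    expected_fisher(model, method = "outer")$matrix
  } else {
    G <- pattern_stats_raw(param, fit$patterns$X, fit$patterns$group, beta,
                           fit$latent, fit$group_weights)$G
    crossprod(G * sqrt(fit$patterns$counts)) / fit$n
  }
}

#' Observed test statistics for a linear hypothesis
#'
#' The four large-sample statistics computed from fitted models:
#' \describe{
#' \item{`observed_wald()`}{\eqn{(A\hat\beta - c)'[A\Sigma A']^{-1}(A\hat\beta
#'   - c)} with \eqn{\Sigma} the inverse information of the dataset at the
#'   unrestricted estimates; needs only the unrestricted fit.}
#' \item{`observed_lr()`}{twice the marginal log-likelihood difference of the
#'   nested fits.}
#' \item{`observed_score()`}{the quadratic form of the total score vector at
#'   the restricted estimates in the dataset covariance at those estimates;
#'   needs only the restricted fit.}
#' \item{`observed_gradient()`}{\eqn{k'(A\hat\beta - c)} with Lagrange
#'   multipliers `k` solving `total score = -A'k` at the restricted
#'   estimates; needs both fits but no information matrix.}
#' }
#'
#' The information matrix entering the Wald and score statistics is the
#' expected Fisher information evaluated at the respective estimates over
#' the enumerated pattern space.
#'
#' @param fit,fit_full,fit_restricted `mml_fit` objects on the same data;
#'   `fit_restricted` must be constrained by `h`.
#' @param h A [linear_hypothesis()].
#' @param information Optional `l x l` unit-`n` information matrix to use in
#'   place of the expected Fisher information at the estimates.
#' @return The statistic value (nonnegative up to roundoff).
#' @export
observed_wald <- function(fit, h, information = NULL) {
  stopifnot(inherits(fit, "mml_fit"))
  if (is.null(information)) information <- fit_information(fit, fit$beta_hat)
  r <- as.vector(h$A %*% fit$beta_hat - h$c)
  Sigma1 <- solve(information)
  fit$n * as.numeric(t(r) %*% solve(h$A %*% Sigma1 %*% t(h$A), r))
}

#' @rdname observed_wald
#' @export
observed_lr <- function(fit_full, fit_restricted) {
  stopifnot(inherits(fit_full, "mml_fit"), inherits(fit_restricted, "mml_fit"))
  if (fit_full$n != fit_restricted$n) stop("fits are not on the same data")
  2 * (fit_full$loglik - fit_restricted$loglik)
}

#' @rdname observed_wald
#' @export
observed_score <- function(fit_restricted, h = fit_restricted$constraint,
                           information = NULL) {
  stopifnot(inherits(fit_restricted, "mml_fit"))
  s <- total_score(fit_restricted)
  if (is.null(information)) {
    information <- fit_information(fit_restricted, fit_restricted$beta_hat)
  }
  # Sigma(beta_r, data) = (n * I_F(beta_r, 1))^-1
  as.numeric(t(s) %*% solve(information, s)) / fit_restricted$n
}

#' @rdname observed_wald
#' @export
observed_gradient <- function(fit_full, fit_restricted, h = fit_restricted$constraint) {
  s <- total_score(fit_restricted)
  k <- solve_lagrange(h$A, s)
  as.numeric(t(k$k) %*% (h$A %*% fit_full$beta_hat - h$c))
}

# Total observed score vector at the (restricted) estimates:
# sum_x h(x) ldot_{beta_hat}(x)
total_score <- function(fit) {
  G <- pattern_stats_raw(
    fit$param, fit$patterns$X, fit$patterns$group, fit$beta_hat,
    fit$latent, fit$group_weights
  )$G
  as.vector(t(G) %*% fit$patterns$counts)
}

#' All four observed statistics at once
#'
#' Convenience wrapper fitting the unrestricted and restricted models and
#' returning the four statistics as a tibble.
#'
#' @param data A [response_data()] or response matrix.
#' @param param An [item_parametrization()].
#' @param h A [linear_hypothesis()].
#' @param latent Latent trait distribution.
#' @return A tibble with columns `statistic` and `value`.
#' @export
observed_statistics <- function(data, param, h, latent = latent_normal()) {
  if (!inherits(data, "response_data")) data <- response_data(data)
  fit_full <- fit_mml(data, param, latent = latent)
  fit_restr <- fit_mml(data, param, constraint = h, latent = latent,
                       start = fit_full$beta_hat)
  tibble::tibble(
    statistic = c("wald", "lr", "score", "gradient"),
    value = c(
      observed_wald(fit_full, h),
      observed_lr(fit_full, fit_restr),
      observed_score(fit_restr, h),
      observed_gradient(fit_full, fit_restr, h)
    )
  )
}

#' Sampling-based noncentrality parameters
#'
#' Approximates the unit noncentrality parameters without enumerating the
#' pattern space: (1) generate one large artificial dataset of size
#' `n_artificial` from the alternative parameters, (2) fit the restricted
#' and unrestricted models by MML and compute the four observed statistics,
#' (3) subtract the degrees of freedom and divide by `n_artificial`
#' (clamping at zero). As `n_artificial` grows this converges to the
#' analytical noncentrality.
#'
#' @param beta Alternative item parameters (stacked vector).
#' @param param An [item_parametrization()].
#' @param h A [linear_hypothesis()].
#' @param latent Latent trait distribution.
#' @param n_artificial Size of the artificial dataset (the larger the more
#'   accurate; 1e5 by default, 1e6 for high accuracy).
#' @param seed Integer seed for the artificial dataset.
#' @param group_weights Group weights for two-group layouts.
#' @return An `ncp_result` (see [ncp()]) whose `lambda` entries are the
#'   sampling approximations; `restricted` holds the restricted fit.
#' @export
sampling_ncp <- function(beta, param, h, latent = latent_normal(),
                         n_artificial = 1e5, seed = 1,
                         group_weights = c(0.5, 0.5)) {
  data <- simulate_responses(beta, param, latent = latent, n = n_artificial,
                             seed = seed, group_weights = group_weights)
  fit_full <- fit_mml(data, param, latent = latent, start = beta)
  fit_restr <- fit_mml(data, param, constraint = h, latent = latent,
                       start = fit_full$beta_hat)
  if (!fit_full$converged || !fit_restr$converged) {
    warning("MML fit did not converge; sampling-based noncentrality may be unreliable")
  }
  stats_ <- c(
    wald = observed_wald(fit_full, h),
    lr = observed_lr(fit_full, fit_restr),
    score = observed_score(fit_restr, h),
    gradient = observed_gradient(fit_full, fit_restr, h)
  )
  lambda <- pmax((stats_ - h$df) / n_artificial, 0)
  restricted <- structure(
    list(beta_r = fit_restr$beta_hat, objective = fit_restr$loglik / n_artificial,
         converged = fit_restr$converged, grad_norm = fit_restr$grad_norm,
         counts = c(`function` = fit_restr$n_iterations, gradient = NA)),
    class = "restricted_solution"
  )
  new_ncp_result(lambda, list(beta = beta), h, restricted)
}
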