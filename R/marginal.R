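#' Size of the response-pattern space
#'
#' With `I` items and `K` response categories there are `K^I` distinct
#' response patterns. The analytical power-analysis path sums over all of
#' them, so this count gates its feasibility; a hundred five-category items
#' already imply about 7.9e69 patterns, far beyond enumeration, and the
#' sampling-based path must be used instead.
#'
#' @param I Number of items.
#' @param K Number of categories.
#' @return `K^I` as a double (exact for counts below 2^53, a magnitude
#'   beyond).
#' @examples
#' pattern_space_size(10, 2)
#' pattern_space_size(100, 5)
#' @export
pattern_space_size <- function(I, K) {
  stopifnot(I >= 1, K >= 1)
  K^I
}

# Largest pattern space the analytical path will enumerate.
.pattern_gate <- 2e6

#' Marginal IRT model over the full pattern space
#'
#' Bundles an item parametrization, a parameter vector `beta`, and a latent
#' trait distribution into a model object exposing the marginal pattern
#' probabilities \eqn{g_\beta(x) = \int f_{\beta,\theta}(x)\,\Phi(\theta)
#' d\theta}, evaluated by quadrature over the latent distribution. For the
#' two-group DIF layout the pattern space is the product of group label and
#' response pattern, and `g` is the joint probability including the group
#' weight.
#'
#' @param items Item parameters: either a data frame (see
#'   [beta_from_items()]) or a numeric `beta` vector matching `param`.
#' @param param An [item_parametrization()]; inferred from a data frame input
#'   when omitted.
#' @param latent A [latent_normal()] or [latent_tabulated()] distribution.
#' @param group_weights Group membership probabilities for the two-group
#'   layout (default equal split).
#' @return An object of class `marginal_model`.
#' @examples
#' m <- marginal_model(tibble::tibble(item = 1:2, a = 1, d = 0))
#' sum(exp(pattern_logprob(m)))
#' @export
marginal_model <- function(items, param = NULL, latent = latent_normal(),
                           group_weights = c(0.5, 0.5)) {
  if (is.numeric(items) && is.null(dim(items))) {
    stopifnot(!is.null(param))
    beta <- as.numeric(items)
  } else {
    items <- tibble::as_tibble(items)
    if (is.null(param)) param <- infer_parametrization(items)
    beta <- unname(beta_from_items(items, param))
  }
  stopifnot(length(beta) == param$length, all(is.finite(beta)))
  if (param$family == "dif_two_group") {
    stopifnot(length(group_weights) == 2, all(group_weights > 0))
    group_weights <- group_weights / sum(group_weights)
  } else {
    group_weights <- NULL
  }
  size <- pattern_space_size(param$n_items, param$n_categories)
  if (size > .pattern_gate) {
    stop(
      "pattern space has ", format(size), " patterns (> ", format(.pattern_gate),
      "); the analytical path cannot enumerate it -- use sampling_ncp()"
    )
  }
  structure(
    list(
      param = param, beta = beta, latent = latent,
      group_weights = group_weights,
      patterns = enumerate_patterns(param)
    ),
    class = "marginal_model"
  )
}

#' @export
print.marginal_model <- function(x, ...) {
  cat("<marginal_model> ", x$param$family, ": I = ", x$param$n_items,
    ", K = ", x$param$n_categories, ", ",
    nrow(x$patterns$X), " pattern rows\n",
    sep = ""
  )
  invisible(x)
}

# Enumerate all response patterns in odometer order (last item fastest).
# Categories are coded 0..K-1 internally. For the DIF layout the space is
# duplicated with a group index (1 = A, 2 = B).
enumerate_patterns <- function(param) {
  I <- param$n_items
  K <- param$n_categories
  P <- K^I
  X <- matrix(0L, nrow = P, ncol = I)
  for (i in seq_len(I)) {
    X[, i] <- rep(rep(0:(K - 1), each = K^(I - i)), length.out = P)
  }
  if (param$family == "dif_two_group") {
    list(X = rbind(X, X), group = rep(1:2, each = P))
  } else {
    list(X = X, group = NULL)
  }
}

# Effective per-group 2PL (a, d) vectors for the DIF layout.
dif_group_items <- function(beta, I) {
  list(
    A = list(a = c(beta[1], beta[seq(5, 2 * I + 1, by = 2)]),
             d = c(beta[2], beta[seq(6, 2 * I + 2, by = 2)])),
    B = list(a = c(beta[3], beta[seq(5, 2 * I + 1, by = 2)]),
             d = c(beta[4], beta[seq(6, 2 * I + 2, by = 2)]))
  )
}

# Core computation: marginal pattern probabilities g (P-vector) and, if
# requested, the P x l matrix G of gradients of log g with respect to beta.
# Everything downstream (likelihoods, information matrices, all four test
# statistics) is built from these two quantities. `pattern_stats()` works on
# a model's full enumerated space; `pattern_stats_raw()` on any pattern
# matrix (e.g. the unique observed patterns of a dataset), which is what
# keeps fitting feasible when K^I is far too large to enumerate.
pattern_stats <- function(model, beta = model$beta, want_grad = TRUE) {
  pattern_stats_raw(
    model$param, model$patterns$X, model$patterns$group, beta,
    model$latent, model$group_weights, want_grad
  )
}

pattern_stats_raw <- function(param, X, group, beta, latent,
                              group_weights = NULL, want_grad = TRUE) {
  switch(param$family,
    two_pl = pattern_stats_2pl(X, beta, latent, want_grad),
    gpcm = pattern_stats_gpcm(X, beta, param$n_categories, latent, want_grad),
    dif_two_group = {
      I <- param$n_items
      l <- param$length
      if (is.null(group_weights)) group_weights <- c(0.5, 0.5)
      grp <- dif_group_items(beta, I)
      P <- nrow(X)
      g <- numeric(P)
      logg <- numeric(P)
      G <- if (want_grad) matrix(0, P, l) else NULL
      for (gi in 1:2) {
        rows <- which(group == gi)
        if (!length(rows)) next
        gpar <- grp[[gi]]
        b <- as.vector(rbind(gpar$a, gpar$d))
        res <- pattern_stats_2pl(X[rows, , drop = FALSE], b, latent, want_grad)
        w <- group_weights[gi]
        g[rows] <- w * res$g
        logg[rows] <- log(w) + res$logg
        if (want_grad) {
          item1_cols <- if (gi == 1) c(1L, 2L) else c(3L, 4L)
          G[rows, item1_cols] <- res$G[, 1:2]
          G[rows, 5:l] <- res$G[, -(1:2), drop = FALSE]
        }
      }
      out <- list(g = g, logg = logg)
      if (want_grad) out$G <- G
      out
    }
  )
}

pattern_stats_2pl <- function(X, beta, latent, want_grad) {
  I <- ncol(X)
  t_q <- latent$nodes
  w <- latent$weights
  a <- beta[seq(1, 2 * I, by = 2)]
  d <- beta[seq(2, 2 * I, by = 2)]
  eta <- outer(a, t_q) + d # I x Q
  logp1 <- -log1p(exp(-eta))
  logp0 <- -log1p(exp(eta))
  LL <- X %*% logp1 + (1 - X) %*% logp0 # P x Q, log f(x | theta_q)
  M <- exp(LL) %*% diag(w, length(w)) # P x Q, w_q f(x | theta_q)
  g <- rowSums(M)
  out <- list(g = g, logg = log(g))
  if (want_grad) {
    p <- stats::plogis(eta)
    Mt <- as.vector(M %*% t_q)
    Dd <- X * g - M %*% t(p) # P x I, unnormalized d-scores
    Da <- X * Mt - M %*% t(p * rep(t_q, each = I)) # P x I
    G <- matrix(0, nrow = nrow(X), ncol = 2 * I)
    G[, seq(1, 2 * I, by = 2)] <- Da / g
    G[, seq(2, 2 * I, by = 2)] <- Dd / g
    out$G <- G
  }
  out
}

pattern_stats_gpcm <- function(X, beta, K, latent, want_grad) {
  I <- ncol(X)
  t_q <- latent$nodes
  Q <- length(t_q)
  w <- latent$weights
  P <- nrow(X)
  # per item: slope + K-1 free intercepts (first category intercept fixed 0)
  a <- beta[seq(1, I * K, by = K)]
  logP <- vector("list", I) # each K x Q
  Ebar <- matrix(0, I, Q) # expected category index per item/node
  for (i in seq_len(I)) {
    d_i <- c(0, beta[(i - 1) * K + 2:K])
    eta <- outer(0:(K - 1) * a[i], t_q) + d_i # K x Q
    eta <- sweep(eta, 2, apply(eta, 2, max))
    pi <- exp(eta)
    pi <- sweep(pi, 2, colSums(pi), "/")
    logP[[i]] <- log(pi)
    Ebar[i, ] <- colSums(pi * (0:(K - 1)))
  }
  LL <- matrix(0, P, Q)
  for (i in seq_len(I)) LL <- LL + logP[[i]][X[, i] + 1, , drop = FALSE]
  M <- exp(LL) %*% diag(w, Q)
  g <- rowSums(M)
  out <- list(g = g, logg = log(g))
  if (want_grad) {
    G <- matrix(0, P, I * K)
    Mt <- as.vector(M %*% t_q)
    for (i in seq_len(I)) {
      pi <- exp(logP[[i]])
      G[, (i - 1) * K + 1] <- (X[, i] * Mt - M %*% (t_q * Ebar[i, ])) / g
      for (k in 2:K) {
        ind <- as.numeric(X[, i] == (k - 1))
        G[, (i - 1) * K + k] <- (ind * g - M %*% pi[k, ]) / g
      }
    }
    out$G <- G
  }
  out
}

#' Marginal log-probability of response patterns
#'
#' Returns \eqn{\log g_\beta(x)} for one pattern or, by default, for the full
#' enumerated pattern space of the model (whose exponentials sum to 1 up to
#' quadrature error).
#'
#' @param model A [marginal_model()].
#' @param x Optional single response pattern (categories coded 0..K-1) of
#'   length `I`; for two-group models, a list `list(group =, x =)` with group
#'   1 or 2. If omitted, the log-probabilities of the full pattern space are
#'   returned, in enumeration order.
#' @return A numeric vector of log-probabilities.
#' @export
pattern_logprob <- function(model, x = NULL) {
  stopifnot(inherits(model, "marginal_model"))
  logg <- pattern_stats(model, want_grad = FALSE)$logg
  if (is.null(x)) {
    return(logg)
  }
  logg[pattern_row_index(model, x)]
}

pattern_row_index <- function(model, x) {
  param <- model$param
  grp <- 1L
  if (param$family == "dif_two_group") {
    stopifnot(is.list(x), !is.null(x$group))
    grp <- as.integer(x$group)
    x <- x$x
  }
  x <- as.integer(x)
  if (length(x) != param$n_items) stop("pattern length must equal the number of items")
  K <- param$n_categories
  idx <- sum(x * K^((param$n_items - 1):0)) + 1L
  P <- K^param$n_items
  idx + (grp - 1L) * P
}

#' Score vector and Hessian of the marginal log-likelihood of one pattern
#'
#' The gradient \eqn{\dot{l}_\beta(x)} is computed analytically by
#' differentiating under the quadrature sum (the posterior-weighted
#' complete-data score identity); the Hessian \eqn{\ddot{l}_\beta(x)} by
#' central finite differences of that analytic gradient with step
#' `1e-5 * max(1, |beta_j|)`, then symmetrized.
#'
#' @inheritParams pattern_logprob
#' @param x A single response pattern (see [pattern_logprob()]).
#' @return A list with elements `gradient` (length `l`) and `hessian`
#'   (`l` x `l`, symmetric).
#' @export
score_and_hessian <- function(model, x) {
  idx <- pattern_row_index(model, x)
  ps <- pattern_stats(model)
  grad <- ps$G[idx, ]
  l <- model$param$length
  H <- matrix(0, l, l)
  for (j in seq_len(l)) {
    h <- 1e-5 * max(1, abs(model$beta[j]))
    bp <- bm <- model$beta
    bp[j] <- bp[j] + h
    bm[j] <- bm[j] - h
    H[, j] <- (pattern_stats(model, bp)$G[idx, ] - pattern_stats(model, bm)$G[idx, ]) / (2 * h)
  }
  H <- (H + t(H)) / 2
  list(gradient = grad, hessian = H)
}
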