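#' Simulate response matrices from a marginal IRT model
#'
#' Draws each person's latent trait from the latent distribution (per group
#' for two-group layouts), then each item response independently from the
#' item response function given that trait -- the local independence
#' assumption of the models. Normal latent distributions are sampled
#' directly; tabulated ones from their discrete support.
#'
#' @param beta Item parameters (stacked vector) or an item-parameter data
#'   frame.
#' @param param An [item_parametrization()] (inferred from a data frame
#'   `beta`).
#' @param latent Latent trait distribution.
#' @param n Number of persons.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @param group_weights Group membership probabilities for two-group layouts.
#' @return A [response_data()].
#' @examples
#' d <- simulate_responses(c(1, 0, 1, 0.5), item_parametrization("two_pl", 2),
#'   n = 100, seed = 1
#' )
#' head(d$responses)
#' @export
simulate_responses <- function(beta, param = NULL, latent = latent_normal(),
                               n, seed = NULL, group_weights = c(0.5, 0.5)) {
  if (is.data.frame(beta)) {
    if (is.null(param)) param <- infer_parametrization(tibble::as_tibble(beta))
    beta <- unname(beta_from_items(beta, param))
  }
  stopifnot(!is.null(param), length(beta) == param$length, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- draw_theta(latent, n)
  if (param$family == "dif_two_group") {
    gw <- group_weights / sum(group_weights)
    group <- sample(1:2, n, replace = TRUE, prob = gw)
    I <- param$n_items
    grp <- dif_group_items(beta, I)
    X <- matrix(0L, n, I)
    for (gi in 1:2) {
      rows <- which(group == gi)
      if (!length(rows)) next
      gpar <- grp[[gi]]
      for (i in seq_len(I)) {
        p <- prob_2pl(gpar$a[i], gpar$d[i], theta[rows])
        X[rows, i] <- as.integer(stats::runif(length(rows)) < p)
      }
    }
    return(response_data(X, group = group))
  }
  I <- param$n_items
  K <- param$n_categories
  X <- matrix(0L, n, I)
  if (param$family == "two_pl") {
    a <- beta[seq(1, 2 * I, by = 2)]
    d <- beta[seq(2, 2 * I, by = 2)]
    for (i in seq_len(I)) {
      X[, i] <- as.integer(stats::runif(n) < prob_2pl(a[i], d[i], theta))
    }
  } else {
    for (i in seq_len(I)) {
      d_i <- c(0, beta[(i - 1) * K + 2:K])
      a_i <- beta[(i - 1) * K + 1]
      p <- prob_gpcm(a_i, d_i, theta) # n x K
      u <- stats::runif(n)
      X[, i] <- as.integer(rowSums(u > t(apply(p, 1, cumsum))) )
      # rowSums over exceeded cumulative bins yields the 0-based category
    }
  }
  response_data(X)
}

draw_theta <- function(latent, n) {
  if (latent$kind == "normal") {
    stats::rnorm(n, latent$mean, latent$sd)
  } else {
    sample(latent$nodes, n, replace = TRUE, prob = latent$weights)
  }
}

#' Simulation-study conditions and their parameter recipes
#'
#' `sim_condition()` describes one cell of the validation grid: hypothesis
#' type (Rasch-vs-2PL, two-group DIF, PCM-vs-GPCM), number of items (5, 10,
#' 20, or 50), sample size (100 to 3000), and effect size ("no", "small",
#' "large"). The full cross has 3 x 4 x 5 x 3 = 180 conditions;
#' `sim_grid()` enumerates it.
#'
#' `draw_condition_parameters()` draws generating item parameters for a
#' condition: intercepts standard normal; slopes lognormal with natural-scale
#' mean 1 and an effect- and length-dependent natural-scale standard
#' deviation (0.22/0.17/0.12/0.10 for large, 0.16/0.12/0.08/0.05 for small
#' effects at 5/10/20/50 items); for DIF the first item is fixed at
#' (1.125, 0.125) vs (0.875, -0.125) for the small and group differences of
#' 0.5 in both parameters for the large effect, with anchor slopes lognormal
#' with SD 0.1. "No effect" conditions satisfy the null constraint exactly
#' (common unit slope; identical groups).
#'
#' @param hypothesis_type One of `"rasch_2pl"`, `"dif"`, `"pcm_gpcm"`.
#' @param n_items Number of items: 5, 10, 20, or 50.
#' @param n Sample size: 100, 250, 500, 1000, or 3000.
#' @param effect Effect size: `"no"`, `"small"`, `"large"`.
#' @param seed Integer seed; defaults to a hash of the condition so the full
#'   grid is reproducible without stored fixtures.
#' @param n_categories Categories for `"pcm_gpcm"` (default 3).
#' @return `sim_condition()`: a `sim_condition` object. `sim_grid()`: a
#'   tibble of all 180 conditions. `draw_condition_parameters()`: a list
#'   with `beta`, `param`, and `hypothesis`.
#' @export
sim_condition <- function(hypothesis_type = c("rasch_2pl", "dif", "pcm_gpcm"),
                          n_items, n, effect = c("no", "small", "large"),
                          seed = NULL, n_categories = 3) {
  hypothesis_type <- match.arg(hypothesis_type)
  effect <- match.arg(effect)
  stopifnot(n_items %in% c(5, 10, 20, 50), n %in% c(100, 250, 500, 1000, 3000))
  if (is.null(seed)) seed <- condition_seed(hypothesis_type, n_items, n, effect)
  structure(
    list(
      hypothesis_type = hypothesis_type, n_items = as.integer(n_items),
      n = as.integer(n), effect = effect, seed = as.integer(seed),
      n_categories = as.integer(if (hypothesis_type == "pcm_gpcm") n_categories else 2)
    ),
    class = "sim_condition"
  )
}

# Deterministic small-integer seed from the condition label.
condition_seed <- function(type, n_items, n, effect) {
  s <- utf8ToInt(paste(type, n_items, n, effect, sep = "_"))
  as.integer(sum(s * seq_along(s)) %% 100000L + 1L)
}

#' @rdname sim_condition
#' @export
sim_grid <- function() {
  tidyr::expand_grid(
    hypothesis_type = c("rasch_2pl", "dif", "pcm_gpcm"),
    n_items = c(5L, 10L, 20L, 50L),
    n = c(100L, 250L, 500L, 1000L, 3000L),
    effect = c("no", "small", "large")
  )
}

# Natural-scale lognormal: mean m, standard deviation s.
rlnorm_meansd <- function(n, m, s) {
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

slope_sd <- function(n_items, effect) {
  sds <- list(
    large = c(`5` = 0.22, `10` = 0.17, `20` = 0.12, `50` = 0.10),
    small = c(`5` = 0.16, `10` = 0.12, `20` = 0.08, `50` = 0.05)
  )
  sds[[effect]][[as.character(n_items)]]
}

#' @rdname sim_condition
#' @param cond A `sim_condition`.
#' @export
draw_condition_parameters <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  set.seed(cond$seed)
  I <- cond$n_items
  type <- cond$hypothesis_type
  if (type == "rasch_2pl") {
    a <- if (cond$effect == "no") rep(1, I) else rlnorm_meansd(I, 1, slope_sd(I, cond$effect))
    d <- stats::rnorm(I)
    param <- item_parametrization("two_pl", I)
    beta <- as.vector(rbind(a, d))
    h <- rasch_vs_2pl(I)
  } else if (type == "dif") {
    anchors_a <- rlnorm_meansd(I - 1, 1, 0.1)
    anchors_d <- stats::rnorm(I - 1)
    item1 <- switch(cond$effect,
      no = c(1, 0, 1, 0),
      small = c(1.125, 0.125, 0.875, -0.125),
      large = c(1.25, 0.25, 0.75, -0.25)
    )
    param <- item_parametrization("dif_two_group", I)
    beta <- c(item1, as.vector(rbind(anchors_a, anchors_d)))
    h <- dif_first_item(I)
  } else {
    K <- cond$n_categories
    a <- if (cond$effect == "no") rep(1, I) else rlnorm_meansd(I, 1, slope_sd(I, cond$effect))
    param <- item_parametrization("gpcm", I, n_categories = K)
    beta <- numeric(I * K)
    for (i in seq_len(I)) {
      beta[(i - 1) * K + 1] <- a[i]
      beta[(i - 1) * K + 2:K] <- stats::rnorm(K - 1)
    }
    h <- pcm_vs_gpcm(I, K)
  }
  list(beta = beta, param = param, hypothesis = h)
}

#' @rdname sim_condition
#' @export
simulate_condition <- function(cond) {
  pars <- draw_condition_parameters(cond)
  simulate_responses(pars$beta, pars$param, n = cond$n, seed = cond$seed + 1L)
}
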