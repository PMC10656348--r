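#' Item response functions
#'
#' `prob_2pl()` is the two-parameter logistic item response function in the
#' slope/intercept parametrization: the probability of a correct (category 1)
#' response is \eqn{1 / (1 + \exp(-(a\theta + d)))}. `prob_gpcm()` is the
#' generalized partial credit response function for `K` ordered categories,
#' \eqn{P(x = k) \propto \exp((k-1) a \theta + d_k)} for \eqn{k = 1, \dots, K},
#' with the first intercept fixed at zero for identification.
#'
#' Both functions are vectorized over `theta`.
#'
#' @param a Slope parameter.
#' @param d Intercept parameter (scalar for `prob_2pl()`; a length-`K` vector
#'   with first entry 0 for `prob_gpcm()`).
#' @param theta Latent trait value(s).
#' @return `prob_2pl()`: probabilities in (0, 1), same length as `theta`.
#'   `prob_gpcm()`: a matrix with `length(theta)` rows and `K` columns whose
#'   rows sum to 1 (a plain vector if `theta` is scalar).
#' @examples
#' prob_2pl(a = 1, d = 0, theta = 0)
#' prob_gpcm(a = 1, d = c(0, 1, -1), theta = 0.5)
#' @export
prob_2pl <- function(a, d, theta) {
  stats::plogis(a * theta + d)
}

#' @rdname prob_2pl
#' @export
prob_gpcm <- function(a, d, theta) {
  K <- length(d)
  stopifnot(K >= 2)
  if (d[1] != 0) {
    stop("first intercept of a GPCM item must be fixed at 0 for identification")
  }
  eta <- outer(theta, 0:(K - 1) * a) + rep(d, each = length(theta))
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  if (length(theta) == 1L) drop(p) else p
}

#' Parameter-vector layouts for supported model families
#'
#' An `item_parametrization` fixes the order in which item parameters are
#' stacked into the single vector \eqn{\beta} that every linear hypothesis,
#' information matrix, and test statistic in this package operates on.
#'
#' Layouts:
#' \describe{
#' \item{`two_pl`}{\eqn{(a_1, d_1, \dots, a_I, d_I)}, length `2 * I`.}
#' \item{`gpcm`}{per item a slope followed by the `K - 1` free intercepts
#'   \eqn{(a_i, d_{i2}, \dots, d_{iK})}; the first intercept of each item is
#'   fixed at 0 and not stored. Length `I * K`.}
#' \item{`dif_two_group`}{a dichotomous two-group layout in which the first
#'   item's parameters are duplicated per group,
#'   \eqn{(a_{1A}, d_{1A}, a_{1B}, d_{1B}, a_2, d_2, \dots, a_I, d_I)},
#'   length `2 * I + 2`; items 2..I are shared anchors.}
#' }
#'
#' Restricted (equal-slope) models -- Rasch within `two_pl`, PCM within
#' `gpcm` -- are represented in this same full-length space through equality
#' constraints, so that design matrices, covariance matrices and statistics
#' all live in one coordinate system.
#'
#' @param family One of `"two_pl"`, `"gpcm"`, `"dif_two_group"`.
#' @param n_items Number of items `I`.
#' @param n_categories Number of response categories `K` (2 for the
#'   dichotomous families).
#' @return An object of class `item_parametrization` with fields `family`,
#'   `n_items`, `n_categories`, `length` (of beta), and `layout`, a tibble
#'   with one row per slot of beta (columns `slot`, `item`, `role`, `group`).
#' @examples
#' item_parametrization("two_pl", n_items = 5)
#' parameter_count(item_parametrization("two_pl", 5), restricted = TRUE)
#' @export
item_parametrization <- function(family = c("two_pl", "gpcm", "dif_two_group"),
                                 n_items,
                                 n_categories = 2) {
  family <- match.arg(family)
  stopifnot(n_items >= 1, n_categories >= 2)
  if (family %in% c("two_pl", "dif_two_group") && n_categories != 2) {
    stop("family '", family, "' is dichotomous (n_categories = 2)")
  }
  layout <- switch(family,
    two_pl = tibble::tibble(
      item = rep(seq_len(n_items), each = 2),
      role = rep(c("a", "d"), n_items),
      group = NA_character_
    ),
    gpcm = tibble::tibble(
      item = rep(seq_len(n_items), each = n_categories),
      role = rep(c("a", paste0("d", 2:n_categories)), n_items),
      group = NA_character_
    ),
    dif_two_group = tibble::tibble(
      item = c(1L, 1L, 1L, 1L, rep(seq_len(n_items)[-1], each = 2)),
      role = c("a", "d", "a", "d", rep(c("a", "d"), n_items - 1)),
      group = c("A", "A", "B", "B", rep(NA_character_, 2 * (n_items - 1)))
    )
  )
  layout <- tibble::add_column(layout, slot = seq_len(nrow(layout)), .before = 1)
  structure(
    list(
      family = family, n_items = as.integer(n_items),
      n_categories = as.integer(n_categories),
      length = nrow(layout), layout = layout
    ),
    class = "item_parametrization"
  )
}

#' @export
print.item_parametrization <- function(x, ...) {
  cat("<item_parametrization> ", x$family, ": I = ", x$n_items,
    ", K = ", x$n_categories, ", length(beta) = ", x$length, "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of identifiable parameters of a model family
#'
#' Counts the free parameters of the unrestricted model, or of the
#' equal-slope restricted model (Rasch within 2PL, PCM within GPCM) in which
#' all slopes share one common value. Under marginal estimation the Rasch
#' model has one slope plus `I` intercepts, i.e. `I + 1` parameters.
#'
#' @param param An [item_parametrization()].
#' @param restricted If `TRUE`, count the parameters of the equal-slope
#'   restricted model.
#' @return Integer parameter count.
#' @export
parameter_count <- function(param, restricted = FALSE) {
  stopifnot(inherits(param, "item_parametrization"))
  I <- param$n_items
  K <- param$n_categories
  switch(param$family,
    two_pl = if (restricted) I + 1L else 2L * I,
    gpcm = if (restricted) I * (K - 1L) + 1L else I * K,
    dif_two_group = {
      if (restricted) {
        stop("no equal-slope restriction is defined for the DIF layout")
      }
      2L * I + 2L
    }
  )
}

#' Convert between item-parameter tables and the stacked beta vector
#'
#' The tabular form has one row per item (and per group for the group-specific
#' item of a DIF layout) with columns `item`, optional `group`, `a`, and the
#' intercepts: `d` (alias `d1`) for dichotomous families, `d2`..`dK` for the
#' GPCM.
#'
#' @param items A data frame of item parameters.
#' @param param An [item_parametrization()]. For `beta_from_items()` it may be
#'   omitted and is then inferred from the table.
#' @param beta A numeric parameter vector laid out as in `param`.
#' @return `beta_from_items()`: a named numeric vector. `items_from_beta()`:
#'   a tibble.
#' @examples
#' items <- tibble::tibble(item = 1:3, a = c(1, 1.2, 0.8), d = c(0, 0.5, -0.5))
#' beta <- beta_from_items(items)
#' items_from_beta(beta, item_parametrization("two_pl", 3))
#' @export
beta_from_items <- function(items, param = NULL) {
  items <- tibble::as_tibble(items)
  if (!"d" %in% names(items) && "d1" %in% names(items)) {
    names(items)[names(items) == "d1"] <- "d"
  }
  if (is.null(param)) param <- infer_parametrization(items)
  lay <- param$layout
  beta <- numeric(param$length)
  grp_blank <- if (!"group" %in% names(items)) rep(TRUE, nrow(items)) else is_blank(items[["group"]])
  for (s in seq_len(nrow(lay))) {
    it <- lay$item[s]
    grp <- lay$group[s]
    row <- if (is.na(grp)) {
      which(items$item == it & grp_blank)
    } else {
      which(items$item == it & !grp_blank & items$group == grp)
    }
    if (length(row) != 1L) {
      stop("could not match item ", it, if (!is.na(grp)) paste0(" group ", grp),
        " uniquely in the parameter table"
      )
    }
    col <- if (lay$role[s] == "d") "d" else lay$role[s]
    beta[s] <- items[[col]][row]
  }
  names(beta) <- layout_names(param)
  beta
}

#' @rdname beta_from_items
#' @export
items_from_beta <- function(beta, param) {
  stopifnot(length(beta) == param$length)
  lay <- param$layout
  lay$value <- as.numeric(beta)
  key <- dplyr::distinct(lay, .data$item, .data$group)
  rows <- purrr::pmap(key, function(item, group) {
    sel <- lay$item == item &
      (if (is.na(group)) is.na(lay$group) else !is.na(lay$group) & lay$group == group)
    sub <- lay[sel, ]
    vals <- stats::setNames(as.list(sub$value), ifelse(sub$role == "d", "d", sub$role))
    tibble::as_tibble(c(list(item = item, group = group), vals))
  })
  dplyr::bind_rows(rows)
}

layout_names <- function(param) {
  lay <- param$layout
  paste0(
    lay$role, "_", lay$item,
    ifelse(is.na(lay$group), "", lay$group)
  )
}

is_blank <- function(x) {
  if (is.null(x)) return(TRUE)
  is.na(x) | x == ""
}

infer_parametrization <- function(items) {
  has_group <- "group" %in% names(items) && any(!is_blank(items$group))
  dcols <- grep("^d[0-9]*$", names(items), value = TRUE)
  K <- if (any(grepl("^d[2-9]", dcols))) max(as.integer(sub("d", "", setdiff(dcols, "d")))) else 2L
  I <- length(unique(items$item))
  if (has_group) {
    item_parametrization("dif_two_group", n_items = I)
  } else if (K > 2) {
    item_parametrization("gpcm", n_items = I, n_categories = K)
  } else {
    item_parametrization("two_pl", n_items = I)
  }
}

#' Read or write an item-parameter table
#'
#' Plain-CSV interchange for item parameters: columns `item`, optional
#' `group`, `a`, and `d` (or `d1`) for dichotomous items, `d2`..`dK` for
#' polytomous items; one header row.
#'
#' @param path File path.
#' @param items A data frame of item parameters.
#' @return `read_item_params()` returns a tibble; `write_item_params()`
#'   returns `path` invisibly.
#' @export
read_item_params <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_item_params
#' @export
write_item_params <- function(items, path) {
  utils::write.csv(items, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
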