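#' Linear hypotheses on item parameters
#'
#' A linear hypothesis constrains the stacked item-parameter vector through
#' \eqn{A\beta = c}, where `A` has full row rank `m`; `m` is the degrees of
#' freedom of the associated chi-square tests. `linear_hypothesis()` builds
#' one from an explicit matrix; the constructors below build the three
#' canonical hypotheses.
#'
#' \describe{
#' \item{[rasch_vs_2pl()]}{equal slopes across items in the 2PL layout:
#'   `I - 1` consecutive slope-difference contrasts \eqn{a_i - a_{i+1} = 0}.}
#' \item{[dif_first_item()]}{equal item-1 parameters across two groups in the
#'   DIF layout: \eqn{a_{1A} - a_{1B} = 0}, \eqn{d_{1A} - d_{1B} = 0}
#'   (2 degrees of freedom).}
#' \item{[pcm_vs_gpcm()]}{equal slopes across items in the GPCM layout, the
#'   polytomous analogue of the Rasch-vs-2PL contrast.}
#' }
#'
#' @param A An `m x l` numeric matrix of full row rank.
#' @param c A numeric vector of length `m` of constants (defaults to zeros).
#' @param description Free-text label.
#' @return An object of class `linear_hypothesis` with fields `A`, `c`, `df`,
#'   and `description`.
#' @examples
#' h <- rasch_vs_2pl(5)
#' h$df
#' @export
linear_hypothesis <- function(A, c = rep(0, nrow(A)), description = "") {
  A <- as.matrix(A)
  stopifnot(is.numeric(A), length(c) == nrow(A))
  if (qr(t(A), tol = 1e-10)$rank < nrow(A)) {
    stop("hypothesis matrix A must have full row rank; ",
         "rank-deficient constraints corrupt the degrees of freedom")
  }
  structure(
    list(A = A, c = as.numeric(c), df = nrow(A), description = description),
    class = "linear_hypothesis"
  )
}

#' @export
print.linear_hypothesis <- function(x, ...) {
  cat("<linear_hypothesis> ", x$description,
    " (df = ", x$df, ", l = ", ncol(x$A), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname linear_hypothesis
#' @param I Number of items.
#' @export
rasch_vs_2pl <- function(I) {
  stopifnot(I >= 2)
  A <- matrix(0, I - 1, 2 * I)
  for (r in seq_len(I - 1)) {
    A[r, 2 * r - 1] <- 1
    A[r, 2 * r + 1] <- -1
  }
  linear_hypothesis(A, description = sprintf("Rasch vs 2PL, equal slopes (I = %d)", I))
}

#' @rdname linear_hypothesis
#' @export
dif_first_item <- function(I) {
  stopifnot(I >= 2)
  l <- 2 * I + 2
  A <- matrix(0, 2, l)
  A[1, 1] <- 1
  A[1, 3] <- -1
  A[2, 2] <- 1
  A[2, 4] <- -1
  linear_hypothesis(A, description = sprintf("no DIF on item 1 (I = %d)", I))
}

#' @rdname linear_hypothesis
#' @param K Number of response categories.
#' @export
pcm_vs_gpcm <- function(I, K) {
  stopifnot(I >= 2, K >= 2)
  A <- matrix(0, I - 1, I * K)
  for (r in seq_len(I - 1)) {
    A[r, (r - 1) * K + 1] <- 1
    A[r, r * K + 1] <- -1
  }
  linear_hypothesis(A, description = sprintf("PCM vs GPCM, equal slopes (I = %d, K = %d)", I, K))
}

#' Test whether two hypotheses are reparametrizations of each other
#'
#' Two hypothesis matrices describe the same constraint set iff one is an
#' invertible row transformation of the other, `A2 = C A1` with `c2 = C c1`.
#' The Wald and gradient statistics (and, because the implied models agree,
#' the likelihood-ratio and score statistics) are invariant under such
#' replacements.
#'
#' @param h1,h2 Two [linear_hypothesis()] objects over the same parameter
#'   length.
#' @param tol Numerical tolerance for the row-space comparison.
#' @return `TRUE` or `FALSE`.
#' @export
equivalent_under_reparametrization <- function(h1, h2, tol = 1e-8) {
  stopifnot(inherits(h1, "linear_hypothesis"), inherits(h2, "linear_hypothesis"))
  if (ncol(h1$A) != ncol(h2$A)) stop("hypotheses refer to parameter vectors of different length")
  if (h1$df != h2$df) {
    return(FALSE)
  }
  # C = A2 A1' (A1 A1')^-1 is the only candidate row transformation
  C <- h2$A %*% t(h1$A) %*% solve(h1$A %*% t(h1$A))
  ok_A <- max(abs(h2$A - C %*% h1$A)) < tol
  ok_c <- max(abs(h2$c - C %*% h1$c)) < tol
  ok_inv <- abs(det(C)) > tol
  ok_A && ok_c && ok_inv
}

#' Read or write a hypothesis as JSON
#'
#' Interchange format for user-defined hypotheses:
#' `{"A": [[...]], "c": [...], "description": "..."}`.
#'
#' @param path File path.
#' @param h A [linear_hypothesis()].
#' @export
read_hypothesis_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_hypothesis(
    A = as.matrix(obj$A),
    c = if (is.null(obj$c)) rep(0, nrow(as.matrix(obj$A))) else obj$c,
    description = if (is.null(obj$description)) "" else obj$description
  )
}

#' @rdname read_hypothesis_json
#' @export
write_hypothesis_json <- function(h, path) {
  jsonlite::write_json(
    list(A = h$A, c = h$c, description = h$description),
    path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
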