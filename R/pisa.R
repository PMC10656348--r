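#' PISA 2015 mathematics item parameters (M1 and M2 clusters)
#'
#' Published slope/intercept parameters of the dichotomous items in two PISA
#' 2015 mathematics item clusters, fitted with the 2PL model (the 2PL was
#' applied only to items that fit the Rasch model poorly, which is why many
#' slopes are exactly 1). These tables are the worked example for the
#' Rasch-vs-2PL and DIF power analyses: M1 has 10 items, M2 has 9.
#'
#' @return A tibble with columns `item`, `a`, `d`.
#' @examples
#' pisa_m1()
#' @export
pisa_m1 <- function() {
  tibble::tibble(
    item = 1:10,
    a = c(1.00, 1.00, 1.00, 1.00, 1.43, 0.69, 1.70, 1.48, 1.00, 1.00),
    d = c(0.96, 0.67, 0.67, 0.28, 0.11, -0.04, -0.87, -0.65, -0.25, 0.09)
  )
}

#' @rdname pisa_m1
#' @export
pisa_m2 <- function() {
  tibble::tibble(
    item = 1:9,
    a = c(0.62, 1.00, 1.00, 0.59, 1.78, 2.30, 0.76, 1.00, 0.63),
    d = c(-0.09, 0.02, 0.61, 0.91, -0.91, -1.80, -0.25, -0.03, 0.03)
  )
}

#' Two-group DIF alternative built on the M1 cluster
#'
#' The DIF worked example: group A responds according to the M1 parameters;
#' group B differs on item 1 only, with slope `a` and intercept `d` as
#' given (defaults: a harder, more discriminating first item, a = 1.2,
#' d = 0.5). Items 2-10 are shared anchors.
#'
#' @param a_b,d_b Group-B parameters of item 1.
#' @return A tibble in the two-group layout accepted by [marginal_model()]:
#'   columns `item`, `group`, `a`, `d` with item 1 duplicated per group.
#' @export
pisa_m1_dif <- function(a_b = 1.2, d_b = 0.5) {
  m1 <- pisa_m1()
  dplyr::bind_rows(
    tibble::tibble(item = 1L, group = c("A", "B"),
                   a = c(m1$a[1], a_b), d = c(m1$d[1], d_b)),
    dplyr::mutate(m1[-1, ], group = NA_character_)
  )
}
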