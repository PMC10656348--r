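# Small model builders shared across tests.

two_item_model <- function(a = c(1, 1.3), d = c(0.2, -0.4),
                           latent = latent_normal()) {
  marginal_model(as.vector(rbind(a, d)),
    param = item_parametrization("two_pl", 2), latent = latent
  )
}

five_item_beta <- function() {
  c(0.8, 0.2, 1.2, -0.4, 1.0, 0.1, 1.3, 0.6, 0.7, -0.5)
}

# Independent scalar marginal probability for a dichotomous pattern:
# integrate the conditional pattern probability against the normal density
# with stats::integrate (adaptive; no quadrature sharing with the package).
integrate_pattern <- function(a, d, x) {
  f <- function(th) {
    p <- vapply(th, function(t) prod(stats::plogis((a * t + d) * ifelse(x == 1, 1, -1))), 0)
    p * stats::dnorm(th)
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
}
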