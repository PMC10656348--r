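# Brute-force oracle for small dichotomous models: every sum over the
# pattern space is an explicit loop, every integral a 1-D adaptive
# quadrature, and derivatives use hand-written formulas -- fully independent
# of the package's quadrature, vectorization, and optimizer.
#
# The Wald and score forms need the inverse expected information, which
# exists only when the parameter count 2I does not exceed the multinomial
# degrees of freedom 2^I - 1; with two items the model is unidentified
# (4 parameters, 3 degrees of freedom), so the information-based statistics
# are exercised at I = 3 and the information-free pair (LR, gradient) also
# at I = 2.
oracle_ncp <- function(a, d, statistics = c("wald", "lr", "score", "gradient")) {
  I <- length(a)
  patterns <- as.matrix(expand.grid(rep(list(0:1), I)))
  beta <- as.vector(rbind(a, d))
  g_of <- function(beta) {
    aa <- beta[seq(1, 2 * I, 2)]
    dd <- beta[seq(2, 2 * I, 2)]
    apply(patterns, 1, function(x) integrate_pattern(aa, dd, x))
  }
  dg_of <- function(beta) {
    aa <- beta[seq(1, 2 * I, 2)]
    dd <- beta[seq(2, 2 * I, 2)]
    t(apply(patterns, 1, function(x) {
      vapply(seq_len(2 * I), function(j) {
        i <- ceiling(j / 2)
        f <- function(th) {
          p <- stats::plogis(outer(aa, th) + dd) # I x length(th)
          lik <- apply(p^x * (1 - p)^(1 - x), 2, prod)
          s <- x[i] - p[i, ]
          if (j %% 2 == 1) s <- s * th
          lik * s * stats::dnorm(th)
        }
        stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value
      }, 0)
    }))
  }
  g_alt <- g_of(beta)
  opt <- stats::optim(c(mean(a), d), function(p) {
    -sum(g_alt * log(g_of(as.vector(rbind(rep(p[1], I), p[-1])))))
  }, method = "BFGS", control = list(reltol = 1e-15, maxit = 2000))
  beta_r <- as.vector(rbind(rep(opt$par[1], I), opt$par[-1]))
  A <- rasch_vs_2pl(I)$A
  out <- c()
  if ("wald" %in% statistics) {
    L_alt <- dg_of(beta) / g_alt
    I_alt <- t(L_alt) %*% (L_alt * g_alt)
    r <- as.vector(A %*% beta)
    out["wald"] <- as.numeric(t(r) %*% solve(A %*% solve(I_alt) %*% t(A), r))
  }
  g_r <- g_of(beta_r)
  L_r <- dg_of(beta_r) / g_r
  sbar <- as.vector(t(L_r) %*% g_alt)
  out["lr"] <- 2 * sum(g_alt * (log(g_alt) - log(g_r)))
  if ("score" %in% statistics) {
    I_r <- t(L_r) %*% (L_r * g_r)
    out["score"] <- as.numeric(t(sbar) %*% solve(I_r, sbar))
  }
  out["gradient"] <- sum(sbar * (beta - beta_r))
  out
}
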