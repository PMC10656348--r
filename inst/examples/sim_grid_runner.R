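# Scaled-down validation grid: expected vs observed rejection rates.
#
# The full validation design crosses 3 hypothesis types x 4 item counts x
# 5 sample sizes x 3 effect sizes (180 conditions) with thousands of
# replications per cell. This runner executes an arbitrary subset at a
# reduced replication count so the expected-vs-observed comparison can be
# reproduced on a laptop. Usage:
#
#   Rscript sim_grid_runner.R [n_reps] [max_conditions]
#
# Defaults: 200 replications over a 6-condition spot-check subset
# (5/10 items, all effect sizes, n in {500, 3000}, Rasch-vs-2PL and DIF).
# Output: one row per condition with the expected hit rate (analytical
# noncentrality) and the observed hit rate, plus the 99% envelope.

suppressMessages({
  library(mmlpower)
  library(dplyr)
})

argv <- commandArgs(trailingOnly = TRUE)
n_reps <- if (length(argv) >= 1) as.integer(argv[1]) else 200L
max_conditions <- if (length(argv) >= 2) as.integer(argv[2]) else 6L

subset <- sim_grid() |>
  filter(n_items %in% c(5, 10), n %in% c(500, 3000)) |>
  filter(hypothesis_type != "pcm_gpcm") |>
  slice_head(n = max_conditions)

run_condition <- function(hypothesis_type, n_items, n, effect, n_reps) {
  cond <- sim_condition(hypothesis_type, n_items, n, effect)
  pars <- draw_condition_parameters(cond)
  expected <- ncp(
    marginal_model(pars$beta, param = pars$param),
    pars$hypothesis
  )$lambda
  crit <- qchisq(0.95, pars$hypothesis$df)
  set.seed(cond$seed + 1L)
  rej <- matrix(NA, n_reps, 4)
  for (r in seq_len(n_reps)) {
    data <- simulate_responses(pars$beta, pars$param, n = n)
    rej[r, ] <- observed_statistics(data, pars$param, pars$hypothesis)$value > crit
  }
  tibble::tibble(
    hypothesis_type, n_items, n, effect,
    statistic = names(expected),
    expected_hit = power_at_n(expected, pars$hypothesis$df, n),
    observed_hit = colMeans(rej),
    envelope = confidence_envelope(n_reps, power_at_n(expected, pars$hypothesis$df, n))
  )
}

results <- purrr::pmap_dfr(subset, run_condition, n_reps = n_reps)
results <- mutate(results,
  within = abs(observed_hit - expected_hit) <= envelope
)
print(as.data.frame(results), digits = 3)
cat(sprintf(
  "\n%d of %d condition-statistic cells inside the 99%% envelope\n",
  sum(results$within), nrow(results)
))
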