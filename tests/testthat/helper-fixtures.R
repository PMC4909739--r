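# Shared fixtures: small simulated experiments and hand-built tables.

fit_default_sim <- function(seed = 1, cv = 0, n_reps = 5L, ...) {
  cfg <- default_sim_config(seed = seed, cv = cv)
  cfg$n_reps <- as.integer(n_reps)
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  sim <- simulate_pot_experiment(cfg)
  fit <- partition_p32(sim$observations, sim$labeling,
                       doses = c(TSP = 50, TCSS = 50),
                       seed_budgets = sim$seed_budgets,
                       reference = "TSP")
  list(sim = sim, fit = fit)
}

cumulative_truth <- function(sim) {
  gt <- sim$ground_truth
  gt[gt$scope == "cumulative", ]
}

# published cumulative means as partition_aggregate input
published_means <- function() {
  pub <- tcss_published_summary()
  pub[, c("treatment", "Pt", "r_over_R", "Pseed", "dose")]
}
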