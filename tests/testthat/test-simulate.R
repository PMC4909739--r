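test_that("the generator is reproducible and refuses to run unseeded", {
  a <- simulate_pot_experiment(default_sim_config(seed = 101))
  b <- simulate_pot_experiment(default_sim_config(seed = 101))
  expect_identical(a$observations, b$observations)
  expect_identical(a$seed_budgets, b$seed_budgets)
  c <- simulate_pot_experiment(default_sim_config(seed = 102))
  expect_false(identical(a$observations$shoot_p_mg_kg,
                         c$observations$shoot_p_mg_kg))
  expect_error(default_sim_config(seed = NULL), "seed")
  expect_error(incubation_config(seed = NULL), "seed")
})

test_that("simulated plant activity never exceeds the introduced label", {
  for (s in c(1, 7, 23)) {
    sim <- simulate_pot_experiment(default_sim_config(seed = s, cv = 0.2))
    tot <- tapply(sim$observations$activity_bq_kg, sim$observations$pot_id,
                  sum)
    expect_true(all(tot <= sim$labeling$activity_bq_per_kg))
  }
})

test_that("seed budgets reproduce the configured shoot allocation exactly", {
  sim <- simulate_pot_experiment(default_sim_config(seed = 6))
  sb <- sim$seed_budgets
  alloc <- seed_p_allocated(sb$sown_seed_p, sb$residual_seed_p,
                            sb$shoot_p, sb$root_p, sb$collet_p)
  want <- vapply(sim$config$treatments[sb$treatment],
                 function(tr) tr$seed_alloc, 0)
  expect_equal(unname(alloc), unname(want), tolerance = 1e-12)
})

test_that("ground truth is internally consistent with the generating model", {
  sim <- simulate_pot_experiment(default_sim_config(seed = 12))
  gt <- sim$ground_truth
  expect_equal(gt$Pseed + gt$Psoil + gt$Pfert, gt$Pt, tolerance = 1e-12)
  cum <- gt[gt$scope == "cumulative", ]
  per <- gt[gt$scope == "per_cut", ]
  for (tr in unique(gt$treatment)) {
    expect_equal(cum$Pt[cum$treatment == tr],
                 sum(per$Pt[per$treatment == tr]))
  }
  # default truth carries the published cumulative magnitudes
  expect_equal(cum$Pt, c(4.6, 19.7, 12.5), tolerance = 0.01)
  expect_equal(cum$Pdff[cum$treatment == "TSP"], 55)
  expect_equal(cum$Pdff[cum$treatment == "TCSS"], 56)
})

test_that("violation of the equal-SA assumption biases Psoil as derived", {
  # soil-pool SA multiplier m on a fertilized treatment makes the
  # estimated Psoil equal m * truth: bias = (m - 1) * Psoil_true
  for (m in c(0.7, 0.8, 1.2)) {
    cfg <- default_sim_config(seed = 15, cv = 0)
    cfg$treatments$TCSS$sa_multiplier <- m
    sim <- simulate_pot_experiment(cfg)
    fit <- partition_p32(sim$observations, sim$labeling,
                         doses = c(TSP = 50, TCSS = 50),
                         seed_budgets = sim$seed_budgets)
    truth <- cumulative_truth(sim)
    ps_true <- truth$Psoil[truth$treatment == "TCSS"]
    ps_hat <- fit$cumulative$Psoil[fit$cumulative$treatment == "TCSS"]
    expect_equal(ps_hat - ps_true, (m - 1) * ps_true, tolerance = 1e-8)
    # Pfert absorbs the opposite bias through the mass balance
    pf_true <- truth$Pfert[truth$treatment == "TCSS"]
    pf_hat <- fit$cumulative$Pfert[fit$cumulative$treatment == "TCSS"]
    expect_equal(pf_hat - pf_true, -(m - 1) * ps_true, tolerance = 1e-8)
  }
})

test_that("incubation simulator is deterministic and guards the trap", {
  a <- simulate_incubation(incubation_config(seed = 5, titration_sd_ml = 0.05))
  b <- simulate_incubation(incubation_config(seed = 5, titration_sd_ml = 0.05))
  expect_identical(a$titrations, b$titrations)
  huge <- incubation_config(
    treatments = list(hot = list(basal = 200, A = 0, k = 0.5)), seed = 1)
  expect_error(simulate_incubation(huge), "saturation")
})

test_that("degree days accumulate temperature above the base", {
  expect_equal(degree_days(rep(25, 4)), 100)
  expect_equal(degree_days(rep(25.67, 27)), 693.09)
  expect_equal(degree_days(c(-5, 3, 10), base = 4), 6)
})

test_that("a fitted partition can parametrically bootstrap new experiments", {
  fx <- fit_default_sim(seed = 2, cv = 0.05)
  boot <- simulate(fx$fit, nsim = 2, seed = 9)
  expect_length(boot, 2)
  expect_s3_class(boot[[1]], "p32_simulation")
  refit <- partition_p32(boot[[1]]$observations, boot[[1]]$labeling,
                         doses = c(TSP = 50, TCSS = 50),
                         seed_budgets = boot[[1]]$seed_budgets)
  # bootstrap magnitudes stay near the fitted ones
  expect_equal(refit$cumulative$Pdff[refit$cumulative$treatment == "TCSS"],
               fx$fit$cumulative$Pdff[fx$fit$cumulative$treatment == "TCSS"],
               tolerance = 0.15)
  expect_error(simulate(fx$fit, seed = NULL), "seed")
})
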