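test_that("cut cumulation sums masses and recomputes ratios", {
  one <- data.frame(treatment = "TSP", cut = 1, Pt = 2, Pseed = 0.5,
                    Psoil = 0.5, Pfert = 1, r_over_R = 5, flags = "")
  cum1 <- cumulate_cuts(one, dose = 50)
  expect_equal(cum1$Pt, 2)
  expect_equal(cum1$Pdff, 50)
  expect_equal(cum1$CPU, 2)

  two <- rbind(one, transform(one, cut = 2))
  cum2 <- cumulate_cuts(two, dose = 50)
  expect_equal(cum2$Pt, 4)
  expect_equal(cum2$Pfert, 2)
  expect_equal(cum2$Pdff, 50)

  # three synthetic cuts against an independent brute-force sum oracle
  set.seed(11)
  d <- data.frame(treatment = "TCSS", cut = 1:3,
                  Pt = runif(3, 1, 8), Pseed = c(0.4, 0, 0),
                  Psoil = runif(3, 0.5, 3), r_over_R = runif(3, 1, 9))
  d$Pfert <- d$Pt - d$Pseed - d$Psoil
  cc <- cumulate_cuts(d, dose = 50)
  expect_equal(cc$Pt, sum(d$Pt))
  expect_equal(cc$Psoil, sum(d$Psoil))
  expect_equal(cc$Pdff, 100 * sum(d$Pfert) / sum(d$Pt))
  expect_equal(cc$SA, (sum(d$r_over_R) / 100) / sum(d$Pt))
  expect_equal(cc$L, sum(d$Pt) / (sum(d$r_over_R) / 100))

  expect_error(cumulate_cuts(transform(two, treatment = c("TSP", "TCSS"))),
               "mix")
  expect_error(cumulate_cuts(transform(two, cut = c(1, 1))), "duplicated")
})

test_that("noise-free partition recovers the generating ground truth exactly", {
  fx <- fit_default_sim(seed = 3, cv = 0)
  truth <- cumulative_truth(fx$sim)
  cum <- fx$fit$cumulative
  for (tr in c("control", "TSP", "TCSS")) {
    got <- cum[cum$treatment == tr, ]
    want <- truth[truth$treatment == tr, ]
    expect_equal(got$Pt, want$Pt, tolerance = 1e-10)
    expect_equal(got$Psoil, want$Psoil, tolerance = 1e-10)
    expect_equal(got$Pfert, want$Pfert, tolerance = 1e-10)
    expect_equal(got$Pdff, want$Pdff, tolerance = 1e-10)
    if (tr != "control") expect_equal(got$CPU, want$CPU, tolerance = 1e-10)
  }
})

test_that("mass balance Pseed + Psoil + Pfert = Pt holds on every row", {
  fx <- fit_default_sim(seed = 5, cv = 0.15)
  pc <- fx$fit$per_cut
  expect_equal(pc$Pseed + pc$Psoil + pc$Pfert, pc$Pt, tolerance = 1e-12)
  pp <- fx$fit$per_pot_cumulative
  expect_equal(pp$Pseed + pp$Psoil + pp$Pfert, pp$Pt, tolerance = 1e-12)
})

test_that("decay correction makes counts comparable across delayed count dates", {
  # same experiment counted immediately vs after a 10-day bench delay
  fx0 <- fit_default_sim(seed = 9, cv = 0, count_delay_days = 0)
  fx10 <- fit_default_sim(seed = 9, cv = 0, count_delay_days = 10)
  expect_equal(fx10$fit$cumulative$r_over_R, fx0$fit$cumulative$r_over_R,
               tolerance = 1e-10)
  expect_equal(fx10$fit$cumulative$Pfert, fx0$fit$cumulative$Pfert,
               tolerance = 1e-10)
  # uncorrected 59-day-old counts would be ~17x too small; sanity-check scale
  raw <- fx10$sim$observations
  expect_true(all(raw$activity_bq_kg <
                    decay_correct(raw$activity_bq_kg,
                                  raw$harvest_day + 10)))
})

test_that("a missing control or reference treatment is a hard error", {
  fx <- fit_default_sim(seed = 2, cv = 0)
  obs <- fx$sim$observations
  expect_error(partition_p32(obs[obs$treatment != "control", ],
                             fx$sim$labeling, doses = c(TSP = 50, TCSS = 50)),
               "control")
  expect_error(partition_p32(obs, fx$sim$labeling,
                             doses = c(TSP = 50, TCSS = 50),
                             reference = "DAP"),
               "reference")
  expect_error(partition_p32(obs[0, ], fx$sim$labeling,
                             doses = c(TSP = 50)), "empty")
})

test_that("negative Pfert estimates are flagged and retained, not clipped", {
  fx <- fit_default_sim(seed = 4, cv = 0)
  obs <- fx$sim$observations
  # inflate one TSP pot's cut-1 activity so Psoil > Pt there
  i <- which(obs$pot_id == "TSP_1" & obs$cut == 1)
  obs$activity_bq_kg[i] <- obs$activity_bq_kg[i] * 10
  fit <- partition_p32(obs, fx$sim$labeling, doses = c(TSP = 50, TCSS = 50),
                       seed_budgets = fx$sim$seed_budgets)
  row <- fit$per_cut[fit$per_cut$pot_id == "TSP_1" & fit$per_cut$cut == 1, ]
  expect_lt(row$Pfert, 0)
  expect_match(row$flags, "negative-Pfert")
  # mass balance still closes on the flagged row
  expect_equal(row$Pseed + row$Psoil + row$Pfert, row$Pt, tolerance = 1e-12)
})

test_that("aggregate-mode chain reproduces ratio quantities from published means", {
  agg <- partition_aggregate(published_means())
  expect_equal(agg$L[agg$treatment == "control"], 38.983, tolerance = 1e-4)
  expect_equal(agg$L[agg$treatment == "TSP"], 98.010, tolerance = 1e-4)
  expect_equal(agg$SA[agg$treatment == "control"], 0.025652, tolerance = 1e-4)
  expect_equal(agg$IC0[1], 2.9648, tolerance = 1e-4)
  # the aggregate chain cannot reproduce the published per-replicate
  # cumulated Psoil/Pfert: it gives the direct-arithmetic values instead
  expect_equal(agg$Psoil[agg$treatment == "TSP"], 6.7795, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(agg$Psoil[agg$treatment == "TSP"], 8.8,
                                tolerance = 0.05)))
})

test_that("fit methods expose coefficients, summaries, and letters", {
  fx <- fit_default_sim(seed = 8, cv = 0.1)
  cm <- coef(fx$fit)
  expect_true(all(c("Pt", "Psoil", "Pfert", "Pdff", "L") %in% colnames(cm)))
  expect_setequal(rownames(cm), c("control", "TSP", "TCSS"))
  sm <- summary(fx$fit)
  expect_s3_class(sm, "summary.p32_partition")
  expect_true("Pt" %in% names(sm$comparisons))
  expect_s3_class(sm$comparisons$Pt, "snk_result")
  expect_output(print(fx$fit), "Isotope-dilution partition")
  ae <- fx$fit$effectiveness
  expect_equal(ae$AE_CPU[ae$treatment == "TSP"], 100)
})
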