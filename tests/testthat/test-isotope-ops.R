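test_that("tracer recovery is a percentage of introduced R and sums over cuts", {
  expect_equal(fraction_recovered(0, 3.7e6), 0)
  expect_equal(fraction_recovered(3.7e6, 3.7e6), 100)
  expect_equal(fraction_recovered(4.366e5, 3.7e6), 11.8, tolerance = 1e-3)
  # additive when activities are summed first
  a <- c(1e5, 2e5, 1.5e5)
  expect_equal(fraction_recovered(sum(a), 3.7e6),
               sum(fraction_recovered(a, 3.7e6)))
  expect_error(fraction_recovered(10, 0), "R")
})

test_that("specific activity and L-value are reciprocal tracer dilutions", {
  expect_equal(specific_activity(11.8, 4.6), 0.02565, tolerance = 1e-3)
  expect_equal(specific_activity(20.1, 19.7), 0.01020, tolerance = 1e-3)
  expect_equal(specific_activity(0, 5.0), 0)
  expect_error(specific_activity(10, 0), "undefined")

  expect_equal(l_value(4.6, 11.8), 38.983, tolerance = 1e-4)
  expect_equal(l_value(19.7, 20.1), 98.010, tolerance = 1e-4)
  expect_equal(l_value(7.3, 100), 7.3)  # full recovery: L equals uptake
  expect_error(l_value(5, 0), "undefined")

  set.seed(7)
  for (i in 1:25) {
    pt <- runif(1, 0.5, 30)
    r <- runif(1, 0.1, 100)
    expect_equal(l_value(pt, r) * specific_activity(r, pt), 1)
    expect_gte(l_value(pt, r), pt)  # L >= Pt whenever recovery <= 100%
  }
})

test_that("seed P allocation follows the shoot share of whole-plant P", {
  expect_equal(seed_p_allocated(1.0, 1.0, shoot_p = 2), 0)
  expect_equal(seed_p_allocated(1.2, 0.3, shoot_p = 3.0, root_p = 1.2,
                                collet_p = 0.3), 0.6)
  # shoot share of 1 allocates the full depletion
  expect_equal(seed_p_allocated(1.2, 0.3, shoot_p = 3.0), 0.9)
  expect_error(seed_p_allocated(1.0, 1.5, shoot_p = 2), "residual")
  expect_error(seed_p_allocated(1.0, 0.5, shoot_p = 0), "whole-plant")
})

test_that("control isotopic composition anchors the partition", {
  expect_equal(ic0(11.8, 4.6, 0.62), 2.9648, tolerance = 1e-4)
  expect_equal(ic0(11.8, 4.6, 0), 11.8 / 4.6)
  expect_equal(ic0(0, 4.6, 0.62), 0)
  expect_error(ic0(11.8, 0.5, 0.62), "degenerate")
})

test_that("soil-derived P scales control uptake by the tracer ratio", {
  expect_equal(psoil_from_tracer(4.6, 0.62, 20.1, 11.8), 6.7795,
               tolerance = 1e-4)
  expect_equal(psoil_from_tracer(4.6, 0.62, 11.8, 11.8), 4.6 - 0.62)
  expect_equal(psoil_from_tracer(4.6, 0.62, 0, 11.8), 0)
  expect_error(psoil_from_tracer(4.6, 0.62, 20.1, 0), "r0")
})

test_that("fertilizer P is the mass-balance residual, never clipped", {
  expect_equal(pfert_residual(4.6, 0.62, 3.98), 0)
  expect_equal(pfert_residual(12.5, 0.67, 5.5), 6.33)
  expect_equal(pfert_residual(10, 1, 10), -1)  # noise case is retained
})

test_that("Pdff and CPU are percentages of uptake and dose", {
  expect_equal(pdff(10.9, 19.7), 55.33, tolerance = 1e-3)
  expect_equal(pdff(7.0, 12.5), 56.0)
  expect_equal(pdff(0, 5), 0)
  expect_error(pdff(1, 0), "undefined")
  expect_equal(cpu(10.9, 50), 21.8)
  expect_equal(cpu(7.0, 50), 14.0)
  expect_equal(cpu(0, 50), 0)
  expect_error(cpu(1, 0), "undefined")
})

test_that("Pdff decreases as tracer recovery of the fertilized crop rises", {
  # more tracer recovered means more soil-derived P at fixed total uptake
  Pt0 <- 4.6; Pseed0 <- 0.62; r0 <- 11.8; Pt <- 19.7; Pseed <- 0.89
  rf <- seq(2, 30, length.out = 15)
  pd <- vapply(rf, function(r) {
    ps <- psoil_from_tracer(Pt0, Pseed0, r, r0)
    pdff(pfert_residual(Pt, Pseed, ps), Pt)
  }, 0)
  expect_true(all(diff(pd) < 0))
})

test_that("agronomic effectiveness compares test and reference fertilizers", {
  ae <- agronomic_effectiveness(list(Pfert = 7.0, Pdff = 56),
                                list(Pfert = 10.9, Pdff = 55,
                                     treatment = "TSP"))
  expect_equal(ae$AE_CPU, 64.22, tolerance = 1e-3)
  expect_equal(ae$AE_Pdff, 101.8, tolerance = 1e-3)
  expect_equal(ae$reference_treatment, "TSP")
  self <- agronomic_effectiveness(list(Pfert = 10.9, Pdff = 55),
                                  list(Pfert = 10.9, Pdff = 55))
  expect_equal(self$AE_CPU, 100)
  expect_equal(self$AE_Pdff, 100)
  expect_error(agronomic_effectiveness(list(Pfert = 1, Pdff = 1),
                                       list(Pfert = 0, Pdff = 0)),
               "reference")
})
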