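# Channel-block analysis: percent block, Hill fits, conductance transform,
# Boltzmann activation, gating-shift and voltage-dependence verdicts.

test_that("percent_block computes, clamps and validates", {
  expect_equal(percent_block(2, 1), 50)
  expect_equal(percent_block(2, 2), 0)
  expect_equal(percent_block(2, 0), 100)
  # invariant to common scaling of both currents
  expect_equal(percent_block(0.02, 0.013), percent_block(2000, 1300))
  expect_warning(pb <- percent_block(2, 2.2), "clamped")
  expect_equal(pb, 0)
  expect_error(percent_block(0, 1), "zero")
  expect_error(percent_block(2, -1), "same sign")
})

test_that("fit_hill round-trips noise-free curves across h and IC50", {
  for (h in c(0.5, 1, 2)) {
    for (ic50 in c(1e-10, 1e-8, 1e-6, 1e-4)) {
      dr <- gen_dose_response(ic50 = ic50, h = h, n_conc = 9, decades = 3,
                              noise_sd = 0, seed = 17)
      fit <- fit_hill(dr)
      expect_equal(fit$ic50, ic50, tolerance = 1e-6)
      expect_equal(fit$h, h, tolerance = 1e-6)
      # half block at the fitted IC50 for any h
      expect_equal(predict(fit, data.frame(conc = fit$ic50)), 50, tolerance = 1e-9)
    }
  }
})

test_that("fit_hill honours fix_h and flags extrapolation", {
  dr <- gen_dose_response(ic50 = 9e-9, h = 1, noise_sd = 0, seed = 2)
  fit <- fit_hill(dr, fix_h = 1)
  expect_equal(fit$h, 1)
  expect_equal(fit$ic50, 9e-9, tolerance = 1e-6)
  low <- data.frame(conc = 10^seq(-10, -9, length.out = 5),
                    block = c(2, 4, 7, 11, 16))
  expect_warning(f2 <- fit_hill(low), "not bracketed")
  expect_true(f2$extrapolated)
  expect_error(fit_hill(data.frame(conc = c(1e-9, 2e-9, 4e-9), block = c(10, 30, 60))),
               "at least 4")
})

test_that("IC50 recovery under 5% noise is within 20% in >= 90% of seeds", {
  ic50 <- 9e-9
  ok <- vapply(1:200, function(s) {
    dr <- gen_dose_response(ic50 = ic50, h = 1, noise_sd = 0.05, seed = s)
    fit <- suppressWarnings(fit_hill(dr))
    abs(fit$ic50 - ic50) / ic50 <= 0.20
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("conductance transform inverts the generating activation curve", {
  truth <- list(v_half = 14, slope_k = 8, erev = -90)
  iv <- gen_gv_family(v_half = truth$v_half, slope_k = truth$slope_k,
                      erev = truth$erev, noise_sd = 0, seed = 1)
  gv <- conductance_from_iv(data.frame(v = iv$v, i = iv$i_control),
                            erev = truth$erev)
  po <- 1 / (1 + exp((truth$v_half - gv$v) / truth$slope_k))
  expect_equal(gv$g_norm, po / max(po), tolerance = 1e-8)
  # ohmic channel with open probability 1: flat normalized conductance
  v <- seq(-40, 40, 10)
  ohmic <- conductance_from_iv(data.frame(v = v, i = 0.1 * (v + 90)), erev = -90)
  expect_equal(ohmic$g_norm, rep(1, length(v)))
  expect_error(conductance_from_iv(data.frame(v = v, i = rep(0, length(v))),
                                   erev = -90), "zero conductance")
  expect_error(conductance_from_iv(data.frame(v = c(-3, 0, 3), i = c(-1, 0, 1)),
                                   erev = 0), "within")
})

test_that("fit_boltzmann round-trips and degrades gracefully", {
  iv <- gen_gv_family(v_half = 14, slope_k = 8, noise_sd = 0, seed = 1)
  gv <- conductance_from_iv(data.frame(v = iv$v, i = iv$i_control), erev = -90)
  fit <- fit_boltzmann(data.frame(v = gv$v, g = gv$g_norm))
  expect_equal(fit$v_half, 14, tolerance = 1e-6)
  expect_equal(fit$slope_k, 8, tolerance = 1e-6)
  expect_equal(predict(fit, data.frame(v = fit$v_half)), fit$gmax / 2,
               tolerance = 1e-9)
  flat <- data.frame(v = seq(-40, 40, 10), g = 1)
  expect_warning(f2 <- fit_boltzmann(flat), "degenerate")
  expect_false(f2$converged)
  upper <- data.frame(v = seq(20, 60, 10), g = c(0.90, 0.95, 0.97, 0.99, 1.0))
  expect_warning(fit_boltzmann(upper), "poorly spanned")
})

test_that("compare_v_half detects shifts and declares stability", {
  same <- compare_v_half(c(14, 13, 15), c(14, 13, 15))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$verdict, "no_shift")
  big <- compare_v_half(c(14, 13.5, 14.5), c(34, 33.5, 34.5))
  expect_identical(big$verdict, "shift_detected")
  expect_error(compare_v_half(14, 15), "at least 2")
  # replicate midpoints near 14 vs 15 mV with 2 mV within-pair noise: a 1 mV
  # difference should mostly not reach significance at n = 3
  verdicts <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      a <- rnorm(3, 14, 2)
      b <- a + 1 + rnorm(3, 0, 2)
    })
    suppressWarnings(compare_v_half(a, b)$verdict)
  }, character(1))
  expect_gt(mean(verdicts == "no_shift"), 0.5)
})

test_that("voltage dependence verdict follows the spread rule", {
  v <- seq(-30, 30, 10)
  const <- data.frame(v = v, block = rep(50, length(v)))
  expect_identical(voltage_dependence_of_block(const)$verdict,
                   "voltage_independent")
  rising <- data.frame(v = v, block = seq(20, 80, length.out = length(v)))
  expect_identical(voltage_dependence_of_block(rising)$verdict,
                   "voltage_dependent")
  expect_error(voltage_dependence_of_block(data.frame(v = c(0, 10), block = c(50, 50))),
               "3 test potentials")
  # computed from current pairs when block is absent
  pairs <- data.frame(v = v, i_control = 2 * (v + 90), i_toxin = 1 * (v + 90))
  out <- voltage_dependence_of_block(pairs)
  expect_equal(out$table$block, rep(50, length(v)))
})
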