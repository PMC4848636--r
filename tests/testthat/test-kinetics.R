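# Tight-binding kinetics: Morrison model, Ki_app fitting, substrate
# correction, titration and reversibility.

test_that("morrison_fraction matches limiting cases and rejects bad input", {
  # no inhibitor
  expect_equal(morrison_fraction(27e-9, 0, 5.4e-9), 1.0)
  # stoichiometric limit ki -> 0: vi/v0 -> 1 - i0/e0
  expect_equal(morrison_fraction(10e-9, 4e-9, 1e-18), 0.6, tolerance = 1e-6)
  # monotone non-increasing and within [0, 1]
  i_grid <- seq(0, 200e-9, length.out = 101)
  fr <- morrison_fraction(27e-9, i_grid, 5.4e-9)
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(morrison_fraction(-1e-9, 1e-9, 1e-9), "positive")
  expect_error(morrison_fraction(1e-9, -1e-9, 1e-9), "non-negative")
  expect_error(morrison_fraction(1e-9, 1e-9, NaN), "finite")
})

test_that("morrison_fraction agrees with the equilibrium bisection oracle", {
  withr::with_seed(421, {
    e0 <- 10^runif(300, -9, -3)
    i0 <- 10^runif(300, -9, -3)
    ki <- 10^runif(300, -9, -3)
  })
  a <- morrison_fraction(e0, i0, ki)
  b <- mapply(morrison_oracle, e0, i0, ki)
  expect_true(all(abs(a - b) / abs(b) < 1e-8))
})

test_that("fit_morrison recovers the generating Ki_app on noise-free curves", {
  e0 <- 100e-9
  for (ki_app in c(0.01, 0.1, 1, 10, 100) * e0) {
    cur <- gen_morrison_curve(e0 = e0, ki_app = ki_app, n_points = 12,
                              noise_sd = 0, seed = 11)
    fit <- suppressWarnings(fit_morrison(cur, e0 = e0))
    expect_true(fit$converged)
    expect_equal(fit$ki_app, ki_app, tolerance = 1e-6)
  }
})

test_that("fit_morrison flags uninformative and flat curves", {
  flat <- data.frame(conc = seq(0, 1e-7, length.out = 6), activity = 1)
  expect_error(fit_morrison(flat, e0 = 1e-8), "no inhibition detected")
  few <- data.frame(conc = c(0, 1e-8), activity = c(1, 0.4))
  expect_error(fit_morrison(few, e0 = 1e-8), "at least 5 points")
  weak <- data.frame(conc = seq(0, 1e-9, length.out = 8),
                     activity = seq(1, 0.9, length.out = 8))
  w <- capture_warnings(fit_morrison(weak, e0 = 1e-7))
  expect_true(any(grepl("poorly constrained", w)))
})

test_that("median Ki_app recovery under 2% noise is within 10%", {
  ki_app <- 10e-9
  e0 <- 100e-9
  rel <- vapply(1:200, function(s) {
    cur <- gen_morrison_curve(e0 = e0, ki_app = ki_app, noise_sd = 0.02, seed = s)
    fit <- suppressWarnings(fit_morrison(cur, e0 = e0))
    abs(fit$ki_app - ki_app) / ki_app
  }, numeric(1))
  expect_lt(median(rel), 0.10)
})

test_that("ki_app standard errors are calibrated under 2% noise", {
  ki_app <- 20e-9
  e0 <- 100e-9
  cover <- vapply(1:200, function(s) {
    cur <- gen_morrison_curve(e0 = e0, ki_app = ki_app, noise_sd = 0.02, seed = s)
    fit <- suppressWarnings(fit_morrison(cur, e0 = e0))
    abs(fit$ki_app - ki_app) <= 2 * fit$ki_app_se
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("correct_ki follows the competitive correction exactly", {
  # s0 = km halves the apparent constant
  expect_equal(correct_ki(5.4e-9, s0 = 1e-3, km = 1e-3), 2.7e-9)
  expect_equal(correct_ki(29.2e-9, s0 = 0.5e-3, km = 0.5e-3), 14.6e-9)
  # s0 = 0 leaves it unchanged
  expect_equal(correct_ki(3.3e-9, s0 = 0, km = 1e-3), 3.3e-9)
  # linearity in ki_app and exact round trip
  ki <- 7e-9; s0 <- 4e-4; km <- 25e-5
  expect_equal(correct_ki(ki * (1 + s0 / km), s0, km), ki)
  expect_equal(correct_ki(2 * 5e-9, s0, km), 2 * correct_ki(5e-9, s0, km))
  # strictly decreasing in s0/km
  s0s <- seq(0, 2e-3, length.out = 10)
  expect_true(all(diff(correct_ki(1e-8, s0s, 1e-3)) < 0))
  expect_error(correct_ki(1e-8, 1e-3, NA), "correction unavailable")
})

test_that("tight-binding classification is inclusive at 1e-7 M", {
  expect_true(classify_tight_binding(2.7e-9))
  expect_true(classify_tight_binding(1.0e-7))
  expect_false(classify_tight_binding(5.0e-7))
})

test_that("titration recovers the active concentration and validates inputs", {
  tt <- gen_titration(active_conc = 100e-9, e_total = 100e-9,
                      n_points = 12, noise_sd = 0, seed = 3)
  fit <- suppressWarnings(fit_titration(tt, e0_over_ki = 200))
  expect_equal(fit$active_conc, 100e-9, tolerance = 0.005)
  # low enzyme-to-Ki ratio: result returned but flagged
  f2 <- NULL
  w <- capture_warnings(f2 <- fit_titration(tt, e0_over_ki = 10))
  expect_true(any(grepl("stoichiometric", w)))
  expect_true(length(f2$warnings) > 0)
  flat <- data.frame(conc = seq(0, 1e-7, length.out = 8), activity = 1)
  expect_error(fit_titration(flat), "no titration signal")
  sparse <- data.frame(conc = c(0, 5e-8, 1e-7), activity = c(1, 0.95, 0.05))
  expect_error(fit_titration(sparse), "underdetermined")
})

test_that("reversibility verdicts follow the substrate and time rules", {
  pre_stable <- data.frame(minutes = c(1, 5, 10, 20),
                           activity = c(0.63, 0.63, 0.64, 0.63))
  sub_up <- data.frame(s0_over_km = c(0.5, 1, 2), activity = c(0.55, 0.63, 0.72))
  expect_identical(assess_reversibility(sub_up, pre_stable)$verdict,
                   "reversible_substrate_competitive")
  sub_flat <- data.frame(s0_over_km = c(0.5, 1, 2), activity = c(0.63, 0.63, 0.64))
  expect_identical(assess_reversibility(sub_flat, pre_stable)$verdict,
                   "inconsistent")
  pre_falling <- data.frame(minutes = c(1, 5, 10, 20),
                            activity = c(0.80, 0.70, 0.62, 0.55))
  expect_identical(assess_reversibility(sub_up, pre_falling)$verdict,
                   "equilibrium_not_reached")
  sub_bad <- data.frame(s0_over_km = c(0.5, 1, 2), activity = c(0.5, 0.6, 0.7),
                        e0 = c(1e-8, 1e-8, 2e-8))
  expect_error(assess_reversibility(sub_bad, pre_stable), "not comparable")
})

test_that("ki_result assembles the corrected-Ki report", {
  cur <- gen_morrison_curve(e0 = 27e-9, ki_app = 5.4e-9, noise_sd = 0, seed = 5)
  fit <- fit_morrison(cur, e0 = 27e-9)
  row <- ki_result(fit, s0 = 1e-3, km = 1e-3, enzyme = "trypsin")
  expect_equal(row$ki, 2.7e-9, tolerance = 1e-6)
  expect_true(row$tight_binding)
  expect_identical(row$assumption, "competitive")
  expect_equal(row$e0_over_ki, 10, tolerance = 1e-5)
})
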