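# Dose scheduling and multiple-dose stiff integration.

test_that("dose schedules convert mg/kg to internal amount units", {
  sch <- dose_schedule(dose_regimen(180, 0.10201, n_doses = 3, interval_tau = 24), pyr)
  expect_equal(sch$time, c(0, 24, 48))
  expect_equal(sch$amount, rep(1.83618e7, 3))

  one <- dose_schedule(dose_regimen(10, 0.1, n_doses = 1, start_time = 5), pyr)
  expect_equal(nrow(one), 1)
  expect_equal(one$time, 5)

  mol <- dose_schedule(dose_regimen(60, 0.10201, n_doses = 1), art)
  expect_equal(mol$amount, 60 * 0.10201 * 1e6 / 384.42, tolerance = 1e-12)
  expect_equal(mol$amount, 1.5921e4, tolerance = 1e-4)
})

test_that("simulated profiles are linear in dose and zero without dose", {
  reg1 <- dose_regimen(180, 0.10201, n_doses = 2, interval_tau = 24)
  reg2 <- dose_regimen(360, 0.10201, n_doses = 2, interval_tau = 24)
  s1 <- simulate_regimen(pyr, reg1, duration = 48, grid_step = 0.5)
  s2 <- simulate_regimen(pyr, reg2, duration = 48, grid_step = 0.5)
  p1 <- sim_profile(s1, "lung"); p2 <- sim_profile(s2, "lung")
  nz <- p1$conc > 0
  expect_true(all(abs(p2$conc[nz] / p1$conc[nz] - 2) < 1e-6))

  tiny <- dose_regimen(1e-12, 0.10201, n_doses = 1)
  s0 <- simulate_regimen(pyr, tiny, duration = 24, grid_step = 1)
  expect_lt(max(sim_profile(s0, "blood")$conc), 1e-10)
})

test_that("single-dose blood AUC to infinity equals dose / (CL/F)", {
  reg <- dose_regimen(60, 0.10201, n_doses = 1)
  sim <- simulate_regimen(art, reg, duration = 48, grid_step = 0.01)
  pr <- sim_profile(sim, "blood")
  auc <- auc_trapezoid(pr$time_h, pr$conc)
  dose <- dose_schedule(reg, art)$amount
  expect_equal(auc, dose / (art$parent$CL_F * 1000), tolerance = 1e-3)
})

test_that("the n-dose profile superposes n shifted single-dose profiles", {
  reg3 <- dose_regimen(180, 0.10201, n_doses = 3, interval_tau = 24)
  s3 <- simulate_regimen(pyr, reg3, duration = 96, grid_step = 0.25)
  multi <- sim_profile(s3, "blood")

  reg1 <- dose_regimen(180, 0.10201, n_doses = 1)
  s1 <- simulate_regimen(pyr, reg1, duration = 96, grid_step = 0.25)
  single <- sim_profile(s1, "blood")

  tgrid <- seq(50, 96, by = 0.25)
  multi_c <- stats::approx(multi$time_h, multi$conc, xout = tgrid)$y
  super <- rowSums(vapply(c(0, 24, 48), function(shift)
    stats::approx(single$time_h + shift, single$conc, xout = tgrid,
                  yleft = 0)$y,
    numeric(length(tgrid))))
  expect_true(all(abs(super / multi_c - 1) < 1e-3))
})

test_that("conservation: with zero clearance the total amount is constant", {
  m <- update_parameters(pyr, c(CL_F = 0))
  reg <- dose_regimen(180, 0.10201, n_doses = 1)
  dose <- dose_schedule(reg, m)$amount
  sim <- simulate_regimen(m, reg, duration = 200, grid_step = 1)
  totals <- rowSums(sim$amounts[, -1])
  expect_true(all(abs(totals / dose - 1) < 1e-6))
})

test_that("the stiff artesunate system integrates and refines stably", {
  reg <- dose_regimen(60, 0.10201, n_doses = 3, interval_tau = 24)
  sim <- simulate_regimen(art, reg, duration = 72)
  pr <- sim_profile(sim, "blood")
  expect_true(all(is.finite(pr$conc)) && all(pr$conc >= 0))
  auc_a <- auc_trapezoid(pr$time_h, pr$conc, 0, 24)

  fine <- simulate_regimen(art, reg, duration = 72, grid_step = 0.01)
  prf <- sim_profile(fine, "blood")
  auc_b <- auc_trapezoid(prf$time_h, prf$conc, 0, 24)
  expect_equal(auc_a, auc_b, tolerance = 5e-4)
})

test_that("interval averages match the steady-state oracle after long dosing", {
  reg <- dose_regimen(180, 0.10201, n_doses = 14, interval_tau = 24)
  sim <- simulate_regimen(pyr, reg, duration = 14 * 24)
  t0 <- 13 * 24; t1 <- 14 * 24
  blood <- interval_average(sim, "blood", t0 = t0, t1 = t1)
  lung <- interval_average(sim, "lung", t0 = t0, t1 = t1)
  trachea <- interval_average(sim, "trachea", t0 = t0, t1 = t1)
  oracle <- steady_state_ratios(pyr)
  expect_equal(lung / blood, unname(oracle[["lung_to_blood"]]), tolerance = 5e-3)
  expect_equal(trachea / blood, unname(oracle[["trachea_to_blood"]]), tolerance = 5e-3)

  expect_equal(interval_average(sim, "blood", t0 = 300, t1 = 312) /
                 interval_average(sim, "plasma", t0 = 300, t1 = 312),
               pyr$parent$K_bp)
  expect_error(interval_average(sim, "blood", t0 = 10, t1 = 10), "exceed")
})
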