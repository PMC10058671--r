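# Noncompartmental analysis primitives.

test_that("trapezoidal AUC: worked cases, interpolated windows, additivity", {
  expect_equal(auc_trapezoid(c(0, 4, 10), c(3, 3, 3)), 30)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 2, 0)), 2)

  k <- 0.7; t <- seq(0, 10 / k, by = 0.01)
  expect_equal(auc_trapezoid(t, 5 * exp(-k * t)), 5 / k, tolerance = 1e-4)

  # window endpoints between samples are linearly interpolated
  expect_equal(auc_trapezoid(c(0, 2), c(0, 4), 0.5, 1.5), 2)

  # additivity over an interior split point
  t <- c(0, 0.5, 1, 3, 7, 12); c0 <- c(0, 8, 6, 3, 1, 0.2)
  expect_equal(auc_trapezoid(t, c0, 0, 3) + auc_trapezoid(t, c0, 3, 12),
               auc_trapezoid(t, c0))

  expect_error(auc_trapezoid(c(0, 1), c(1, 1), 1, 0.5), "exceed")
  expect_error(auc_trapezoid(c(1), c(1)), "two points")
})

test_that("terminal half-life regression is exact on exponentials and flags rises", {
  t <- seq(0, 3, by = 0.5)
  res <- terminal_halflife(t, 10 * exp(-1.7328 * t))
  expect_equal(res$k_e, 1.7328, tolerance = 1e-12)
  expect_equal(res$t_half, log(2) / 1.7328, tolerance = 1e-12)
  expect_false(res$flagged)
  expect_equal(res$r_squared, 1)

  # exact recovery for any window of >= 3 points
  for (w in list(c(0, 1.2), c(1, 3))) {
    r <- terminal_halflife(t, 4 * exp(-0.25 * t), window = w)
    expect_equal(r$k_e, 0.25, tolerance = 1e-12)
  }

  rising <- terminal_halflife(t, 2 * exp(0.3 * t))
  expect_true(rising$flagged)
  expect_true(is.na(rising$t_half))

  expect_error(terminal_halflife(c(0, 1), c(2, 1)), ">= 3")
  expect_error(terminal_halflife(t, 10 * exp(-t), window = c(0, 0.6)), ">= 3")
})

test_that("Cmax/Tmax observation with earliest-time tie-break", {
  expect_equal(cmax_tmax(c(0, 1, 2), c(0, 5, 3)), list(C_max = 5, T_max = 1))
  expect_equal(cmax_tmax(c(0, 1, 2), c(4, 5, 5))$T_max, 1)
  expect_equal(cmax_tmax(c(0, 1, 2), c(7, 5, 3))$T_max, 0)
  expect_error(cmax_tmax(numeric(0), numeric(0)), "empty")
})

test_that("Cavg and accumulation ratio reproduce the worked steady-state arithmetic", {
  expect_equal(cavg(57189.7, 24), 2382.904, tolerance = 1e-6)
  expect_equal(cavg(931.4, 24), 38.808, tolerance = 1e-4)
  expect_equal(cavg(0, 24), 0)
  expect_error(cavg(10, 0), "tau")

  expect_equal(accumulation_ratio(57189.7, 32508.2), 1.7592, tolerance = 1e-4)
  expect_equal(round(accumulation_ratio(57189.7, 32508.2), 1), 1.8)
  expect_equal(accumulation_ratio(5, 5), 1)
  expect_error(accumulation_ratio(1, 0), "AUC")

  # one-compartment closed form: R = 1 / (1 - exp(-k tau))
  expect_equal(accumulation_ratio(1 / (1 - exp(-0.72)), 1), 1.9483767, tolerance = 1e-7)
})

test_that("tissue-to-blood ratios reproduce the reported exposure ratios", {
  expect_equal(tissue_to_blood_ratio(320.5, 931.4), 0.3441, tolerance = 1e-3)
  expect_equal(tissue_to_blood_ratio(140.5, 931.4), 0.1508, tolerance = 1e-3)
  expect_equal(tissue_to_blood_ratio(7, 7), 1)
  expect_error(tissue_to_blood_ratio(1, 0), "blood")
})

test_that("simulated artesunate tail gives the flip-flop terminal half-life", {
  sim <- simulate_regimen(art, dose_regimen(60, 0.10201, n_doses = 1),
                          duration = 8, grid_step = 0.02)
  pr <- sim_profile(sim, "blood")
  res <- terminal_halflife(pr$time_h, pr$conc, window = c(1, 3))
  expect_equal(res$t_half, log(2) / 1.74, tolerance = 0.02)
})

test_that("nca_report ties its pieces together consistently", {
  t <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 28, 48)
  conc <- 100 * (exp(-0.1 * t) - exp(-1.5 * t))
  rep <- nca_report(t, conc, tau = 24,
                    windows = list(day1 = c(0, 24), ss = c(24, 48)),
                    terminal_window = c(4, 48))
  expect_equal(rep$c_avg[["day1"]] * 24, rep$auc[["day1"]])
  expect_equal(rep$accumulation_ratio, rep$auc[["ss"]] / rep$auc[["day1"]])
  expect_equal(rep$t_half, log(2) / rep$k_e)
  expect_equal(rep$C_max, max(conc))
})
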