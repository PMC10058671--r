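# Synthetic study generation: design arithmetic, noise model, censoring.

test_that("the default design matches the study protocol", {
  des <- default_design()
  expect_length(des$blood_times, 22)
  expect_length(des$tissue_times, 13)
  expect_equal(des$n_per_timepoint, 4L)
  expect_named(des$dose_groups, c("low", "high"))
  expect_equal(des$dose_groups$low$dose_per_kg, 180)
  expect_equal(des$dose_groups$high$dose_per_kg, 360)
  expect_equal(des$dose_groups$low$n_doses, 3L)

  art_des <- default_design("artesunate")
  expect_equal(art_des$dose_groups$low$dose_per_kg, 60)
  expect_equal(art_des$dose_groups$high$dose_per_kg, 120)
})

test_that("noise-free generation reproduces model predictions exactly", {
  des <- default_design()
  des$dose_groups <- des$dose_groups["low"]
  d <- generate_dataset(pyr, des, error_model(cv = 0, seed = 7))
  blood <- d[d$matrix == "blood", ]
  expect_equal(nrow(blood), 22 * 4)
  expect_equal(nrow(d), (22 + 13 + 13) * 4)
  # all four replicates at a time point identical and equal to the model
  by_time <- split(blood$concentration, blood$time_h)
  expect_true(all(vapply(by_time, function(x) diff(range(x)) == 0, logical(1))))

  # compare against a simulation evaluated exactly at the design times
  sim <- simulate_regimen(pyr, des$dose_groups$low,
                          times = sort(unique(c(des$blood_times, 0, 24, 48))))
  pr <- sim_profile(sim, "blood")
  pred <- pr$conc[match(sort(unique(blood$time_h)), pr$time_h)]
  got <- vapply(by_time, `[[`, numeric(1), 1)[order(as.numeric(names(by_time)))]
  expect_equal(unname(got), pred, tolerance = 1e-7)
  expect_true(all(d$concentration[d$time_h == 0] == 0))
})

test_that("generation is seed-reproducible and replicates differ across seeds", {
  des <- default_design()
  des$dose_groups <- des$dose_groups["low"]
  a <- generate_dataset(pyr, des, error_model(cv = 0.2, seed = 11))
  b <- generate_dataset(pyr, des, error_model(cv = 0.2, seed = 11))
  c2 <- generate_dataset(pyr, des, error_model(cv = 0.2, seed = 12))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$concentration, c2$concentration)))

  reps <- replicate_study(pyr, des, error_model(cv = 0.2, seed = 30),
                          n_replicates = 3)
  expect_identical(reps[[1]],
                   generate_dataset(pyr, des, error_model(cv = 0.2, seed = 30)))
  expect_false(identical(reps[[1]]$concentration, reps[[2]]$concentration))
})

test_that("proportional-lognormal error is mean-corrected", {
  set.seed(99)
  pred <- rep(100, 10000)
  err <- error_model(cv = 0.2, seed = 99)
  draws <- minipbpk:::apply_error(pred, err)
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_equal(stats::sd(draws) / mean(draws), 0.2, tolerance = 0.05)
})

test_that("raising the LLOQ never increases the number of uncensored records", {
  des <- default_design()
  des$dose_groups <- des$dose_groups["low"]
  counts <- vapply(c(0, 1, 100, 5000), function(lloq) {
    des$lloq <- if (lloq == 0) NULL else lloq
    d <- generate_dataset(pyr, des, error_model(cv = 0.2, seed = 5))
    sum(!d$bql)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  des$lloq <- 100
  d <- generate_dataset(pyr, des, error_model(cv = 0.2, seed = 5))
  expect_true(any(d$bql))
  expect_true(all(is.na(d$concentration[d$bql])))
})

test_that("noise-free generation plus NCA recovers the simulated AUC", {
  des <- default_design()
  des$dose_groups <- des$dose_groups["low"]
  d <- generate_dataset(pyr, des, error_model(cv = 0, seed = 1))
  pooled <- pool_dataset(d)
  s <- pooled[pooled$matrix == "blood", ]
  auc_data <- auc_trapezoid(s$time_h, s$conc, 0, 24)

  sim <- simulate_regimen(pyr, des$dose_groups$low,
                          times = sort(unique(c(des$blood_times, 0, 24, 48))))
  pr <- sim_profile(sim, "blood")
  sparse <- pr$conc[match(des$blood_times, pr$time_h)]
  expect_equal(auc_data, auc_trapezoid(des$blood_times, sparse, 0, 24),
               tolerance = 1e-7)
})
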