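# Parameter types, ODE right-hand sides, and the linear-balance oracles.

test_that("physiology validates volumes, flows and derived quantities", {
  ph <- hamster_physiology()
  expect_equal(ph$V_rest, 102.01 - (7.20 + 0.48 + 0.06))
  expect_equal(ph$Q_trachea, 1181.28 * 0.021)
  expect_equal(ph$Q_rest, ph$Q_co - ph$Q_trachea)
  expect_error(physiological_parameters(V_total = 10, V_blood = 7, V_lung = 0.5,
                                        V_trachea = 0.06, V_rest = 5, Q_co = 100),
               "inconsistent")
  expect_error(physiological_parameters(V_total = -1, V_blood = 7, V_lung = 0.5,
                                        V_trachea = 0.06, Q_co = 100),
               "V_total")
  expect_error(disposition_parameters(k_a = -0.1, CL_F = 1, K_lung = 1,
                                      K_trachea = 1, K_rest = 1, k_tl = 0, k_lt = 0),
               "k_a")
  expect_error(pbpk_model("parent_metabolite", hamster_physiology(),
                          pyr$parent, artesunate_model()$metabolite,
                          unit_mode = "mass_ng"),
               "molar_nmol")
})

test_that("single-model derivatives: equilibrium at origin and depot transfer", {
  z <- state_template(pyr)
  expect_equal(unname(pbpk_derivatives(z, pyr)), rep(0, 5))

  s <- z; s[["A_a"]] <- 1e6
  d <- pbpk_derivatives(s, pyr)
  expect_equal(d[["A_a"]], -pyr$parent$k_a * 1e6)
  expect_equal(d[["A_blood"]], pyr$parent$k_a * 1e6)
  expect_equal(unname(d[c("A_lung", "A_trachea", "A_rest")]), rep(0, 3))
})

test_that("single-model mass balance: derivative sum is -C_blood * CL/F", {
  for (s in random_states(pyr, 20)) {
    d <- pbpk_derivatives(s, pyr)
    # cancellation slack scales with the largest flux (the near-zero K_rest
    # makes the rest-compartment return term enormous)
    expect_lt(abs(sum(d) + s[["A_blood"]] / pyr$phys$V_blood *
                    pyr$parent$CL_F * 1000),
              1e-12 * max(abs(d)))
  }
})

test_that("parent-metabolite derivatives: conversion bookkeeping by trachea form", {
  z <- state_template(art)
  expect_equal(unname(pbpk_derivatives(z, art)), rep(0, 9))

  art_mb <- artesunate_model("mass_balanced")
  phys <- art$phys
  for (s in random_states(art, 20)) {
    Cb <- s[["A_blood"]] / phys$V_blood
    Cbm <- s[["A_blood_m"]] / phys$V_blood
    conv <- Cb * art$parent$CL_F * 1000
    elim_m <- Cbm * art$metabolite$CLm_F * 1000

    d <- pbpk_derivatives(s, art_mb)
    parent_sum <- sum(d[c("A_a", "A_blood", "A_lung", "A_trachea", "A_rest")])
    metab_sum <- sum(d[c("A_blood_m", "A_lung_m", "A_trachea_m", "A_rest_m")])
    expect_equal(parent_sum, -conv, tolerance = 1e-10)
    expect_equal(metab_sum, conv - elim_m, tolerance = 1e-10)

    # the printed trachea form leaves an uncancelled blood/trachea exchange
    # residue: Q_trachea * (C_trachea_m/K_trachea_m - C_lung_m/K_lung_m)
    dp <- pbpk_derivatives(s, art)
    resid <- phys$Q_trachea *
      (s[["A_trachea_m"]] / phys$V_trachea / art$metabolite$K_trachea_m -
         s[["A_lung_m"]] / phys$V_lung / art$metabolite$K_lung_m)
    metab_sum_p <- sum(dp[c("A_blood_m", "A_lung_m", "A_trachea_m", "A_rest_m")])
    expect_equal(metab_sum_p, conv - elim_m + resid, tolerance = 1e-8)
  }
})

test_that("with no metabolite clearance the whole dose ends up as metabolite", {
  m <- artesunate_model("mass_balanced")
  m <- update_parameters(m, c(CLm_F = 0))
  reg <- dose_regimen(60, 0.10201, n_doses = 1)
  dose <- dose_schedule(reg, m)$amount
  sim <- simulate_regimen(m, reg, duration = 300, grid_step = 0.5)
  final <- sim$amounts[nrow(sim$amounts), ]
  metab_total <- final$A_blood_m + final$A_lung_m + final$A_trachea_m + final$A_rest_m
  expect_equal(metab_total, dose, tolerance = 1e-3)
})

test_that("steady-state ratio oracle reproduces the reference tissue ratios", {
  r <- steady_state_ratios(pyr)
  expect_equal(unname(r[["lung_to_blood"]]), 25.824980, tolerance = 1e-6)
  expect_equal(unname(r[["trachea_to_blood"]]), 12.393318, tolerance = 1e-6)

  ra <- auc_ratios(art, "parent")
  expect_equal(unname(ra[["lung_to_blood"]]), 10.3165141, tolerance = 1e-6)
  expect_equal(unname(ra[["trachea_to_blood"]]), 1.5720075, tolerance = 1e-6)
})

test_that("oracles decouple to the partition coefficients without lung-trachea exchange", {
  m <- update_parameters(pyr, c(k_tl = 0, k_lt = 0))
  r <- steady_state_ratios(m)
  expect_equal(unname(r[["lung_to_blood"]]), m$parent$K_lung)
  expect_equal(unname(r[["trachea_to_blood"]]), m$parent$K_trachea)

  mm <- artesunate_model("mass_balanced")
  mm$metabolite$k_tl_m <- 0
  mm$metabolite$k_lt_m <- 0
  rm_ <- auc_ratios(mm, "metabolite")
  expect_equal(unname(rm_[["lung_to_blood"]]), mm$metabolite$K_lung_m)
  expect_equal(unname(rm_[["trachea_to_blood"]]), mm$metabolite$K_trachea_m)
})

test_that("metabolite AUC-ratio oracle: both trachea forms give the frozen values", {
  rp <- auc_ratios(artesunate_model("as_printed"), "metabolite")
  expect_equal(unname(rp[["lung_to_blood"]]), 0.34000000, tolerance = 1e-6)
  expect_equal(unname(rp[["trachea_to_blood"]]), 0.13638968, tolerance = 1e-6)

  rb <- auc_ratios(artesunate_model("mass_balanced"), "metabolite")
  expect_equal(unname(rb[["lung_to_blood"]]), 0.3401117, tolerance = 1e-6)
  expect_equal(unname(rb[["trachea_to_blood"]]), 1.0631040, tolerance = 1e-6)
})

test_that("blood/plasma conversion is the stated arithmetic and involutive", {
  expect_equal(blood_plasma_convert(4, 0.75, "plasma_to_blood"), 3)
  expect_equal(blood_plasma_convert(3, 0.75, "blood_to_plasma"), 4)
  expect_equal(blood_plasma_convert(5.7, 1, "plasma_to_blood"), 5.7)
  x <- c(0.3, 12, 400)
  expect_equal(blood_plasma_convert(
    blood_plasma_convert(x, 0.75, "plasma_to_blood"), 0.75, "blood_to_plasma"), x)
  expect_error(blood_plasma_convert(1, 0), "K_bp")
})
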