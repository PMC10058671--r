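# ODE right-hand sides and linear-balance exposure-ratio oracles.
#
# All rates are amount/h with amounts in ng (mass mode) or nmol (molar mode),
# volumes in mL, flows in mL/h; CL/F values arrive in L/h and are converted
# to mL/h here so concentrations are amount/mL throughout.

single_rates <- function(state, phys, p, prefix = "") {
  g <- function(nm) state[[paste0(nm, prefix)]]
  C_blood   <- g("A_blood") / phys$V_blood
  C_lung    <- g("A_lung") / phys$V_lung
  C_trachea <- g("A_trachea") / phys$V_trachea
  C_rest    <- g("A_rest") / phys$V_rest
  list(C_blood = C_blood, C_lung = C_lung, C_trachea = C_trachea,
       C_rest = C_rest)
}

#' Time derivatives of a minimal PBPK state
#'
#' Evaluates the model right-hand side at a state: the five-compartment
#' single-analyte system, or the nine-compartment parent-metabolite system
#' in which the parent's blood clearance term feeds the metabolite's blood
#' compartment. Concentrations are amounts over physiological volumes
#' (perfusion rate-limited kinetics); each tissue returns drug to blood as
#' `C_tissue * Q / K_tissue`.
#'
#' For parent-metabolite models the metabolite trachea equation follows the
#' model's `metabolite_trachea_form` (see [pbpk_model()]).
#'
#' @param state named nonnegative state vector, see [state_template()]
#' @param model a `pbpk_model`
#' @return Named vector of time derivatives (amount/h).
#' @export
pbpk_derivatives <- function(state, model) {
  tmpl <- state_template(model)
  if (is.null(names(state))) {
    if (length(state) != length(tmpl))
      stop_param("state must have %d entries", length(tmpl))
    names(state) <- names(tmpl)
  }
  state <- state[names(tmpl)]
  phys <- model$phys
  p <- model$parent
  CL <- p$CL_F * 1000  # L/h -> mL/h
  if ((p$K_lung == 0 && phys$Q_co > 0) || (p$K_trachea == 0 && phys$Q_trachea > 0) ||
      (p$K_rest == 0 && phys$Q_rest > 0))
    stop_param("zero partition coefficient with nonzero flow: tissue return term undefined")

  cc <- single_rates(state, phys, p)
  d <- numeric(length(tmpl)); names(d) <- names(tmpl)
  d[["A_a"]] <- -p$k_a * state[["A_a"]]
  d[["A_blood"]] <- p$k_a * state[["A_a"]] +
    cc$C_lung * phys$Q_co / p$K_lung +
    cc$C_trachea * phys$Q_trachea / p$K_trachea +
    cc$C_rest * phys$Q_rest / p$K_rest -
    cc$C_blood * (phys$Q_co + phys$Q_trachea + phys$Q_rest + CL)
  d[["A_lung"]] <- cc$C_blood * phys$Q_co - cc$C_lung * phys$Q_co / p$K_lung +
    state[["A_trachea"]] * p$k_tl - state[["A_lung"]] * p$k_lt
  d[["A_trachea"]] <- cc$C_blood * phys$Q_trachea -
    cc$C_trachea * phys$Q_trachea / p$K_trachea +
    state[["A_lung"]] * p$k_lt - state[["A_trachea"]] * p$k_tl
  d[["A_rest"]] <- cc$C_blood * phys$Q_rest - cc$C_rest * phys$Q_rest / p$K_rest

  if (model$kind == "parent_metabolite") {
    m <- model$metabolite
    CLm <- m$CLm_F * 1000
    if ((m$K_lung_m == 0 && phys$Q_co > 0) ||
        (m$K_trachea_m == 0 && phys$Q_trachea > 0) ||
        (m$K_rest_m == 0 && phys$Q_rest > 0))
      stop_param("zero metabolite partition coefficient with nonzero flow")
    C_blood_m   <- state[["A_blood_m"]] / phys$V_blood
    C_lung_m    <- state[["A_lung_m"]] / phys$V_lung
    C_trachea_m <- state[["A_trachea_m"]] / phys$V_trachea
    C_rest_m    <- state[["A_rest_m"]] / phys$V_rest

    d[["A_blood_m"]] <- cc$C_blood * CL +
      C_lung_m * phys$Q_co / m$K_lung_m +
      C_trachea_m * phys$Q_trachea / m$K_trachea_m +
      C_rest_m * phys$Q_rest / m$K_rest_m -
      C_blood_m * (phys$Q_co + phys$Q_trachea + phys$Q_rest + CLm)
    d[["A_lung_m"]] <- C_blood_m * phys$Q_co - C_lung_m * phys$Q_co / m$K_lung_m +
      state[["A_trachea_m"]] * m$k_tl_m - state[["A_lung_m"]] * m$k_lt_m
    trachea_return <- if (model$metabolite_trachea_form == "as_printed")
      C_lung_m * phys$Q_trachea / m$K_lung_m
    else
      C_trachea_m * phys$Q_trachea / m$K_trachea_m
    d[["A_trachea_m"]] <- C_blood_m * phys$Q_trachea - trachea_return +
      state[["A_lung_m"]] * m$k_lt_m - state[["A_trachea_m"]] * m$k_tl_m
    d[["A_rest_m"]] <- C_blood_m * phys$Q_rest - C_rest_m * phys$Q_rest / m$K_rest_m
  }
  d
}

# deSolve-compatible RHS closure
pbpk_rhs <- function(model) {
  function(t, state, parms) list(pbpk_derivatives(state, model))
}

# Shared 2x2 linear balance: with blood exposure normalized to 1, the lung
# and trachea balances (net change zero over the averaging window) give
#   Q_co - (Q_co/K_lung) r_l + k_tl V_trachea r_t - k_lt V_lung r_l = 0
#   [trachea return] + k_lt V_lung r_l - k_tl V_trachea r_t + Q_trachea = 0
# where the trachea return term is -(Q_trachea/K_trachea) r_t for the
# conserving forms and -(Q_trachea/K_lung) r_l for the printed metabolite
# block.
solve_ratio_system <- function(phys, K_lung, K_trachea, k_tl, k_lt,
                               form = c("balanced", "as_printed")) {
  form <- match.arg(form)
  if (K_lung <= 0 || (form == "balanced" && K_trachea <= 0))
    stop_param("partition coefficients must be > 0 for the ratio oracle")
  A <- if (form == "balanced") {
    matrix(c(-phys$Q_co / K_lung - k_lt * phys$V_lung, k_tl * phys$V_trachea,
             k_lt * phys$V_lung, -phys$Q_trachea / K_trachea - k_tl * phys$V_trachea),
           2, 2, byrow = TRUE)
  } else {
    matrix(c(-phys$Q_co / K_lung - k_lt * phys$V_lung, k_tl * phys$V_trachea,
             -phys$Q_trachea / K_lung + k_lt * phys$V_lung, -k_tl * phys$V_trachea),
           2, 2, byrow = TRUE)
  }
  b <- c(-phys$Q_co, -phys$Q_trachea)
  r <- tryCatch(solve(A, b), error = function(e)
    stop_param("singular tissue-balance system (K_lung=%g, K_trachea=%g, k_tl=%g, k_lt=%g): %s",
               K_lung, K_trachea, k_tl, k_lt, conditionMessage(e)))
  c(lung_to_blood = r[1], trachea_to_blood = r[2])
}

#' Steady-state tissue-to-blood concentration ratio oracle
#'
#' Closed-form interval-average lung-to-blood and trachea-to-blood
#' concentration ratios at periodic steady state under repeated dosing,
#' obtained by integrating the lung and trachea balances over one dosing
#' interval (net change zero) and solving the resulting 2x2 linear system.
#' Independent of dose, dosing interval and absorption rate, it serves as an
#' analytic cross-check on long simulations.
#'
#' With no lung-trachea exchange (`k_tl = k_lt = 0`) the system decouples and
#' the ratios are exactly the partition coefficients.
#'
#' @param model a single-analyte `pbpk_model`
#' @return Named vector `(lung_to_blood, trachea_to_blood)`.
#' @examples
#' steady_state_ratios(pyronaridine_model())
#' @export
steady_state_ratios <- function(model) {
  if (model$kind != "single")
    stop_param("steady_state_ratios() is defined for single-analyte models; use auc_ratios() for metabolites")
  p <- model$parent
  solve_ratio_system(model$phys, p$K_lung, p$K_trachea, p$k_tl, p$k_lt,
                     form = "balanced")
}

#' Single-dose tissue-to-blood AUC ratio oracle
#'
#' Closed-form `AUC_tissue / AUC_blood` over a complete single-dose washout
#' (0 to infinity): integrating each tissue balance with empty initial and
#' final states yields the same 2x2 linear system as
#' [steady_state_ratios()], so the two oracles coincide. For the metabolite
#' of a parent-metabolite model, the trachea balance follows the model's
#' `metabolite_trachea_form`.
#'
#' @param model a `pbpk_model`
#' @param analyte `"parent"` or `"metabolite"`
#' @return Named vector `(lung_to_blood, trachea_to_blood)` of AUC ratios.
#' @examples
#' auc_ratios(artesunate_model(), "metabolite")
#' @export
auc_ratios <- function(model, analyte = c("parent", "metabolite")) {
  analyte <- match.arg(analyte)
  phys <- model$phys
  if (analyte == "parent") {
    p <- model$parent
    return(solve_ratio_system(phys, p$K_lung, p$K_trachea, p$k_tl, p$k_lt,
                              form = "balanced"))
  }
  if (model$kind != "parent_metabolite")
    stop_param("metabolite ratios require a parent_metabolite model")
  m <- model$metabolite
  form <- if (model$metabolite_trachea_form == "as_printed") "as_printed" else "balanced"
  solve_ratio_system(phys, m$K_lung_m, m$K_trachea_m, m$k_tl_m, m$k_lt_m,
                     form = form)
}
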