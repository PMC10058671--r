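#' Molar masses of the study compounds
#'
#' Free-base molar masses (g/mol) used to convert administered doses from mg
#' to nmol when a model runs in molar units. Values are standard reference
#' molecular weights and can be overridden wherever a molar mass is accepted.
#'
#' @format Named numeric vector (g/mol).
#' @export
molar_masses <- c(
  pyronaridine      = 518.05,
  artesunate        = 384.42,
  dihydroartemisinin = 284.35
)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_param <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stop_param("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_param("'%s' must be >= 0 (got %g)", name, x)
  as.numeric(x)
}

#' Physiological parameters for a minimal PBPK model
#'
#' Fixed volumes and blood flows of the lumped hamster physiology: blood,
#' lung, trachea and a rest-of-body compartment holding everything else.
#' Derived quantities are computed when omitted: `V_rest` from the total body
#' volume, `Q_trachea` from a cardiac-output fraction, and `Q_rest` as
#' `Q_co - Q_trachea`. Supplied values are checked against the derived ones
#' (1e-9 relative tolerance) so an inconsistent parameter table fails loudly.
#'
#' @param V_total total body volume (mL)
#' @param V_blood blood volume (mL)
#' @param V_lung lung volume (mL)
#' @param V_trachea trachea volume (mL)
#' @param V_rest rest-of-body volume (mL); defaults to
#'   `V_total - (V_blood + V_lung + V_trachea)`
#' @param Q_co cardiac output (mL/h)
#' @param Q_trachea tracheal blood flow (mL/h); defaults to
#'   `Q_co * Q_trachea_fraction`
#' @param Q_rest rest-of-body blood flow (mL/h); defaults to
#'   `Q_co - Q_trachea`
#' @param Q_trachea_fraction fraction of cardiac output perfusing the trachea
#'   (used only when `Q_trachea` is missing)
#' @return An object of class `phys_params`.
#' @examples
#' hamster_physiology()
#' @export
physiological_parameters <- function(V_total, V_blood, V_lung, V_trachea,
                                     V_rest = NULL,
                                     Q_co, Q_trachea = NULL, Q_rest = NULL,
                                     Q_trachea_fraction = 0.021) {
  V_total   <- check_scalar(V_total, "V_total", positive = TRUE)
  V_blood   <- check_scalar(V_blood, "V_blood", positive = TRUE)
  V_lung    <- check_scalar(V_lung, "V_lung", positive = TRUE)
  V_trachea <- check_scalar(V_trachea, "V_trachea", positive = TRUE)
  Q_co      <- check_scalar(Q_co, "Q_co", positive = TRUE)

  v_rest_calc <- V_total - (V_blood + V_lung + V_trachea)
  if (is.null(V_rest)) V_rest <- v_rest_calc
  V_rest <- check_scalar(V_rest, "V_rest", positive = TRUE)
  if (abs(V_rest - v_rest_calc) > 1e-9 * max(1, abs(v_rest_calc)))
    stop_param("V_rest (%g) inconsistent with V_total - (V_blood + V_lung + V_trachea) = %g",
               V_rest, v_rest_calc)

  if (is.null(Q_trachea)) Q_trachea <- Q_co * check_scalar(
    Q_trachea_fraction, "Q_trachea_fraction", positive = TRUE)
  Q_trachea <- check_scalar(Q_trachea, "Q_trachea", positive = TRUE)

  q_rest_calc <- Q_co - Q_trachea
  if (is.null(Q_rest)) Q_rest <- q_rest_calc
  Q_rest <- check_scalar(Q_rest, "Q_rest", positive = TRUE)
  if (abs(Q_rest - q_rest_calc) > 1e-9 * max(1, abs(q_rest_calc)))
    stop_param("Q_rest (%g) inconsistent with Q_co - Q_trachea = %g",
               Q_rest, q_rest_calc)

  structure(list(V_total = V_total, V_blood = V_blood, V_lung = V_lung,
                 V_trachea = V_trachea, V_rest = V_rest,
                 Q_co = Q_co, Q_trachea = Q_trachea, Q_rest = Q_rest),
            class = "phys_params")
}

#' @export
print.phys_params <- function(x, ...) {
  cat("Minimal PBPK physiology\n")
  cat(sprintf("  Volumes (mL): total %.4g | blood %.4g | lung %.4g | trachea %.4g | rest %.4g\n",
              x$V_total, x$V_blood, x$V_lung, x$V_trachea, x$V_rest))
  cat(sprintf("  Flows (mL/h): cardiac output %.6g | trachea %.6g | rest %.6g\n",
              x$Q_co, x$Q_trachea, x$Q_rest))
  invisible(x)
}

#' Reference hamster physiology
#'
#' The golden-hamster physiology used throughout: 102.01 mL total body volume
#' (body weight 102.01 g at unit density), 7.20 mL blood, 0.48 mL lung,
#' 0.06 mL trachea, cardiac output 1181.28 mL/h with 2.1% perfusing the
#' trachea. Rest-of-body volume and flow are derived (94.27 mL, 1156.47 mL/h).
#'
#' @return A `phys_params` object.
#' @export
hamster_physiology <- function() {
  physiological_parameters(V_total = 102.01, V_blood = 7.20, V_lung = 0.48,
                           V_trachea = 0.06, Q_co = 1181.28,
                           Q_trachea_fraction = 0.021)
}

#' Disposition parameters for one analyte
#'
#' Biochemical (drug-specific) parameters of the minimal PBPK model:
#' first-order oral absorption `k_a`, apparent clearance `CL_F` (L/h, i.e.
#' CL/F; converted to mL/h internally), perfusion-limited tissue-to-blood
#' partition coefficients, first-order lung/trachea exchange rate constants,
#' and the blood-to-plasma ratio `K_bp` used to interconvert matrices.
#'
#' @param k_a absorption rate constant (1/h)
#' @param CL_F apparent oral clearance CL/F (L/h)
#' @param K_lung,K_trachea,K_rest tissue-to-blood partition coefficients
#' @param k_tl trachea-to-lung transfer rate constant (1/h)
#' @param k_lt lung-to-trachea transfer rate constant (1/h)
#' @param K_bp blood-to-plasma concentration ratio (default 1)
#' @return An object of class `disposition_params`.
#' @export
disposition_parameters <- function(k_a, CL_F, K_lung, K_trachea, K_rest,
                                   k_tl, k_lt, K_bp = 1) {
  p <- list(
    k_a = check_scalar(k_a, "k_a", nonneg = TRUE),
    CL_F = check_scalar(CL_F, "CL_F", nonneg = TRUE),
    K_lung = check_scalar(K_lung, "K_lung", nonneg = TRUE),
    K_trachea = check_scalar(K_trachea, "K_trachea", nonneg = TRUE),
    K_rest = check_scalar(K_rest, "K_rest", nonneg = TRUE),
    k_tl = check_scalar(k_tl, "k_tl", nonneg = TRUE),
    k_lt = check_scalar(k_lt, "k_lt", nonneg = TRUE),
    K_bp = check_scalar(K_bp, "K_bp", positive = TRUE))
  structure(p, class = "disposition_params")
}

#' Disposition parameters for a metabolite
#'
#' Metabolite analogue of [disposition_parameters()]: the metabolite is
#' formed in blood from the parent (rate `C_blood * CL/F` of the parent) and
#' has its own clearance, partition coefficients and lung/trachea exchange.
#'
#' @param CLm_F apparent metabolite clearance (L/h)
#' @param K_lung_m,K_trachea_m,K_rest_m metabolite partition coefficients
#' @param k_tl_m,k_lt_m metabolite lung/trachea exchange rates (1/h)
#' @param K_bp_m metabolite blood-to-plasma ratio (default 1)
#' @return An object of class `metabolite_params`.
#' @export
metabolite_parameters <- function(CLm_F, K_lung_m, K_trachea_m, K_rest_m,
                                  k_tl_m, k_lt_m, K_bp_m = 1) {
  p <- list(
    CLm_F = check_scalar(CLm_F, "CLm_F", nonneg = TRUE),
    K_lung_m = check_scalar(K_lung_m, "K_lung_m", nonneg = TRUE),
    K_trachea_m = check_scalar(K_trachea_m, "K_trachea_m", nonneg = TRUE),
    K_rest_m = check_scalar(K_rest_m, "K_rest_m", nonneg = TRUE),
    k_tl_m = check_scalar(k_tl_m, "k_tl_m", nonneg = TRUE),
    k_lt_m = check_scalar(k_lt_m, "k_lt_m", nonneg = TRUE),
    K_bp_m = check_scalar(K_bp_m, "K_bp_m", positive = TRUE))
  structure(p, class = "metabolite_params")
}

#' Assemble a minimal PBPK model
#'
#' Binds physiology and disposition parameters into a simulatable model
#' specification. `kind = "single"` is the five-compartment single-analyte
#' model (absorption depot, blood, lung, trachea, rest of body);
#' `kind = "parent_metabolite"` appends four metabolite compartments fed by
#' conversion of the parent in blood and must run in molar units so the
#' conversion conserves moles.
#'
#' The printed metabolite trachea equation returns drug to blood through
#' `C_lung,m / K_lung,m`; `metabolite_trachea_form = "as_printed"` keeps that
#' form (the fitted model), `"mass_balanced"` uses
#' `C_trachea,m / K_trachea,m` so the metabolite block conserves mass. See
#' the package vignette for why both are provided.
#'
#' @param kind `"single"` or `"parent_metabolite"`
#' @param phys a [physiological_parameters()] object
#' @param parent a [disposition_parameters()] object
#' @param metabolite a [metabolite_parameters()] object (required iff
#'   `kind = "parent_metabolite"`)
#' @param unit_mode `"mass_ng"` (amounts in ng) or `"molar_nmol"` (nmol)
#' @param metabolite_trachea_form `"as_printed"` or `"mass_balanced"`
#' @param analyte,metabolite_name compound labels used in outputs
#' @param molar_mass parent molar mass (g/mol), needed for molar dosing;
#'   looked up in [molar_masses] from `analyte` when `NULL`
#' @return An object of class `pbpk_model`.
#' @examples
#' mod <- pyronaridine_model()
#' mod
#' @export
pbpk_model <- function(kind = c("single", "parent_metabolite"),
                       phys, parent, metabolite = NULL,
                       unit_mode = c("mass_ng", "molar_nmol"),
                       metabolite_trachea_form = c("as_printed", "mass_balanced"),
                       analyte = "parent", metabolite_name = "metabolite",
                       molar_mass = NULL) {
  kind <- match.arg(kind)
  unit_mode <- match.arg(unit_mode)
  metabolite_trachea_form <- match.arg(metabolite_trachea_form)
  if (!inherits(phys, "phys_params"))
    stop_param("'phys' must be a phys_params object")
  if (!inherits(parent, "disposition_params"))
    stop_param("'parent' must be a disposition_params object")
  if (kind == "parent_metabolite") {
    if (!inherits(metabolite, "metabolite_params"))
      stop_param("parent_metabolite models require metabolite_parameters()")
    if (unit_mode != "molar_nmol")
      stop_param("parent_metabolite models must use unit_mode = 'molar_nmol' (mole-conserving conversion)")
  } else if (!is.null(metabolite)) {
    stop_param("'metabolite' must be absent for kind = 'single'")
  }
  if (is.null(molar_mass) && analyte %in% names(molar_masses))
    molar_mass <- unname(molar_masses[analyte])
  structure(list(kind = kind, phys = phys, parent = parent,
                 metabolite = metabolite, unit_mode = unit_mode,
                 metabolite_trachea_form = metabolite_trachea_form,
                 analyte = analyte, metabolite_name = metabolite_name,
                 molar_mass = molar_mass),
            class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("Minimal PBPK model (%s, %s)\n", x$kind, x$unit_mode))
  cat(sprintf("  analyte: %s", x$analyte))
  if (x$kind == "parent_metabolite")
    cat(sprintf(" -> %s  [trachea form: %s]", x$metabolite_name,
                x$metabolite_trachea_form))
  cat("\n")
  print(x$phys)
  pp <- unlist(x$parent)
  cat("  parent:     ", paste(sprintf("%s=%.4g", names(pp), pp), collapse = " "), "\n")
  if (!is.null(x$metabolite)) {
    mm <- unlist(x$metabolite)
    cat("  metabolite: ", paste(sprintf("%s=%.4g", names(mm), mm), collapse = " "), "\n")
  }
  invisible(x)
}

#' Reference pyronaridine model
#'
#' Single-analyte minimal PBPK model of pyronaridine in the hamster: whole
#' blood is the reference matrix, amounts are in ng and concentrations in
#' ng/mL. Disposition values are the fitted hamster estimates
#' (k_a 0.03/h, CL/F 0.21 L/h, K_lung 26.06, K_trachea 8.67,
#' K_rest 5.25e-7, k_tl 1.01/h, k_lt 0.92/h).
#'
#' @return A `pbpk_model` object.
#' @export
pyronaridine_model <- function() {
  pbpk_model(
    kind = "single",
    phys = hamster_physiology(),
    parent = disposition_parameters(
      k_a = 0.03, CL_F = 0.21, K_lung = 26.06, K_trachea = 8.67,
      K_rest = 5.25e-7, k_tl = 1.01, k_lt = 0.92, K_bp = 1),
    unit_mode = "mass_ng", analyte = "pyronaridine")
}

#' Reference artesunate/dihydroartemisinin model
#'
#' Parent-metabolite minimal PBPK model: artesunate is absorbed first order
#' (k_a 1.74/h) and converted entirely to dihydroartemisinin in blood via its
#' apparent clearance (CL/F 2517.70 L/h), giving flip-flop kinetics (terminal
#' slope set by absorption). Amounts are nmol so the conversion conserves
#' moles; plasma concentrations derive from blood through K_b:p = 0.75 for
#' both analytes.
#'
#' @param metabolite_trachea_form passed to [pbpk_model()]
#' @return A `pbpk_model` object.
#' @export
artesunate_model <- function(metabolite_trachea_form = c("as_printed", "mass_balanced")) {
  pbpk_model(
    kind = "parent_metabolite",
    phys = hamster_physiology(),
    parent = disposition_parameters(
      k_a = 1.74, CL_F = 2517.70, K_lung = 10.33, K_trachea = 1.48,
      K_rest = 1.32, k_tl = 1.50, k_lt = 0.34, K_bp = 0.75),
    metabolite = metabolite_parameters(
      CLm_F = 10.33, K_lung_m = 0.34, K_trachea_m = 1.08, K_rest_m = 1.21,
      k_tl_m = 6.98, k_lt_m = 0.35, K_bp_m = 0.75),
    unit_mode = "molar_nmol",
    metabolite_trachea_form = match.arg(metabolite_trachea_form),
    analyte = "artesunate", metabolite_name = "dihydroartemisinin")
}

#' Convert concentrations between blood and plasma
#'
#' Matrix interconversion through the blood-to-plasma partition coefficient:
#' blood = plasma * K_bp and plasma = blood / K_bp, so a round trip is the
#' identity.
#'
#' @param value concentration(s)
#' @param K_bp blood-to-plasma ratio (> 0)
#' @param direction `"plasma_to_blood"` or `"blood_to_plasma"`
#' @return Converted concentration(s).
#' @examples
#' blood_plasma_convert(4, 0.75, "plasma_to_blood")  # 3
#' @export
blood_plasma_convert <- function(value, K_bp,
                                 direction = c("plasma_to_blood", "blood_to_plasma")) {
  direction <- match.arg(direction)
  K_bp <- check_scalar(K_bp, "K_bp", positive = TRUE)
  if (direction == "plasma_to_blood") value * K_bp else value / K_bp
}

#' State vector template for a model
#'
#' Named zero state in the model's compartment order: depot (`A_a`), blood,
#' lung, trachea, rest of body, and the four metabolite compartments for
#' parent-metabolite models.
#'
#' @param model a `pbpk_model`
#' @return Named numeric vector of zeros.
#' @export
state_template <- function(model) {
  nm <- c("A_a", "A_blood", "A_lung", "A_trachea", "A_rest")
  if (model$kind == "parent_metabolite")
    nm <- c(nm, "A_blood_m", "A_lung_m", "A_trachea_m", "A_rest_m")
  stats::setNames(numeric(length(nm)), nm)
}

#' Replace disposition parameters in a model
#'
#' Returns a copy of `model` with the named parent and/or metabolite
#' parameters replaced; names ending in `_m` address the metabolite block.
#' Used by the fitting and sensitivity modules.
#'
#' @param model a `pbpk_model`
#' @param values named numeric vector of replacements
#' @return Updated `pbpk_model`.
#' @export
update_parameters <- function(model, values) {
  if (length(values) == 0) return(model)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop_param("'values' must be a fully named numeric vector")
  for (nm in names(values)) {
    if (nm %in% names(model$parent)) {
      model$parent[[nm]] <- check_scalar(values[[nm]], nm, nonneg = TRUE)
    } else if (!is.null(model$metabolite) && nm %in% names(model$metabolite)) {
      model$metabolite[[nm]] <- check_scalar(values[[nm]], nm, nonneg = TRUE)
    } else {
      stop_param("unknown parameter '%s' for this model", nm)
    }
  }
  model
}
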