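# Study-like synthetic datasets: the sparse destructive-sampling design with
# a configurable residual-error model, so NCA and fitting are testable
# without the (unavailable) animal data.

#' Sampling design of a multiple-dose tissue-distribution study
#'
#' @param dose_groups named list of [dose_regimen()] objects
#' @param blood_times blood sampling times (h, sorted, nonnegative)
#' @param tissue_times lung/trachea sampling times (h)
#' @param n_per_timepoint animals per time point per matrix
#' @param matrices sampled matrices
#' @param destructive_tissues if TRUE (default) each tissue time point uses
#'   its own animals, lung and trachea coming from the same animal
#' @param lloq optional lower limit of quantification: a scalar or a vector
#'   named by matrix; concentrations below it are censored (flagged BLQ,
#'   value withheld)
#' @return Object of class `study_design`.
#' @export
study_design <- function(dose_groups, blood_times, tissue_times,
                         n_per_timepoint = 4,
                         matrices = c("blood", "lung", "trachea"),
                         destructive_tissues = TRUE, lloq = NULL) {
  stopifnot(is.list(dose_groups), length(dose_groups) >= 1)
  if (is.null(names(dose_groups)))
    names(dose_groups) <- vapply(dose_groups, `[[`, character(1), "label")
  for (tset in list(blood_times, tissue_times)) {
    if (any(tset < 0) || is.unsorted(tset))
      stop_param("sampling times must be nonnegative and sorted")
  }
  n_per_timepoint <- check_scalar(n_per_timepoint, "n_per_timepoint", positive = TRUE)
  bad <- setdiff(matrices, c("blood", "plasma", "lung", "trachea"))
  if (length(bad)) stop_param("unknown matrices: %s", paste(bad, collapse = ", "))
  structure(list(dose_groups = dose_groups, blood_times = blood_times,
                 tissue_times = tissue_times,
                 n_per_timepoint = as.integer(n_per_timepoint),
                 matrices = matrices,
                 destructive_tissues = isTRUE(destructive_tissues),
                 lloq = lloq),
            class = "study_design")
}

#' Reference 3-day oral study design
#'
#' The two-group daily-oral-dosing design: 180 and 360 mg/kg pyronaridine
#' (or 60 and 120 mg/kg artesunate), once a day for 3 days in 102.01 g
#' hamsters; 22 blood sampling times over 0-72 h, 13 lung/trachea sampling
#' times, and 4 animals per time point with destructive tissue sampling.
#'
#' @param compound `"pyronaridine"` or `"artesunate"` (selects dose levels)
#' @return A `study_design`.
#' @examples
#' default_design()
#' @export
default_design <- function(compound = c("pyronaridine", "artesunate")) {
  compound <- match.arg(compound)
  doses <- if (compound == "pyronaridine") c(180, 360) else c(60, 120)
  groups <- list(
    low = dose_regimen(doses[1], body_weight = 0.10201, n_doses = 3,
                       interval_tau = 24, label = "low"),
    high = dose_regimen(doses[2], body_weight = 0.10201, n_doses = 3,
                        interval_tau = 24, label = "high"))
  study_design(
    dose_groups = groups,
    blood_times = c(0, 0.08, 0.25, 0.5, 0.75, 1, 2, 4, 8, 12, 24,
                    47, 48.08, 48.25, 48.5, 48.75, 49, 50, 52, 56, 60, 72),
    tissue_times = c(0.08, 0.25, 0.5, 0.75, 1, 4, 8, 24,
                     48.08, 48.25, 48.75, 52, 72),
    n_per_timepoint = 4)
}

#' Residual-error model for synthetic observations
#'
#' `proportional_lognormal` draws `obs = pred * exp(sigma Z - sigma^2/2)`
#' with `sigma^2 = log(1 + cv^2)`, so `E[obs] = pred` (mean-corrected
#' multiplicative error, the standard bioanalytical structure).
#' `additive_normal` adds `N(0, sd_additive)` noise truncated at zero;
#' `combined` applies both.
#'
#' @param kind error structure
#' @param cv proportional coefficient of variation (fraction, >= 0)
#' @param sd_additive additive SD in concentration units
#' @param seed RNG seed used by [generate_dataset()]
#' @return Object of class `error_model`.
#' @export
error_model <- function(kind = c("proportional_lognormal", "additive_normal",
                                 "combined"),
                        cv = 0.2, sd_additive = 0, seed = 1) {
  kind <- match.arg(kind)
  cv <- check_scalar(cv, "cv", nonneg = TRUE)
  sd_additive <- check_scalar(sd_additive, "sd_additive", nonneg = TRUE)
  structure(list(kind = kind, cv = cv, sd_additive = sd_additive,
                 seed = as.integer(seed)),
            class = "error_model")
}

apply_error <- function(pred, error) {
  n <- length(pred)
  obs <- pred
  if (error$kind %in% c("proportional_lognormal", "combined") && error$cv > 0) {
    sigma <- sqrt(log(1 + error$cv^2))
    obs <- obs * exp(sigma * stats::rnorm(n) - sigma^2 / 2)
  }
  if (error$kind %in% c("additive_normal", "combined") && error$sd_additive > 0)
    obs <- obs + error$sd_additive * stats::rnorm(n)
  pmax(obs, 0)
}

#' Generate a synthetic observed dataset
#'
#' Simulates every dose group of the design, samples the model
#' concentrations at the design's blood and tissue times, and draws
#' `n_per_timepoint` noisy replicates per time/matrix/analyte under the
#' error model. Concentrations are reported in ng/mL (mass-mode models) or
#' nmol/L (molar-mode models). Predose (t = 0) records are zeros. When an
#' LLOQ is set, sub-LLOQ draws are flagged BLQ with the value withheld.
#'
#' Animal IDs reflect the study structure: tissue records use one animal per
#' (group, time, replicate), shared between lung and trachea (destructive
#' sampling); blood animals are reused over blocks of up to three
#' consecutive time points.
#'
#' @param model a `pbpk_model`
#' @param design a [study_design()]
#' @param error an [error_model()] (its `seed` fixes the draw)
#' @return `data.frame` with columns `animal_id, dose_group, analyte, matrix,
#'   time_h, concentration, units, bql`.
#' @export
generate_dataset <- function(model, design = default_design(),
                             error = error_model()) {
  set.seed(error$seed)
  fac <- conc_unit_factor(model)
  units <- conc_unit_label(model)
  analytes <- model$analyte
  if (model$kind == "parent_metabolite")
    analytes <- c(analytes, model$metabolite_name)

  recs <- list()
  for (g in names(design$dose_groups)) {
    regimen <- design$dose_groups[[g]]
    all_times <- sort(unique(c(regimen$start_time, design$blood_times,
                               design$tissue_times)))
    sim <- simulate_regimen(model, regimen,
                            times = sort(unique(c(all_times,
                                                  dose_schedule(regimen, model)$time))))
    for (mx in design$matrices) {
      tset <- if (mx %in% c("blood", "plasma")) design$blood_times else design$tissue_times
      if (max(tset) > max(sim$times))
        stop_param("design time %g h beyond simulated span", max(tset))
      lloq <- if (is.null(design$lloq)) NA_real_ else
        if (length(design$lloq) == 1 && is.null(names(design$lloq))) design$lloq else
          design$lloq[[mx]] %||% NA_real_
      for (an in analytes) {
        pr <- sim_profile(sim, mx, an)
        pred <- stats::approx(pr$time_h, pr$conc, xout = tset)$y * fac
        for (i in seq_along(tset)) {
          obs <- apply_error(rep(pred[i], design$n_per_timepoint), error)
          ids <- if (mx %in% c("blood", "plasma")) {
            sprintf("%s_B%02d_%d", g, ceiling(i / 3), seq_len(design$n_per_timepoint))
          } else if (design$destructive_tissues) {
            sprintf("%s_T%02d_%d", g, i, seq_len(design$n_per_timepoint))
          } else {
            sprintf("%s_X_%d", g, seq_len(design$n_per_timepoint))
          }
          bql <- !is.na(lloq) & obs < lloq
          recs[[length(recs) + 1L]] <- data.frame(
            animal_id = ids, dose_group = g, analyte = an, matrix = mx,
            time_h = tset[i],
            concentration = ifelse(bql, NA_real_, obs),
            units = units, bql = bql)
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Replicate synthetic studies
#'
#' Independent datasets generated with seeds `seed + 0 .. n_replicates - 1`,
#' identical in everything but the noise draw. Supports parameter-recovery
#' simulation studies.
#'
#' @inheritParams generate_dataset
#' @param n_replicates number of datasets (>= 1)
#' @return List of datasets.
#' @export
replicate_study <- function(model, design = default_design(),
                            error = error_model(), n_replicates = 1) {
  if (n_replicates < 1) stop_param("n_replicates must be >= 1")
  lapply(seq_len(n_replicates) - 1L, function(k) {
    e <- error; e$seed <- error$seed + k
    generate_dataset(model, design, e)
  })
}
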