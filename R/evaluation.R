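# Normalized local sensitivity analysis and predictive-performance metrics.

sensitivity_metric <- function(model, regimen, metric, analyte = NULL,
                               grid_step = NULL, rtol = 1e-8) {
  # single-dose profile on the full regimen grid (blood, AUC 0-last)
  single <- dose_regimen(regimen$dose_per_kg, regimen$body_weight, n_doses = 1,
                         interval_tau = regimen$interval_tau,
                         start_time = regimen$start_time,
                         salt_factor = regimen$salt_factor)
  duration <- regimen$start_time + regimen$n_doses * regimen$interval_tau
  sim <- simulate_regimen(model, single, duration = duration,
                          grid_step = grid_step, rtol = rtol)
  pr <- sim_profile(sim, "blood", analyte)
  switch(metric,
         cmax_blood = max(pr$conc),
         auc_blood = auc_trapezoid(pr$time_h, pr$conc),
         stop_param("unknown metric '%s'", metric))
}

#' Normalized local sensitivity coefficient
#'
#' Forward one-sided sensitivity of a blood exposure metric to one model
#' parameter: the parameter is increased by `delta` (default 1%), the metric
#' recomputed, and the coefficient reported as
#' `((A - B) / B) / ((C - D) / D)` with `A`/`B` the perturbed/original metric
#' and `C`/`D` the perturbed/original parameter. A coefficient of 1 means a
#' 1% parameter change moves the metric by 1%; magnitudes above 1 amplify
#' input error.
#'
#' Metrics are computed on the blood profile of a single oral dose simulated
#' over the regimen's full span (AUC is 0 to last). `parameter = "dose"`
#' perturbs the administered dose instead of a disposition parameter.
#'
#' @param model a `pbpk_model`
#' @param regimen a `dose_regimen` (defines dose level and simulated span)
#' @param parameter disposition parameter name (parent or `_m` metabolite),
#'   or `"dose"`
#' @param metric `"cmax_blood"` or `"auc_blood"`
#' @param delta relative perturbation (> 0), default 0.01
#' @param analyte analyte whose blood profile is scored (default parent)
#' @param grid_step simulation output step (h)
#' @param rtol solver relative tolerance (tighten for tiny `delta`)
#' @return List of class `sensitivity_result`: `parameter`, `metric`,
#'   `coefficient`, `delta`, `baseline`.
#' @export
normalized_sensitivity <- function(model, regimen, parameter,
                                   metric = c("cmax_blood", "auc_blood"),
                                   delta = 0.01, analyte = NULL,
                                   grid_step = NULL, rtol = 1e-8) {
  metric <- match.arg(metric)
  if (!is.numeric(delta) || delta <= 0) stop_param("delta must be > 0")
  B <- sensitivity_metric(model, regimen, metric, analyte, grid_step, rtol)
  if (B == 0) stop_param("baseline %s is zero; sensitivity undefined", metric)
  if (parameter == "dose") {
    reg2 <- regimen; reg2$dose_per_kg <- regimen$dose_per_kg * (1 + delta)
    A <- sensitivity_metric(model, reg2, metric, analyte, grid_step, rtol)
  } else {
    base_val <- model$parent[[parameter]] %||% model$metabolite[[parameter]]
    if (is.null(base_val)) stop_param("unknown parameter '%s'", parameter)
    if (base_val <= 0)
      stop_param("parameter '%s' must be > 0 for a relative perturbation", parameter)
    pert <- stats::setNames(base_val * (1 + delta), parameter)
    A <- sensitivity_metric(update_parameters(model, pert), regimen, metric,
                            analyte, grid_step, rtol)
  }
  structure(list(parameter = parameter, metric = metric,
                 coefficient = ((A - B) / B) / delta, delta = delta,
                 baseline = B),
            class = "sensitivity_result")
}

#' Sensitivity scan over parameters and metrics
#'
#' [normalized_sensitivity()] over the Cartesian product of parameters and
#' metrics, sorted by absolute coefficient (descending). Coefficients with
#' magnitude above 1 are flagged as amplifying input error.
#'
#' @inheritParams normalized_sensitivity
#' @param parameters character vector of parameter names; default all
#'   disposition parameters of the model (parent and metabolite)
#' @param metrics metric names
#' @return `data.frame(parameter, metric, coefficient, amplifying)`.
#' @export
sensitivity_scan <- function(model, regimen, parameters = NULL,
                             metrics = c("cmax_blood", "auc_blood"),
                             delta = 0.01, analyte = NULL, grid_step = NULL,
                             rtol = 1e-8) {
  if (is.null(parameters)) {
    parameters <- setdiff(names(model$parent), "K_bp")
    if (!is.null(model$metabolite))
      parameters <- c(parameters, setdiff(names(model$metabolite), "K_bp_m"))
  }
  if (length(parameters) == 0 || length(metrics) == 0)
    stop_param("parameters and metrics must be nonempty")
  grid <- expand.grid(parameter = parameters, metric = metrics,
                      stringsAsFactors = FALSE)
  grid$coefficient <- mapply(function(p, m)
    normalized_sensitivity(model, regimen, p, m, delta, analyte,
                           grid_step, rtol)$coefficient,
    grid$parameter, grid$metric)
  grid$amplifying <- abs(grid$coefficient) > 1
  out <- grid[order(-abs(grid$coefficient)), ]
  rownames(out) <- NULL
  out
}

#' Fold error of a prediction
#'
#' `FE = P_pred / P_obs` for positive prediction/observation pairs.
#' Predictions within the two-fold band satisfy `0.5 <= FE <= 2`
#' (boundaries inclusive).
#'
#' @param p_pred,p_obs positive values (vectorized)
#' @return Fold error(s).
#' @export
fold_error <- function(p_pred, p_obs) {
  if (any(!is.finite(p_pred)) || any(!is.finite(p_obs)) ||
      any(p_pred <= 0) || any(p_obs <= 0))
    stop_param("fold error requires strictly positive finite inputs")
  p_pred / p_obs
}

#' Average fold error (geometric mean of fold errors)
#'
#' `AFE = 10^(mean(log10(FE)))`; symmetric over- and under-prediction cancel
#' (AFE of \{2, 0.5\} is 1).
#'
#' @param fe_list positive fold errors
#' @return Scalar AFE.
#' @export
average_fold_error <- function(fe_list) {
  if (length(fe_list) == 0) stop_param("empty fold-error list")
  if (any(!is.finite(fe_list)) || any(fe_list <= 0))
    stop_param("fold errors must be positive and finite")
  10^mean(log10(fe_list))
}

#' Predictive-performance report
#'
#' Per-pair fold errors, the AFE, and the fraction of predictions within the
#' (inclusive) two-fold band.
#'
#' @param p_pred,p_obs matched positive vectors
#' @param labels optional pair labels
#' @return List of class `fold_error_report`: `fe` data.frame, `afe`,
#'   `fraction_within_twofold`.
#' @export
fold_error_report <- function(p_pred, p_obs, labels = NULL) {
  if (length(p_pred) != length(p_obs)) stop_param("pred/obs lengths differ")
  fe <- fold_error(p_pred, p_obs)
  within <- fe >= 0.5 & fe <= 2
  if (is.null(labels)) labels <- as.character(seq_along(fe))
  structure(list(
    fe = data.frame(label = labels, pred = p_pred, obs = p_obs, fe = fe,
                    within_twofold = within),
    afe = average_fold_error(fe),
    fraction_within_twofold = mean(within)),
    class = "fold_error_report")
}

#' @export
print.fold_error_report <- function(x, ...) {
  cat(sprintf("Fold-error report: AFE %.3g, %.0f%% within two-fold (n=%d)\n",
              x$afe, 100 * x$fraction_within_twofold, nrow(x$fe)))
  invisible(x)
}
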