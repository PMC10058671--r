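# Naive-pooled least-squares estimation of disposition parameters with the
# physiology fixed. All animals' records enter one weighted sum of squares;
# there are no subject effects (destructive sampling precludes them).

conc_unit_factor <- function(model) if (model$unit_mode == "mass_ng") 1 else 1000
conc_unit_label  <- function(model) if (model$unit_mode == "mass_ng") "ng/mL" else "nmol/L"

#' Define a naive-pooled fitting problem
#'
#' Binds a model (physiology fixed), a long-format observed dataset, one
#' dosing regimen per dose group, the free-parameter set with bounds, and a
#' residual weighting scheme. Parameter names ending in `_m` address the
#' metabolite block. Default bounds span a factor of 1000 around the initial
#' values; estimation happens in log-parameter space because concentrations
#' and plausible parameter ranges span several orders of magnitude.
#'
#' @param model a `pbpk_model` carrying the initial parameter values
#' @param dataset observed dataset (see [generate_dataset()] /
#'   [read_dataset()]); `dose_group` values must match `names(regimens)`
#' @param regimens named list of [dose_regimen()] objects, one per dose group
#' @param free character vector of parameter names to estimate, or a named
#'   numeric vector of starting values
#' @param lower,upper optional named bound vectors (natural scale, > 0)
#' @param weighting `"one_over_pred_sq"` (default; relative residuals),
#'   `"one_over_pred"`, or `"uniform"`
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(model, dataset, regimens,
                        free = c("k_a", "CL_F", "K_lung", "K_trachea"),
                        lower = NULL, upper = NULL,
                        weighting = c("one_over_pred_sq", "one_over_pred", "uniform")) {
  weighting <- match.arg(weighting)
  if (is.character(free)) {
    start <- vapply(free, function(nm) {
      v <- model$parent[[nm]] %||% model$metabolite[[nm]]
      if (is.null(v)) stop_param("free parameter '%s' not in the model", nm)
      v
    }, numeric(1))
  } else {
    start <- free
    model <- update_parameters(model, start)  # validates names
  }
  if (any(start <= 0))
    stop_param("starting values must be > 0 (log-space estimation): %s",
               paste(names(start)[start <= 0], collapse = ", "))
  if (is.null(lower)) lower <- start / 1000
  if (is.null(upper)) upper <- start * 1000
  lower <- lower[names(start)]; upper <- upper[names(start)]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower <= 0) ||
      any(lower >= upper))
    stop_param("bounds must satisfy 0 < lower < upper for every free parameter")
  groups <- unique(dataset$dose_group)
  if (!all(groups %in% names(regimens)))
    stop_param("no regimen for dose group(s): %s",
               paste(setdiff(groups, names(regimens)), collapse = ", "))
  d <- dataset[!dataset$bql, , drop = FALSE]
  if (nrow(d) == 0) stop_param("no quantifiable records to fit")
  structure(list(model = model, dataset = d, regimens = regimens[groups],
                 free = start, lower = lower, upper = upper,
                 weighting = weighting),
            class = "fit_problem")
}

# Predictions for every record of one dose group at the candidate model.
predict_records <- function(model, regimen, records) {
  times <- sort(unique(c(regimen$start_time, records$time_h)))
  sim <- simulate_regimen(model, regimen, times = times)
  fac <- conc_unit_factor(model)
  pred <- numeric(nrow(records))
  for (an in unique(records$analyte)) {
    for (mx in unique(records$matrix)) {
      sel <- records$analyte == an & records$matrix == mx
      if (!any(sel)) next
      pr <- sim_profile(sim, mx, an)
      pred[sel] <- stats::approx(pr$time_h, pr$conc, xout = records$time_h[sel])$y * fac
    }
  }
  pred
}

fit_residuals <- function(theta, problem) {
  model <- update_parameters(problem$model, theta)
  d <- problem$dataset
  pred <- tryCatch({
    out <- numeric(nrow(d))
    for (g in names(problem$regimens)) {
      sel <- d$dose_group == g
      out[sel] <- predict_records(model, problem$regimens[[g]],
                                  d[sel, , drop = FALSE])
    }
    out
  }, error = function(e) {
    warning(sprintf("simulation failed at candidate parameters (%s); penalized",
                    conditionMessage(e)), call. = FALSE)
    NULL
  })
  if (is.null(pred))
    return(rep(1e6 * (1 + sum(abs(log(theta)))), nrow(d)))
  floor_ <- 1e-9 * max(pred, 1e-300)
  w <- switch(problem$weighting,
              uniform = rep(1, nrow(d)),
              one_over_pred = 1 / pmax(pred, floor_),
              one_over_pred_sq = 1 / pmax(pred, floor_)^2)
  sqrt(w) * (d$concentration - pred)
}

#' Weighted pooled sum-of-squares objective
#'
#' The naive-pooled objective `sum(w * (obs - pred)^2)` over every
#' quantifiable record, with predictions simulated per dose group at the
#' candidate parameters and evaluated at each record's time, matrix and
#' analyte. A failed simulation returns a large finite penalty (with a
#' warning) so optimizers survive pathological candidates.
#'
#' @param theta named parameter vector (natural scale)
#' @param problem a [fit_problem()]
#' @return Scalar weighted SSR.
#' @export
pooled_objective <- function(theta, problem) {
  sum(fit_residuals(theta, problem)^2)
}

#' Fit a minimal PBPK model to pooled data
#'
#' Bound-constrained Levenberg-Marquardt least squares (minpack.lm) in
#' log-parameter space, optionally multi-start with the extra starts drawn
#' log-uniformly within the bounds from a fixed seed. After the best fit,
#' each free parameter is profiled (x1.2 and /1.2) and flagged as poorly
#' identifiable when the objective is locally flat.
#'
#' @param problem a [fit_problem()]
#' @param n_starts number of starts (first start = the problem's initial
#'   values)
#' @param seed RNG seed for the extra starts
#' @param maxiter per-start iteration cap
#' @return Object of class `fit_result`: `estimates`, `objective_value`,
#'   `n_obs`, `converged`, per-matrix residual RMS, `poorly_identifiable`,
#'   and per-start diagnostics.
#' @export
fit_model <- function(problem, n_starts = 8, seed = 1, maxiter = 200) {
  phi0 <- log(problem$free)
  lo <- log(problem$lower); hi <- log(problem$upper)
  starts <- list(phi0)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); replicate(n_starts - 1,
      stats::runif(length(phi0), lo, hi), simplify = FALSE) })
    starts <- c(starts, lapply(rng, function(x) stats::setNames(x, names(phi0))))
  }
  runs <- lapply(starts, function(st) {
    tryCatch({
      f <- minpack.lm::nls.lm(
        par = st,
        fn = function(phi) fit_residuals(stats::setNames(exp(phi), names(phi0)),
                                         problem),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = maxiter))
      list(par = stats::setNames(exp(f$par), names(phi0)),
           objective = f$deviance, converged = f$info %in% 1:4,
           message = f$message)
    }, error = function(e) list(par = NULL, objective = Inf,
                                converged = FALSE,
                                message = conditionMessage(e)))
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  if (all(!is.finite(objs))) {
    msgs <- vapply(runs, `[[`, character(1), "message")
    stop_param("all %d starts failed:\n%s", length(runs),
               paste(sprintf("  start %d: %s", seq_along(msgs), msgs), collapse = "\n"))
  }
  best <- runs[[which.min(objs)]]
  est <- best$par

  # local identifiability probe: flat objective under +/-20% perturbation
  d <- problem$dataset
  obj_scale <- {
    floor_ <- 1e-9 * max(d$concentration, 1e-300)
    w <- switch(problem$weighting,
                uniform = 1,
                one_over_pred = 1 / pmax(d$concentration, floor_),
                one_over_pred_sq = 1 / pmax(d$concentration, floor_)^2)
    sum(w * d$concentration^2)
  }
  flat <- vapply(names(est), function(nm) {
    bump <- function(f) {
      th <- est; th[nm] <- min(max(th[nm] * f, problem$lower[nm]), problem$upper[nm])
      pooled_objective(th, problem)
    }
    max(abs(c(bump(1.2), bump(1 / 1.2)) - best$objective)) <
      1e-8 * max(obj_scale, 1e-300)
  }, logical(1))

  resid <- fit_residuals(est, problem)
  rms_by_matrix <- tapply(resid, d$matrix, function(r) sqrt(mean(r^2)))

  structure(list(estimates = est, objective_value = best$objective,
                 n_obs = nrow(d), converged = best$converged,
                 message = best$message,
                 residual_rms_by_matrix = as.list(rms_by_matrix),
                 poorly_identifiable = names(est)[flat],
                 weighting = problem$weighting,
                 start_objectives = objs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Naive-pooled fit (%s weighting): objective %.6g on %d records%s\n",
              x$weighting, x$objective_value, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (nm in names(x$estimates))
    cat(sprintf("  %-12s %.6g%s\n", nm, x$estimates[[nm]],
                if (nm %in% x$poorly_identifiable) "  (poorly identifiable)" else ""))
  invisible(x)
}
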