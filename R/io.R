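# File formats, configuration and the end-to-end pipeline.

dataset_columns <- c("animal_id", "dose_group", "analyte", "matrix",
                     "time_h", "concentration", "units", "bql")
valid_matrices <- c("blood", "plasma", "lung", "trachea")
valid_analytes <- c("pyronaridine", "artesunate", "dihydroartemisinin")

#' Write an observed dataset to CSV
#'
#' Long-format CSV with the canonical column set; numeric values keep full
#' precision so a read/write round trip is lossless.
#'
#' @param dataset dataset data.frame (see [generate_dataset()])
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  missing_cols <- setdiff(dataset_columns, names(dataset))
  if (length(missing_cols))
    stop_param("dataset lacks column(s): %s", paste(missing_cols, collapse = ", "))
  utils::write.csv(dataset[dataset_columns], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and validate an observed dataset
#'
#' Reads a long-format concentration CSV and validates it record by record:
#' the full column set must be present, matrices and analytes must come from
#' the recognized vocabularies, times must be nonnegative, and every
#' non-BLQ concentration must be a nonnegative number. Failures name the
#' offending row.
#'
#' @param path CSV file with columns `animal_id, dose_group, analyte,
#'   matrix, time_h, concentration, units, bql`
#' @return Validated dataset data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_param("dataset file not found: %s", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop_param("cannot parse '%s': %s", path,
                                               conditionMessage(e)))
  missing_cols <- setdiff(dataset_columns, names(d))
  if (length(missing_cols))
    stop_param("'%s' lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  d <- d[dataset_columns]
  d$bql <- as.logical(d$bql)
  bad <- which(!d$matrix %in% valid_matrices)
  if (length(bad))
    stop_param("row %d: unknown matrix '%s' (expected %s)", bad[1],
               d$matrix[bad[1]], paste(valid_matrices, collapse = "/"))
  bad <- which(!d$analyte %in% valid_analytes)
  if (length(bad))
    stop_param("row %d: unknown analyte '%s'", bad[1], d$analyte[bad[1]])
  bad <- which(!is.finite(d$time_h) | d$time_h < 0)
  if (length(bad)) stop_param("row %d: invalid time_h", bad[1])
  bad <- which(!d$bql & (!is.finite(d$concentration) | d$concentration < 0))
  if (length(bad)) stop_param("row %d: invalid concentration", bad[1])
  d
}

config_schema <- list(
  physiology = c("V_total", "V_blood", "V_lung", "V_trachea", "V_rest",
                 "Q_co", "Q_trachea", "Q_rest", "Q_trachea_fraction"),
  parent = c("k_a", "CL_F", "K_lung", "K_trachea", "K_rest", "k_tl", "k_lt",
             "K_bp"),
  metabolite = c("CLm_F", "K_lung_m", "K_trachea_m", "K_rest_m", "k_tl_m",
                 "k_lt_m", "K_bp_m"),
  options = c("kind", "unit_mode", "metabolite_trachea_form", "analyte",
              "metabolite_name", "molar_mass"),
  regimens = NULL)
regimen_keys <- c("dose_per_kg", "body_weight", "n_doses", "interval_tau",
                  "start_time", "salt_factor", "label")

check_keys <- function(section, keys, allowed) {
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop_param("config section '%s': unknown key(s) %s", section,
               paste(unknown, collapse = ", "))
}

#' Load a model configuration file
#'
#' Reads a sectioned YAML configuration (`physiology`, `parent`, optional
#' `metabolite`, `options`, optional `regimens`), validates it strictly
#' (any unknown key is an error, so typos like `K_lung` vs `K_lung_m` fail
#' loudly), computes derived physiology (`V_rest`, `Q_trachea` from a
#' cardiac-output fraction, `Q_rest`), and returns the assembled model plus
#' regimens.
#'
#' @param path YAML file
#' @return List with `model` (a `pbpk_model`), `regimens` (named list of
#'   `dose_regimen`, possibly empty), and `raw` (the parsed file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  check_keys("(top level)", names(cfg), names(config_schema))
  for (sec in c("physiology", "parent"))
    if (is.null(cfg[[sec]])) stop_param("config section '%s' is required", sec)
  for (sec in intersect(names(cfg), c("physiology", "parent", "metabolite", "options")))
    check_keys(sec, names(cfg[[sec]]), config_schema[[sec]])

  errors <- character(0)
  phys <- tryCatch(do.call(physiological_parameters, cfg$physiology),
                   error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  parent <- tryCatch(do.call(disposition_parameters, cfg$parent),
                     error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  metab <- if (!is.null(cfg$metabolite)) {
    tryCatch(do.call(metabolite_parameters, cfg$metabolite),
             error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  }
  if (length(errors))
    stop_param("invalid configuration '%s':\n%s", path,
               paste0("  - ", errors, collapse = "\n"))

  opt <- cfg$options %||% list()
  model <- pbpk_model(
    kind = opt$kind %||% if (is.null(metab)) "single" else "parent_metabolite",
    phys = phys, parent = parent, metabolite = metab,
    unit_mode = opt$unit_mode %||% if (is.null(metab)) "mass_ng" else "molar_nmol",
    metabolite_trachea_form = opt$metabolite_trachea_form %||% "as_printed",
    analyte = opt$analyte %||% "parent",
    metabolite_name = opt$metabolite_name %||% "metabolite",
    molar_mass = opt$molar_mass)

  regimens <- list()
  if (!is.null(cfg$regimens)) {
    for (nm in names(cfg$regimens)) {
      r <- cfg$regimens[[nm]]
      check_keys(paste0("regimens/", nm), names(r), regimen_keys)
      if (is.null(r$label)) r$label <- nm
      regimens[[nm]] <- do.call(dose_regimen, r)
    }
  }
  list(model = model, regimens = regimens, raw = cfg)
}

#' Locate a bundled example configuration
#'
#' @param name `"pyronaridine"` or `"artesunate"`
#' @return Path to the installed YAML file.
#' @export
example_config <- function(name = c("pyronaridine", "artesunate")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".yaml"), package = "minipbpk",
              mustWork = TRUE)
}

#' Run the full analysis pipeline
#'
#' Generate -> fit -> NCA -> sensitivity -> validate on a configured model:
#' synthesizes a study dataset, refits the free disposition parameters from
#' it by naive-pooled least squares, runs pooled NCA per dose group and
#' matrix, scans normalized sensitivity coefficients, compares NCA metrics
#' of the data against the model predictions as fold errors, and writes all
#' artifacts plus run metadata to `out_dir`. A stage failure aborts with the
#' stage name; artifacts of completed stages are preserved.
#'
#' @param config path to a YAML config (with a `regimens` section) or the
#'   list returned by [load_config()]
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed for the synthetic data
#' @param cv proportional residual CV of the generated data
#' @param free free-parameter set for the fit stage
#' @param n_starts fit starts (1 keeps the demo quick)
#' @param stages subset of stages to run
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = 1, cv = 0.2,
                         free = c("k_a", "CL_F", "K_lung", "K_trachea"),
                         n_starts = 1,
                         stages = c("generate", "fit", "nca", "sensitivity",
                                    "validate")) {
  loaded <- if (is.character(config)) load_config(config) else config
  model <- loaded$model
  regimens <- loaded$regimens
  if (length(regimens) == 0)
    stop_param("pipeline requires at least one regimen in the config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_param("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  design <- study_design(dose_groups = regimens,
                         blood_times = default_design()$blood_times,
                         tissue_times = default_design()$tissue_times)
  dataset <- NULL
  if ("generate" %in% stages) {
    dataset <- stage("generate", {
      d <- generate_dataset(model, design,
                            error_model(cv = cv, seed = seed))
      write_dataset(d, file.path(out_dir, "synthetic_dataset.csv"))
      d
    })
    paths$dataset <- file.path(out_dir, "synthetic_dataset.csv")
  }

  if ("fit" %in% stages) {
    paths$fit <- stage("fit", {
      if (is.null(dataset))
        stop_param("no dataset available (did the generate stage run?)")
      prob <- fit_problem(model, dataset, regimens, free = free)
      fit <- fit_model(prob, n_starts = n_starts, seed = seed)
      p <- file.path(out_dir, "fit.json")
      jsonlite::write_json(list(
        estimates = as.list(fit$estimates),
        objective_value = fit$objective_value, n_obs = fit$n_obs,
        converged = fit$converged,
        poorly_identifiable = fit$poorly_identifiable,
        weighting = fit$weighting), p, auto_unbox = TRUE, digits = NA)
      p
    })
  }

  if ("nca" %in% stages) {
    paths$nca <- stage("nca", {
      if (is.null(dataset))
        stop_param("no dataset available (did the generate stage run?)")
      pooled <- pool_dataset(dataset)
      rows <- list()
      for (g in unique(pooled$dose_group)) for (an in unique(pooled$analyte))
        for (mx in unique(pooled$matrix)) {
          s <- pooled[pooled$dose_group == g & pooled$analyte == an &
                        pooled$matrix == mx, ]
          if (nrow(s) < 3) next
          tau <- regimens[[g]]$interval_tau
          last_dose <- regimens[[g]]$start_time +
            (regimens[[g]]$n_doses - 1) * tau
          w0 <- min(s$time_h)  # tissue grids start post-dose, not at 0
          rep <- nca_report(s$time_h, s$conc, tau = tau,
                            windows = list(day1 = c(w0, min(tau, max(s$time_h)))),
                            last_dose_time = last_dose)
          rows[[length(rows) + 1L]] <- data.frame(
            dose_group = g, analyte = an, matrix = mx,
            parameter = c("C_max", "T_max", "AUC_day1", "C_avg_day1",
                          "t_half"),
            value = c(rep$C_max, rep$T_max, rep$auc[["day1"]],
                      rep$c_avg[["day1"]], rep$t_half))
        }
      p <- file.path(out_dir, "nca.csv")
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
      p
    })
  }

  if ("sensitivity" %in% stages) {
    paths$sensitivity <- stage("sensitivity", {
      scan <- sensitivity_scan(model, regimens[[1]])
      p <- file.path(out_dir, "sensitivity.csv")
      utils::write.csv(scan, p, row.names = FALSE)
      p
    })
  }

  if ("validate" %in% stages) {
    paths$validate <- stage("validate", {
      if (is.null(dataset))
        stop_param("no dataset available (did the generate stage run?)")
      pooled <- pool_dataset(dataset)
      fac <- conc_unit_factor(model)
      preds <- obs <- numeric(0); labels <- character(0)
      for (g in unique(pooled$dose_group)) {
        sim <- simulate_regimen(model, regimens[[g]])
        for (an in unique(pooled$analyte)) for (mx in unique(pooled$matrix)) {
          s <- pooled[pooled$dose_group == g & pooled$analyte == an &
                        pooled$matrix == mx, ]
          if (nrow(s) < 3) next
          pr <- sim_profile(sim, mx, an)
          o <- cmax_tmax(s$time_h, s$conc)$C_max
          pdt <- max(pr$conc[pr$time_h <= max(s$time_h)]) * fac
          if (o > 0 && pdt > 0) {
            preds <- c(preds, pdt); obs <- c(obs, o)
            labels <- c(labels, sprintf("Cmax:%s:%s:%s", g, an, mx))
          }
        }
      }
      rep <- fold_error_report(preds, obs, labels)
      p <- file.path(out_dir, "fold_errors.csv")
      fe <- rep$fe
      fe$afe <- rep$afe
      fe$fraction_within_twofold <- rep$fraction_within_twofold
      utils::write.csv(fe, p, row.names = FALSE)
      p
    })
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("minipbpk")),
    r_version = R.version.string,
    seed = seed, cv = cv, stages = stages,
    analyte = model$analyte, kind = model$kind, unit_mode = model$unit_mode,
    metabolite_trachea_form = model$metabolite_trachea_form,
    terminal_window_rule = "last dose + 4 h to end of series",
    solver = list(method = "lsoda", rtol = 1e-8,
                  atol = "1e-10 x dose amount"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$metadata <- file.path(out_dir, "run_metadata.json")
  invisible(paths)
}
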