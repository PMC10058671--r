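# Noncompartmental analysis: model-independent PK parameters from pooled
# concentration-time series.

#' Linear trapezoidal AUC over a window
#'
#' Area under a concentration-time series between `t0` and `t1` by the linear
#' trapezoidal rule. Window endpoints that fall between samples are linearly
#' interpolated; at least two points (after interpolation) must cover the
#' window. AUC is additive over adjacent windows by construction.
#'
#' @param times strictly increasing sample times (h)
#' @param conc nonnegative concentrations, same length
#' @param t0,t1 window bounds; default full series span
#' @return AUC (h * concentration unit).
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 2, 0))  # 2
#' @export
auc_trapezoid <- function(times, conc, t0 = min(times), t1 = max(times)) {
  if (length(times) != length(conc)) stop_param("times and conc lengths differ")
  if (length(times) < 2) stop_param("at least two points are required")
  if (is.unsorted(times, strictly = TRUE)) stop_param("times must be strictly increasing")
  if (t1 <= t0) stop_param("t1 must exceed t0")
  if (t0 < times[1] || t1 > times[length(times)])
    stop_param("window [%g, %g] outside sampled span [%g, %g]",
               t0, t1, times[1], times[length(times)])
  inside <- times > t0 & times < t1
  tt <- c(t0, times[inside], t1)
  cc <- c(stats::approx(times, conc, xout = t0)$y, conc[inside],
          stats::approx(times, conc, xout = t1)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Terminal elimination rate and half-life
#'
#' Log-linear regression of the terminal phase: ordinary least squares of
#' `ln(conc)` on time over the selected window, `k_e` the negative slope and
#' `t_half = ln(2) / k_e`. Requires at least three strictly positive
#' concentrations in the window; zero/BLQ points are excluded from the
#' regression. A nonnegative slope yields a flagged result (`k_e`, `t_half`
#' set to `NA`) rather than an error, since rising tails are a data feature.
#'
#' @param times,conc the series
#' @param window `c(tmin, tmax)` selecting regression points (closed
#'   interval); default all points
#' @return List with `k_e` (1/h), `t_half` (h), `n`, `r_squared`, `window`,
#'   and `flagged` (TRUE when the slope was nonnegative).
#' @examples
#' t <- 0:5; terminal_halflife(t, 10 * exp(-1.7328 * t))$t_half  # 0.4
#' @export
terminal_halflife <- function(times, conc, window = range(times)) {
  if (length(times) != length(conc)) stop_param("times and conc lengths differ")
  sel <- times >= window[1] & times <= window[2] & conc > 0
  if (sum(sel) < 3)
    stop_param("terminal regression needs >= 3 positive concentrations in the window (got %d)",
               sum(sel))
  fit <- stats::lm(log(conc[sel]) ~ times[sel])
  slope <- unname(stats::coef(fit)[2])
  y <- log(conc[sel])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (slope >= 0)
    return(list(k_e = NA_real_, t_half = NA_real_, n = sum(sel),
                r_squared = r2, window = window, flagged = TRUE))
  k_e <- -slope
  list(k_e = k_e, t_half = log(2) / k_e, n = sum(sel), r_squared = r2,
       window = window, flagged = FALSE)
}

#' Maximum concentration and its time
#'
#' Observed maximum and the earliest time it is attained (ties break toward
#' the earlier sample).
#'
#' @param times,conc the series
#' @return List `(C_max, T_max)`.
#' @export
cmax_tmax <- function(times, conc) {
  if (length(times) == 0 || length(conc) == 0) stop_param("empty series")
  if (length(times) != length(conc)) stop_param("times and conc lengths differ")
  i <- which.max(conc)  # first index at the max: earliest-time tie-break
  list(C_max = conc[i], T_max = times[i])
}

#' Average concentration over a dosing interval
#'
#' `C_avg = AUC_tau / tau`.
#'
#' @param auc_tau AUC over one dosing interval
#' @param tau dosing interval (h), > 0
#' @return Average concentration.
#' @examples
#' cavg(57189.7, 24)  # 2382.9 ng/mL
#' @export
cavg <- function(auc_tau, tau) {
  if (!is.numeric(tau) || tau <= 0) stop_param("tau must be > 0")
  auc_tau / tau
}

#' Accumulation ratio
#'
#' Steady-state interval AUC divided by the day-1 interval AUC; measures
#' build-up under repeated dosing (1 means no accumulation).
#'
#' @param auc_tau_ss AUC over one interval at steady state
#' @param auc_day1 AUC over the first dosing interval, > 0
#' @return Unitless ratio.
#' @examples
#' accumulation_ratio(57189.7, 32508.2)  # 1.76, reported rounded as 1.8
#' @export
accumulation_ratio <- function(auc_tau_ss, auc_day1) {
  if (!is.numeric(auc_day1) || auc_day1 <= 0)
    stop_param("day-1 AUC must be > 0")
  auc_tau_ss / auc_day1
}

#' Tissue-to-blood exposure ratio
#'
#' `AUC_tissue / AUC_blood` (or any matched exposure pair, e.g. C_avg
#' values) over identical windows.
#'
#' @param tissue,blood matched exposure values; `blood > 0`
#' @return Unitless ratio.
#' @examples
#' tissue_to_blood_ratio(320.5, 931.4)  # 0.34, DHA lung-to-blood
#' @export
tissue_to_blood_ratio <- function(tissue, blood) {
  if (!is.numeric(blood) || any(blood <= 0)) stop_param("blood exposure must be > 0")
  tissue / blood
}

#' Pool a sparse dataset into mean concentration-time series
#'
#' Naive pooling for destructive sampling designs: all animals' records at a
#' time point are averaged (arithmetic mean) within each dose group, analyte
#' and matrix, giving one pooled profile per stratum. BLQ records are
#' excluded.
#'
#' @param dataset an observed dataset, see [generate_dataset()] /
#'   [read_dataset()]
#' @return `data.frame(dose_group, analyte, matrix, time_h, conc, n)` sorted
#'   by time within stratum.
#' @export
pool_dataset <- function(dataset) {
  d <- dataset[!dataset$bql, , drop = FALSE]
  if (nrow(d) == 0) stop_param("no quantifiable records to pool")
  agg <- stats::aggregate(concentration ~ dose_group + analyte + matrix + time_h,
                          data = d, FUN = mean)
  cnt <- stats::aggregate(concentration ~ dose_group + analyte + matrix + time_h,
                          data = d, FUN = length)
  agg$n <- cnt$concentration
  names(agg)[names(agg) == "concentration"] <- "conc"
  agg[order(agg$dose_group, agg$analyte, agg$matrix, agg$time_h), ]
}

#' Noncompartmental analysis of one pooled profile
#'
#' Computes the standard NCA battery on a single concentration-time series:
#' C_max/T_max, AUC over requested windows, terminal half-life, C_avg per
#' interval and, when both day-1 and steady-state windows are present, the
#' accumulation ratio.
#'
#' The default terminal window starts 4 h after the last dose, a choice that
#' is reported in the result because the half-life estimate is sensitive
#' to it.
#'
#' @param times,conc the pooled series
#' @param tau dosing interval (h)
#' @param windows named list of `c(t0, t1)` AUC windows (e.g.
#'   `list(day1 = c(0, 24), ss = c(48, 72))`)
#' @param terminal_window window for the half-life regression; default from
#'   `last_dose_time + 4` to the end of the series
#' @param last_dose_time time of the final dose (h), used for the default
#'   terminal window
#' @return An `nca_report` list.
#' @export
nca_report <- function(times, conc, tau = 24,
                       windows = list(day1 = c(0, tau)),
                       terminal_window = NULL, last_dose_time = 0) {
  peak <- cmax_tmax(times, conc)
  if (is.null(terminal_window))
    terminal_window <- c(last_dose_time + 4, max(times))
  th <- tryCatch(terminal_halflife(times, conc, terminal_window),
                 error = function(e) list(k_e = NA_real_, t_half = NA_real_,
                                          n = 0, r_squared = NA_real_,
                                          window = terminal_window,
                                          flagged = TRUE))
  aucs <- vapply(windows, function(w) auc_trapezoid(times, conc, w[1], w[2]),
                 numeric(1))
  cavgs <- vapply(seq_along(windows), function(i) {
    w <- windows[[i]]; cavg(aucs[i], w[2] - w[1])
  }, numeric(1))
  names(cavgs) <- names(windows)
  acc <- if (all(c("day1", "ss") %in% names(windows)))
    accumulation_ratio(aucs[["ss"]], aucs[["day1"]]) else NA_real_
  structure(list(C_max = peak$C_max, T_max = peak$T_max, auc = aucs,
                 c_avg = cavgs, k_e = th$k_e, t_half = th$t_half,
                 halflife_diagnostics = th, accumulation_ratio = acc,
                 tau = tau),
            class = "nca_report")
}

#' @export
print.nca_report <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g at %g h | t1/2 %.3g h (n=%d, R2=%.3f)\n",
              x$C_max, x$T_max, x$t_half, x$halflife_diagnostics$n,
              x$halflife_diagnostics$r_squared))
  for (w in names(x$auc))
    cat(sprintf("  AUC[%s] %.6g (Cavg %.6g)\n", w, x$auc[[w]], x$c_avg[[w]]))
  if (!is.na(x$accumulation_ratio))
    cat(sprintf("  accumulation ratio %.3g\n", x$accumulation_ratio))
  invisible(x)
}
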