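## Functional-assay numerics: ACMA dequench percentage, Michaelis-Menten
## nonlinear regression, and four-parameter-logistic melting fits with
## melting-temperature shifts.

#' ACMA dequench percentage
#'
#' Fluorescence recovery after substrate addition, read from a dequench
#' trace at the assay's event times (gradient established by ~3 min,
#' substrate response by ~4 min, gradient collapsed by ~5 min). Two
#' formulas are provided: the literal as-printed form
#' (FI4 - FI3) / (FI5 / FI3) * 100, and the conventional span-normalized
#' form (FI4 - FI3) / (FI5 - FI3) * 100 (the default; the as-printed
#' denominator is a ratio and therefore dimensionally odd, so both are
#' retained without guessing intent).
#'
#' @param trace data frame with `time` (min) and `FI` columns (or a CSV
#'   path).
#' @param formula `"span-normalized"` (default) or `"as-printed"`.
#' @param events numeric times (min) of the three read points.
#' @param tol maximum distance (min) from an event time to the nearest
#'   sample.
#' @return dequench percentage.
#' @export
dequench_percent <- function(trace, formula = c("span-normalized", "as-printed"),
                             events = c(3, 4, 5), tol = 0.1) {
  formula <- match.arg(formula)
  if (is.character(trace)) trace <- read.csv(trace)
  if (!all(c("time", "FI") %in% names(trace)))
    stop_elevator("schema", "trace needs `time` and `FI` columns")
  if (any(diff(trace$time) <= 0))
    stop_elevator("validation", "timestamps must be strictly increasing")
  fi <- vapply(events, function(t0) {
    i <- which.min(abs(trace$time - t0))
    if (abs(trace$time[i] - t0) > tol)
      stop_elevator("validation", "no sample within %.2f min of t = %g", tol, t0)
    trace$FI[i]
  }, 0)
  fi3 <- fi[1]; fi4 <- fi[2]; fi5 <- fi[3]
  if (formula == "as-printed") {
    if (fi3 == 0 || fi5 == 0)
      stop_elevator("degenerate", "FI5/FI3 denominator is zero")
    (fi4 - fi3) / (fi5 / fi3) * 100
  } else {
    if (fi5 == fi3)
      stop_elevator("degenerate", "flat trace: FI5 equals FI3")
    (fi4 - fi3) / (fi5 - fi3) * 100
  }
}

#' Michaelis-Menten fit
#'
#' Least-squares fit of v = V_max * S / (K_M + S) to replicate
#' dose-response data by Levenberg-Marquardt, initialized at
#' V_max = max response and K_M = the concentration nearest half-max.
#'
#' @param concentrations substrate concentrations (mM), >= 4 distinct.
#' @param responses numeric vector (one replicate) or matrix with one
#'   column per replicate, rows matching `concentrations`.
#' @return Object of class `KineticsFit`: `km`, `vmax`, standard errors,
#'   residual summary and the flattened data.
#' @export
mm_fit <- function(concentrations, responses) {
  responses <- as.matrix(responses)
  if (length(unique(concentrations)) < 4L)
    stop_elevator("validation", "need >= 4 distinct concentrations")
  if (nrow(responses) != length(concentrations))
    stop_elevator("schema", "responses rows must match concentrations")
  S <- rep(concentrations, ncol(responses))
  v <- as.numeric(responses)
  if (length(unique(v)) == 1L)
    stop_elevator("degenerate", "all responses identical")
  vmax0 <- max(v)
  km0 <- concentrations[which.min(abs(rowMeans(responses) - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * S / (km + S),
                      start = list(vmax = vmax0, km = max(km0, 1e-6)),
                      lower = c(vmax = 0, km = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) stop_elevator("fit", "Michaelis-Menten fit failed: %s",
                                      conditionMessage(e)))
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(list(km = unname(co["km"]), vmax = unname(co["vmax"]),
                 km_se = unname(se["km"]), vmax_se = unname(se["vmax"]),
                 rss = sum(residuals(fit)^2),
                 concentrations = concentrations, responses = responses),
            class = "KineticsFit")
}

#' @export
print.KineticsFit <- function(x, ...) {
  cat(sprintf("<KineticsFit> K_M = %.2f +/- %.2f mM, V_max = %.2f +/- %.2f\n",
              x$km, x$km_se, x$vmax, x$vmax_se))
  invisible(x)
}

#' Four-parameter logistic melting fit
#'
#' Fit of y = d + (a - d) / (1 + (T / T_m)^b) on linear temperature,
#' with T_m the inflection (EC50-analogue): `a` is the low-temperature
#' plateau, `d` the high-temperature plateau, `b` the slope.
#' Levenberg-Marquardt with documented initialization (plateaus from the
#' temperature extremes, T_m at the half-signal crossing).
#'
#' @param temperatures degrees C, >= 5 values spanning the transition.
#' @param signal measured signal (e.g. GFP fluorescence of the intact
#'   dimer).
#' @return Object of class `MeltFit`: `tm` (degrees C), `slope`,
#'   `lower`, `upper` plateaus, standard errors.
#' @export
logistic4_fit <- function(temperatures, signal) {
  if (length(temperatures) < 5L)
    stop_elevator("validation", "need >= 5 temperatures")
  if (length(signal) != length(temperatures))
    stop_elevator("schema", "signal length must match temperatures")
  rng <- range(signal)
  if (diff(rng) < .Machine$double.eps^0.5 * max(1, abs(rng[2])))
    stop_elevator("degenerate", "flat signal: no transition to fit")
  ord <- order(temperatures)
  Tq <- temperatures[ord]; y <- signal[ord]
  k <- max(2L, round(length(y) / 5))
  a0 <- mean(head(y, k)); d0 <- mean(tail(y, k))
  half <- (a0 + d0) / 2
  tm0 <- Tq[which.min(abs(y - half))]
  b0 <- if (a0 > d0) 10 else -10
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (Tq / tm)^b),
                      start = list(a = a0, d = d0, tm = max(tm0, 1), b = b0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) stop_elevator("fit", "4PL fit failed: %s",
                                      conditionMessage(e)))
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4),
                                              c("a", "d", "tm", "b")))
  lower <- min(co["a"], co["d"]); upper <- max(co["a"], co["d"])
  if (co["tm"] < min(Tq) || co["tm"] > max(Tq))
    warn_elevator("fit", "fitted T_m %.1f outside the measured range", co["tm"])
  structure(list(tm = unname(co["tm"]), slope = unname(co["b"]),
                 lower = unname(lower), upper = unname(upper),
                 tm_se = unname(se["tm"]),
                 rss = sum(residuals(fit)^2),
                 init = c(a = a0, d = d0, tm = tm0, b = b0)),
            class = "MeltFit")
}

#' @export
print.MeltFit <- function(x, ...) {
  cat(sprintf("<MeltFit> T_m = %.2f C (slope %.1f, plateaus %.1f / %.1f)\n",
              x$tm, x$slope, x$lower, x$upper))
  invisible(x)
}

#' Melting-temperature shift
#'
#' Difference of apparent melting temperatures between a condition (e.g.
#' in the presence of a lipid) and its control.
#'
#' @param fit,control [logistic4_fit()] results.
#' @return delta T_m in degrees C (condition minus control).
#' @export
delta_tm <- function(fit, control) fit$tm - control$tm

#' @importFrom stats residuals setNames
NULL
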