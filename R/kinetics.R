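## Quantitative enzymology of the PER2 phosphoswitch.
##
## Under substrate-depletion conditions with [S]0 << Km, product formation
## follows P(t) = S0 * (1 - exp(-(kcat/Km) * [E] * t)), so a single endpoint
## inverts exactly to the apparent second-order rate constant
## kcat/Km = -ln(1 - P/S0) / ([E] * t). Reporter half-lives come from a
## one-phase exponential decay fitted from the moment of translation
## shut-off (cycloheximide addition) to the plateau at minimum signal, and
## substrate selectivity couples to protein stability through an ordinary
## least-squares regression of half-life on the FASP/Degron efficiency
## ratio. Replicates are aggregated as mean +/- s.d. throughout.

#' Build a progress curve
#' @param timepoints strictly increasing times.
#' @param signal signal per timepoint (same length).
#' @param time_unit "s" or "hr".
#' @param signal_unit free-text unit (e.g. "uM", "counts", "peak_volume").
#' @param replicate replicate id.
#' @param substrate substrate label (e.g. "FASP", "Degron").
#' @return a `progress_curve`.
#' @export
progress_curve <- function(timepoints, signal, time_unit = "s",
                           signal_unit = "uM", replicate = 1L,
                           substrate = "other") {
  stopifnot(length(timepoints) == length(signal))
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  structure(list(timepoints = as.numeric(timepoints),
                 signal = as.numeric(signal), time_unit = time_unit,
                 signal_unit = signal_unit, replicate = replicate,
                 substrate = substrate),
            class = "progress_curve")
}

#' Initial rate from the early-time window of a progress curve
#'
#' Least-squares slope of signal versus time over the selected window.
#' When `S0` is supplied the window is additionally restricted to points
#' below `max_conversion` (default 10 percent) substrate conversion.
#'
#' @param curve a [progress_curve()].
#' @param window `c(tmin, tmax)` time window (default: all points).
#' @param S0 optional initial substrate concentration in signal units.
#' @param max_conversion maximal fractional conversion kept (default 0.1).
#' @return list(rate, se, n_points, window): slope in signal units per
#'   time unit with its standard error.
#' @export
initial_rate <- function(curve, window = NULL, S0 = NULL,
                         max_conversion = 0.1) {
  stopifnot(inherits(curve, "progress_curve"))
  keep <- rep(TRUE, length(curve$timepoints))
  if (!is.null(window))
    keep <- keep & curve$timepoints >= window[1] &
      curve$timepoints <= window[2]
  if (!is.null(S0))
    keep <- keep & (curve$signal - curve$signal[1]) <= max_conversion * S0
  if (sum(keep) < 3)
    stop("data error: fewer than 3 points in the initial-rate window")
  t <- curve$timepoints[keep]; y <- curve$signal[keep]
  fit <- stats::lm(y ~ t)
  # suppress the "perfect fit" note: exact lines are legitimate input here
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(sm["t", "Estimate"]),
       se = unname(sm["t", "Std. Error"]),
       n_points = sum(keep), window = range(t))
}

#' Enzymatic efficiency (kcat/Km) from pseudo-first-order depletion
#'
#' Inverts `P(t) = S0 * (1 - exp(-(kcat/Km) * E * t))`, the exact solution
#' when `S0 << Km` so that substrate depletion is pseudo-first-order in S.
#' Multiple product values (replicates) are converted individually and
#' summarized as mean +/- s.d.
#'
#' @param P product concentration(s) at time `t` (M); one value per
#'   replicate.
#' @param E_total total enzyme concentration (M).
#' @param S0 initial substrate concentration (M).
#' @param t incubation time (s).
#' @return an `efficiency_estimate`: list(kcat_over_Km (M^-1 s^-1), sd,
#'   replicates, conditions).
#' @export
estimate_efficiency <- function(P, E_total, S0, t) {
  stopifnot(E_total > 0, S0 > 0, t > 0)
  if (any(P < 0)) stop("data error: negative product concentration")
  if (any(P >= S0))
    stop("saturation error: product >= S0; pseudo-first-order estimate undefined")
  k <- -log(1 - P / S0) / (E_total * t)
  structure(list(kcat_over_Km = mean(k),
                 sd = if (length(k) > 1) stats::sd(k) else 0,
                 replicates = k,
                 conditions = list(E_total = E_total, S0 = S0, t = t)),
            class = "efficiency_estimate")
}

#' Pointwise site ratio with first-order error propagation
#'
#' Ratio of two matched phosphosite progress curves (e.g. consensus pS662
#' over priming pS659 peak volumes), with uncertainty propagated to first
#' order from a common spectral noise standard deviation:
#' `sd(r) = r * sqrt((noise/num)^2 + (noise/den)^2)`. Timepoints where the
#' denominator is below three times the noise floor are flagged undefined
#' (NA ratio).
#'
#' @param numerator,denominator [progress_curve()]s with identical
#'   timepoints.
#' @param noise_sd spectrum noise standard deviation (signal units).
#' @return a `site_ratio_series`: data.frame(time, ratio, sd, defined).
#' @export
site_ratio <- function(numerator, denominator, noise_sd) {
  stopifnot(inherits(numerator, "progress_curve"),
            inherits(denominator, "progress_curve"))
  if (!isTRUE(all.equal(numerator$timepoints, denominator$timepoints)))
    stop("site_ratio requires matched timepoints")
  stopifnot(noise_sd >= 0)
  num <- numerator$signal; den <- denominator$signal
  defined <- den > 3 * noise_sd
  ratio <- ifelse(defined, num / den, NA_real_)
  sdr <- ifelse(defined,
                abs(ratio) * sqrt((noise_sd / num)^2 + (noise_sd / den)^2),
                NA_real_)
  structure(data.frame(time = numerator$timepoints, ratio = ratio,
                       sd = sdr, defined = defined),
            class = c("site_ratio_series", "data.frame"))
}

#' One-phase exponential decay fit (reporter half-life)
#'
#' Nonlinear least squares of
#' `Y(t) = (Y0 - plateau) * exp(-k * (t - t_chx)) + plateau` over the
#' window from the treatment time `t_chx` (e.g. cycloheximide addition) to
#' the observed minimum of the series. Starting values are deterministic:
#' Y0 from the first post-treatment point, plateau from the window minimum,
#' k from a log-linear fit of the plateau-subtracted signal. Half-life is
#' `ln 2 / k`.
#'
#' @param time time vector (hr).
#' @param signal raw reporter signal (e.g. luminescence counts), positive.
#' @param t_chx treatment time (hr); fitting starts here.
#' @return a `decay_fit`: list(Y0, span, plateau, k (per hr), half_life
#'   (hr), fit_window, residual_sd, n_points).
#' @export
fit_one_phase_decay <- function(time, signal, t_chx = 0) {
  stopifnot(length(time) == length(signal))
  keep <- time >= t_chx
  t <- time[keep]; y <- signal[keep]
  if (length(t) < 5)
    stop("data error: need at least 5 points after t_chx")
  if (any(y <= 0)) stop("data error: signal must be positive")
  # fit window ends at the observed minimum (the plateau)
  imin <- which.min(y)
  if (imin < 5) imin <- length(t)
  t <- t[seq_len(imin)]; y <- y[seq_len(imin)]
  if (max(y) - min(y) <= .Machine$double.eps * max(y) ||
      stats::sd(y) < 1e-12 * mean(y))
    stop("no-decay error: series is constant")
  plateau0 <- min(y)
  Y00 <- y[1]
  pos <- y - plateau0 > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos] - plateau0) ~ t[pos]))[2]
    max(1e-6, -unname(sl))
  } else 1
  span0 <- max(Y00 - plateau0, .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ span * exp(-k * (t - t_chx)) + plateau,
      start = list(span = span0, k = k0, plateau = plateau0),
      lower = c(span = 0, k = 0, plateau = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit error: one-phase decay did not converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["k"]] <= 0 || p[["span"]] <= 0)
    stop("no-decay error: fitted decay rate is not positive")
  structure(list(Y0 = unname(p[["span"]] + p[["plateau"]]),
                 span = unname(p[["span"]]),
                 plateau = unname(p[["plateau"]]),
                 k = unname(p[["k"]]),
                 half_life = log(2) / unname(p[["k"]]),
                 fit_window = range(t),
                 residual_sd = stats::sd(stats::resid(fit)),
                 n_points = length(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> half-life %.3g hr (k = %.3g /hr, plateau %.3g, span %.3g)\n",
              x$half_life, x$k, x$plateau, x$span))
  invisible(x)
}

#' Regression of reporter half-life on the FASP/Degron efficiency ratio
#'
#' Ordinary least squares of half-life (hr) on the ratio of enzymatic
#' efficiencies, with the 95 percent confidence interval of the slope from
#' the t distribution and a pointwise confidence band for plotting.
#'
#' @param ratio per-mutant FASP/Degron kcat/Km ratio.
#' @param half_life per-mutant reporter half-life (hr).
#' @param band_points number of points in the exported confidence band.
#' @return a `regression_fit`: list(slope, intercept, slope_ci (95 percent),
#'   r_squared, p_value, band (data.frame ratio, fit, lwr, upr), n).
#' @export
efficiency_halflife_regression <- function(ratio, half_life,
                                           band_points = 50) {
  stopifnot(length(ratio) == length(half_life))
  if (length(ratio) < 3)
    stop("data error: need at least 3 mutants for regression")
  df <- data.frame(ratio = ratio, half_life = half_life)
  fit <- stats::lm(half_life ~ ratio, data = df)
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, "ratio", level = 0.95))
  grid <- data.frame(ratio = seq(min(ratio), max(ratio),
                                 length.out = band_points))
  band <- cbind(grid,
                as.data.frame(suppressWarnings(
                  stats::predict(fit, grid, interval = "confidence",
                                 level = 0.95))))
  structure(list(slope = unname(stats::coef(fit)["ratio"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_ci = as.numeric(ci),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["ratio", "Pr(>|t|)"]),
                 band = band, n = length(ratio), lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.3g [%.3g, %.3g], intercept %.3g, R^2 %.3f, p = %.3g (n = %d)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Serialize a fit result as JSON
#' @param fit a `decay_fit`, `efficiency_estimate` or `regression_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$lm <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
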