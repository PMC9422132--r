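# Tracer kinetics and dose-response fitting: isotope-efflux rate constants
# from log-linear regression, generic slope extraction from imaging time
# series, and four-parameter logistic (Hill/IC50) fits.

#' Isotope efflux series
#'
#' Paired activity counts of an effluxing tracer (86Rb+) and an
#' extracellular-space marker (3H-mannitol) over time.
#'
#' @param time_s sample times (s), strictly increasing, starting at 0.
#' @param rb_counts tracer activity per time point (counts, >= 0).
#' @param mannitol_counts extracellular background activity (counts, >= 0).
#' @param label condition label.
#' @return An object of class `efflux_series`.
#' @export
efflux_series <- function(time_s, rb_counts, mannitol_counts = NULL,
                          label = "control") {
  if (is.null(mannitol_counts)) mannitol_counts <- rep(0, length(time_s))
  if (length(time_s) != length(rb_counts) ||
      length(time_s) != length(mannitol_counts)) {
    stop("time_s, rb_counts and mannitol_counts must have equal length",
         call. = FALSE)
  }
  if (time_s[1] != 0) stop("first time point must be 0", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(rb_counts < 0) || any(mannitol_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(list(time_s = as.numeric(time_s),
                 rb_counts = as.numeric(rb_counts),
                 mannitol_counts = as.numeric(mannitol_counts),
                 label = label),
            class = "efflux_series")
}

#' Background-correct an efflux series
#'
#' Subtracts the mannitol-inferred extracellular background from the tracer
#' counts (optionally scaled); values driven negative are clipped to zero
#' with a warning. The default correction is a direct subtraction;
#' `scale` makes the policy swappable.
#'
#' @param series an [efflux_series()].
#' @param scale multiplier applied to the background before subtraction.
#' @return Numeric vector of corrected activities.
#' @export
background_correct <- function(series, scale = 1) {
  stopifnot(inherits(series, "efflux_series"))
  corrected <- series$rb_counts - scale * series$mannitol_counts
  if (any(corrected < 0)) {
    warning(sprintf("background exceeded tracer counts at %d point(s); clipped to zero",
                    sum(corrected < 0)), call. = FALSE)
    corrected <- pmax(corrected, 0)
  }
  corrected
}

#' Efflux rate constant by log-linear regression
#'
#' Regresses `ln(A_T / A_0)` of the background-corrected activity on time;
#' the rate constant is the negated slope, reported in min^-1.
#'
#' @param series an [efflux_series()].
#' @param scale background scale passed to [background_correct()].
#' @return An object of class `efflux_fit` with `rate_constant_per_min`,
#'   `intercept`, `r_squared`, and the `lm` fit.
#' @examples
#' s <- efflux_series(c(0, 20, 40, 60, 80), 1e4 * exp(-0.4 * c(0, 20, 40, 60, 80) / 60))
#' efflux_rate_constant(s)$rate_constant_per_min # 0.40
#' @export
efflux_rate_constant <- function(series, scale = 1) {
  stopifnot(inherits(series, "efflux_series"))
  if (length(series$time_s) < 3) {
    stop("at least 3 time points are required", call. = FALSE)
  }
  a <- background_correct(series, scale)
  if (any(a <= 0)) {
    stop(sprintf("non-positive corrected activity at time(s) %s s; cannot take logarithm",
                 paste(series$time_s[a <= 0], collapse = ", ")),
         call. = FALSE)
  }
  y <- log(a / a[1])
  t_min <- series$time_s / 60
  fit <- stats::lm(y ~ t_min)
  # noiseless series are a designed use (exact-recovery checks): silence
  # summary.lm's perfect-fit warning
  s <- suppressWarnings(summary(fit))
  structure(list(rate_constant_per_min = -unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 fit = fit, label = series$label),
            class = "efflux_fit")
}

#' @export
print.efflux_fit <- function(x, ...) {
  cat(sprintf("Efflux rate constant %.3f min^-1 (R^2 = %.3f, %s)\n",
              x$rate_constant_per_min, x$r_squared, x$label))
  invisible(x)
}

#' Linear rate from a time series
#'
#' OLS slope of a signal on time, for imaging read-outs (dye translocation,
#' ion-indicator fluorescence). Rates are reported per minute regardless of
#' the input time unit.
#'
#' @param time sample times.
#' @param signal signal values (same length).
#' @param time_unit `"min"` (default) or `"s"`.
#' @return List with `slope_per_min`, `slope_se_per_min`, `intercept`,
#'   `r_squared`, `n`.
#' @export
rate_from_series <- function(time, signal, time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(signal)) {
    stop("time and signal must have equal length", call. = FALSE)
  }
  if (length(time) < 3) stop("at least 3 points are required", call. = FALSE)
  if (stats::var(time) == 0) {
    stop("singular design: all time points are equal", call. = FALSE)
  }
  t_min <- if (time_unit == "s") time / 60 else time
  fit <- stats::lm(signal ~ t_min)
  # noiseless series are a designed use (exact-recovery checks): silence
  # summary.lm's perfect-fit warning
  s <- suppressWarnings(summary(fit))
  list(slope_per_min = unname(stats::coef(fit)[2]),
       slope_se_per_min = unname(s$coefficients[2, 2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       n = length(time))
}

#' Four-parameter logistic (Hill) dose-response fit
#'
#' Fits `Y = Ymin + (Ymax - Ymin) / (1 + (IC50 / X)^HillSlope)` by bounded
#' Levenberg-Marquardt nonlinear least squares. Initialization: plateaus
#' from the response extremes, IC50 from the geometric mean of the doses
#' bracketing half-maximum, Hill slope 1; bounds IC50 > 0 and Hill slope in
#' [0.1, 10].
#'
#' @param dose_um doses (uM), at least 4, all positive.
#' @param response measured responses.
#' @return An object of class `dose_response_fit` with `ic50`, `hill_slope`,
#'   `y_min`, `y_max`, and the `nls` fit.
#' @examples
#' d <- c(1, 3, 10, 30, 100)
#' y <- 2 + (90 - 2) / (1 + (10.7 / d)^1)
#' hill_fit(d, y)$ic50
#' @export
hill_fit <- function(dose_um, response) {
  if (length(dose_um) != length(response)) {
    stop("dose_um and response must have equal length", call. = FALSE)
  }
  if (length(dose_um) < 4) {
    stop("at least 4 doses are required", call. = FALSE)
  }
  if (any(dose_um <= 0)) stop("doses must be positive", call. = FALSE)
  span <- diff(range(response))
  if (span <= 1e-12 * max(abs(response), 1)) {
    stop("flat response (y_max ~ y_min): no transition to fit", call. = FALSE)
  }
  y_min0 <- min(response); y_max0 <- max(response)
  half <- (y_min0 + y_max0) / 2
  ord <- order(dose_um)
  d_s <- dose_um[ord]; r_s <- response[ord]
  below <- which(r_s <= half); above <- which(r_s >= half)
  ic50_0 <- if (length(below) && length(above)) {
    sqrt(d_s[max(below)] * d_s[min(above)])
  } else exp(mean(log(d_s)))
  start <- list(y_min = y_min0, y_max = y_max0, ic50 = ic50_0, hill = 1)
  df <- data.frame(x = dose_um, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y_min + (y_max - y_min) / (1 + (ic50 / x)^hill),
                      data = df, start = start,
                      lower = c(-Inf, -Inf, 1e-9, 0.1),
                      upper = c(Inf, Inf, Inf, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("Hill fit failed to converge (%s); initialization: y_min=%.3g y_max=%.3g ic50=%.3g hill=1",
                   conditionMessage(e), y_min0, y_max0, ic50_0),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  structure(list(ic50 = unname(cf["ic50"]),
                 hill_slope = unname(cf["hill"]),
                 y_min = unname(cf["y_min"]),
                 y_max = unname(cf["y_max"]),
                 fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.3g uM, Hill slope %.2f, plateaus [%.3g, %.3g]\n",
              x$ic50, x$hill_slope, x$y_min, x$y_max))
  invisible(x)
}
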