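# Seeded synthetic-data generators with the statistical structure each
# analysis stage assumes: dye-dilution perfusion series (multiplicative
# fluorescence noise), osmotic-challenge datasets (additive animal scatter),
# isotope efflux (Poisson counts), and Hill dose-response curves (additive
# noise). A fixed seed gives byte-identical output; the caller's RNG state
# is left untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a ventriculo-cisternal perfusion series
#'
#' Forward model of the dye-dilution experiment: at steady state the
#' outflow fluorescence is `Co = Ci * ri / (ri + Vp)`. The first
#' `equilibration_min` minutes ramp towards steady state as a saturating
#' exponential (mixing of the ventricular dead volume); the ramp lies
#' outside every default analysis window. Fractions are perturbed by
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#'
#' @param true_vp true CSF production rate (ul min^-1).
#' @param ri infusion rate (ul min^-1).
#' @param ci inflow fluorescence (a.u.).
#' @param noise_cv multiplicative noise CV on the outflow fluorescence.
#' @param duration_min total duration (min).
#' @param interval_min collection-fraction length (min).
#' @param equilibration_min time constant region of the initial ramp (min).
#' @param seed RNG seed (NULL for the current RNG stream).
#' @param animal_id,condition labels.
#' @return A [perfusion_series()].
#' @examples
#' s <- simulate_perfusion(6.8, seed = 1)
#' windowed_vp(s, c(50, 65))
#' @export
simulate_perfusion <- function(true_vp = 6.8, ri = 9, ci = 100,
                               noise_cv = 0.02, duration_min = 120,
                               interval_min = 5, equilibration_min = 30,
                               seed = NULL, animal_id = "sim",
                               condition = "vehicle") {
  if (true_vp < -ri) stop("true_vp must be >= -ri", call. = FALSE)
  with_seed(seed, {
    mid <- seq(interval_min / 2, duration_min - interval_min / 2,
               by = interval_min)
    co_ss <- ci * ri / (ri + true_vp)
    tau <- equilibration_min / 4
    # saturating-exponential mixing ramp, truncated at the equilibration
    # boundary so analysis windows see the exact steady state
    ramp <- ifelse(mid < equilibration_min, exp(-mid / tau), 0)
    co <- co_ss + (ci - co_ss) * ramp
    if (noise_cv > 0) co <- co * (1 + stats::rnorm(length(co), 0, noise_cv))
    co <- pmax(co, 1e-6 * ci)
    perfusion_series(mid, ci, co, infusion_rate_ul_min = ri,
                     animal_id = animal_id, condition = condition)
  })
}

#' Simulate an osmotic-challenge dataset
#'
#' Per-animal production rates `Vp_i = baseline + slope * dOsm_i + eps_i`
#' with `slope = lp * area` in mixed units (ul min^-1 mOsm^-1) and
#' independent Gaussian animal scatter.
#'
#' @param baseline_vp baseline production rate (ul min^-1).
#' @param slope_ul_min_mosm true regression slope; alternatively supply
#'   `lp` and `area_cm2` whose product (after unit conversion) is used.
#' @param osm_offsets imposed ventricular osmolality offsets (mOsm).
#' @param noise_sd animal scatter SD (ul min^-1); see
#'   [calibrate_noise_for_r2()] to target a fit quality.
#' @param seed RNG seed.
#' @param lp,area_cm2 optional permeability (cm s^-1 Osm^-1) and area used
#'   to derive the slope when `slope_ul_min_mosm` is NULL.
#' @return List with `delta_osm_mosm`, `vp_ul_min`, and the embedded truth.
#' @export
simulate_osmotic_challenge <- function(baseline_vp = 6.8,
                                       slope_ul_min_mosm = 0.023,
                                       osm_offsets = seq(-50, 50, length.out = 11),
                                       noise_sd = NULL, seed = NULL,
                                       lp = NULL, area_cm2 = NULL) {
  if (is.null(slope_ul_min_mosm)) {
    if (is.null(lp) || is.null(area_cm2)) {
      stop("supply slope_ul_min_mosm, or lp and area_cm2", call. = FALSE)
    }
    # cm/s/Osm * cm2 -> ul/min/mOsm
    slope_ul_min_mosm <- cm3_s_to_ul_min(lp * area_cm2) * 1e-3
  }
  if (length(osm_offsets) < 3) stop("need at least 3 animals", call. = FALSE)
  if (is.null(noise_sd)) {
    noise_sd <- calibrate_noise_for_r2(0.48, slope_ul_min_mosm, osm_offsets)
  }
  with_seed(seed, {
    vp <- baseline_vp + slope_ul_min_mosm * osm_offsets +
      stats::rnorm(length(osm_offsets), 0, noise_sd)
    list(delta_osm_mosm = osm_offsets, vp_ul_min = vp,
         truth = list(baseline_vp = baseline_vp,
                      slope_ul_min_mosm = slope_ul_min_mosm,
                      noise_sd = noise_sd))
  })
}

#' Noise level reproducing a target regression R-squared
#'
#' For a linear model with fixed design, the population R-squared is
#' `s^2 var(x) / (s^2 var(x) + sigma^2)`; inverting gives the noise SD
#' that makes the expected fit quality match a target.
#'
#' @param target_r2 target R-squared in (0, 1).
#' @param slope true slope.
#' @param x design points.
#' @return Noise standard deviation.
#' @examples
#' calibrate_noise_for_r2(0.48, 0.023, seq(-50, 50, 10))
#' @export
calibrate_noise_for_r2 <- function(target_r2, slope, x) {
  if (target_r2 <= 0 || target_r2 >= 1) {
    stop("target_r2 must be in (0, 1)", call. = FALSE)
  }
  signal_var <- slope^2 * stats::var(x)
  sqrt(signal_var * (1 - target_r2) / target_r2)
}

#' Simulate an isotope efflux series
#'
#' Tracer counts are Poisson with mean `a0 * exp(-k t) + bg`; the mannitol
#' background channel is Poisson with mean `bg`.
#'
#' @param k_per_min true efflux rate constant (min^-1), >= 0.
#' @param a0 initial tracer count level.
#' @param times_s sampling times (s).
#' @param bg_level extracellular background count level.
#' @param noise logical; FALSE returns the noiseless means (useful for
#'   exact-recovery checks).
#' @param seed RNG seed.
#' @param label condition label.
#' @return An [efflux_series()].
#' @export
simulate_efflux <- function(k_per_min = 0.40, a0 = 10000,
                            times_s = c(0, 20, 40, 60, 80), bg_level = 200,
                            noise = TRUE, seed = NULL, label = "sim") {
  if (k_per_min < 0) stop("k_per_min must be >= 0", call. = FALSE)
  with_seed(seed, {
    mean_rb <- a0 * exp(-k_per_min * times_s / 60) + bg_level
    mean_bg <- rep(bg_level, length(times_s))
    if (noise) {
      rb <- stats::rpois(length(times_s), mean_rb)
      bg <- stats::rpois(length(times_s), mean_bg)
    } else {
      rb <- mean_rb; bg <- mean_bg
    }
    efflux_series(times_s, rb, bg, label = label)
  })
}

#' Simulate a dose-response table
#'
#' Forward-evaluates the four-parameter logistic
#' `Y = Ymin + (Ymax - Ymin)/(1 + (IC50/X)^Hill)` plus additive Gaussian
#' noise.
#'
#' @param ic50 true IC50 (uM).
#' @param hill true Hill slope.
#' @param y_min,y_max response plateaus.
#' @param doses dose vector (uM); default two-decade log spacing around
#'   the IC50.
#' @param noise_sd additive noise SD (response units); default 2% of the
#'   plateau span.
#' @param seed RNG seed.
#' @return Data frame with columns `dose_um`, `response`, plus a `truth`
#'   attribute.
#' @export
simulate_dose_response <- function(ic50 = 10.7, hill = 1, y_min = 0,
                                   y_max = 100, doses = NULL,
                                   noise_sd = NULL, seed = NULL) {
  if (ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (y_max < y_min) stop("y_max must be >= y_min", call. = FALSE)
  if (is.null(doses)) {
    doses <- ic50 * 10^seq(-1.5, 1.5, length.out = 9)
  }
  if (is.null(noise_sd)) noise_sd <- 0.02 * (y_max - y_min)
  with_seed(seed, {
    y <- y_min + (y_max - y_min) / (1 + (ic50 / doses)^hill)
    if (noise_sd > 0) y <- y + stats::rnorm(length(doses), 0, noise_sd)
    out <- data.frame(dose_um = doses, response = y)
    attr(out, "truth") <- list(ic50 = ic50, hill = hill,
                               y_min = y_min, y_max = y_max,
                               noise_sd = noise_sd)
    out
  })
}
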