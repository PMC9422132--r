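# The permeability derivation ledger: regression slope -> trans-epithelial
# Lp -> per-membrane Lp -> per-true-area luminal Lp -> the osmotic gradient
# required to drive the observed secretion by conventional osmosis, plus the
# isotonic ion-transfer rate and van't Hoff pressure equivalents.

#' Trans-epithelial osmotic water permeability from the challenge slope
#'
#' Converts the osmotic-challenge regression slope (ul min^-1 mOsm^-1,
#' secretion change per imposed osmolality step) and the apparent membrane
#' area into an osmotic water permeability: `Lp = slope / area` with unit
#' conversions ul -> cm^3, min -> s, mOsm -> Osm.
#'
#' @param slope_ul_min_mosm regression slope (ul min^-1 mOsm^-1).
#' @param area_apparent_cm2 apparent (cross-sectional) area (cm^2).
#' @return Lp,trans in cm s^-1 Osm^-1 (per apparent area).
#' @examples
#' lp_from_slope(0.023, 4.6) # 8.3e-5 cm/s/Osm
#' @export
lp_from_slope <- function(slope_ul_min_mosm, area_apparent_cm2) {
  stopifnot_positive(slope_ul_min_mosm = slope_ul_min_mosm,
                     area_apparent_cm2 = area_apparent_cm2)
  # (ul/min)/mOsm -> (cm3/s)/Osm : *1e-3/60 for volume rate, *1e3 for Osm
  slope_cm3_s_osm <- ul_min_to_cm3_s(slope_ul_min_mosm) * 1e3
  slope_cm3_s_osm / area_apparent_cm2
}

#' Per-membrane permeability of two membranes in series
#'
#' The trans-epithelial measurement lumps the luminal and basolateral
#' membranes in series; each membrane alone is twice as permeable.
#'
#' @param lp_trans trans-epithelial Lp (cm s^-1 Osm^-1).
#' @return Single-membrane Lp (cm s^-1 Osm^-1).
#' @export
split_series_membranes <- function(lp_trans) {
  if (lp_trans < 0) stop("lp_trans must be non-negative", call. = FALSE)
  2 * lp_trans
}

#' Luminal permeability per true membrane area
#'
#' Rescales a per-apparent-area membrane permeability to the true
#' (microvillus-amplified) membrane area.
#'
#' @param lp_membrane single-membrane Lp per apparent area (cm s^-1 Osm^-1).
#' @param amplification fold surface amplification (>= 1).
#' @return Luminal Lp per true area (cm s^-1 Osm^-1).
#' @export
lp_per_true_area <- function(lp_membrane, amplification) {
  if (amplification < 1) stop("amplification must be >= 1", call. = FALSE)
  if (lp_membrane < 0) stop("lp_membrane must be non-negative", call. = FALSE)
  lp_membrane / amplification
}

#' Osmotic gradient required to drive a given secretion rate
#'
#' For conventional osmosis, the volume flux per area `Vp/A` requires a
#' driving gradient `dOsm_req = (Vp/A) / Lp`. With a plasma osmolality
#' supplied, the implied ventricular osmolality is also reported.
#'
#' @param vp_ul_min CSF production rate (ul min^-1).
#' @param area_cm2 membrane area matching the permeability's reference
#'   area (cm^2).
#' @param lp_cm_s_osm osmotic water permeability (cm s^-1 Osm^-1).
#' @param plasma_osm_mosm optional plasma osmolality (mOsm).
#' @return An object of class `osmotic_requirement`: `vp_ul_min`,
#'   `delta_osm_req_mosm`, and `ventricular_osm_mosm` (NA without plasma).
#' @examples
#' required_gradient(6.8, 4.6, 8.7e-5, plasma_osm_mosm = 307)
#' @export
required_gradient <- function(vp_ul_min, area_cm2, lp_cm_s_osm,
                              plasma_osm_mosm = NULL) {
  stopifnot_positive(area_cm2 = area_cm2, lp_cm_s_osm = lp_cm_s_osm)
  if (vp_ul_min < 0) stop("vp_ul_min must be non-negative", call. = FALSE)
  flux_cm_s <- ul_min_to_cm3_s(vp_ul_min) / area_cm2
  req_osm <- flux_cm_s / lp_cm_s_osm
  req_mosm <- req_osm * 1e3
  structure(list(vp_ul_min = vp_ul_min,
                 delta_osm_req_mosm = req_mosm,
                 ventricular_osm_mosm = if (is.null(plasma_osm_mosm))
                   NA_real_ else plasma_osm_mosm + req_mosm),
            class = "osmotic_requirement")
}

#' @export
print.osmotic_requirement <- function(x, ...) {
  cat(sprintf("Required osmotic gradient: %.0f mOsm above plasma",
              x$delta_osm_req_mosm))
  if (!is.na(x$ventricular_osm_mosm)) {
    cat(sprintf(" (~%.0f mOsm ventricular)", x$ventricular_osm_mosm))
  }
  cat(sprintf(" to drive %.1f ul/min\n", x$vp_ul_min))
  invisible(x)
}

#' Isotonic solute transfer rate sustaining a secretion rate
#'
#' The solute flux that must cross the luminal membrane for the secreted
#' fluid to emerge isotonic: `rate = Vp * osmolality`, with the osmolality
#' (per kg) converted to per-volume via the fluid density.
#'
#' @param vp_ul_min secretion rate (ul min^-1).
#' @param osmolality_mosm fluid osmolality (mOsm, i.e. mmol kg^-1).
#' @param density_g_ml fluid density (g ml^-1), default 1.00.
#' @return Solute transfer rate in mmol s^-1.
#' @examples
#' ion_transfer_rate(6.8, 307) # 3.48e-5 mmol/s
#' @export
ion_transfer_rate <- function(vp_ul_min, osmolality_mosm, density_g_ml = 1.0) {
  stopifnot_positive(osmolality_mosm = osmolality_mosm,
                     density_g_ml = density_g_ml)
  if (vp_ul_min < 0) stop("vp_ul_min must be non-negative", call. = FALSE)
  mass_kg_s <- ul_min_to_cm3_s(vp_ul_min) * density_g_ml * 1e-3
  mass_kg_s * osmolality_mosm
}

#' Van't Hoff osmotic pressure of a concentration difference
#'
#' `pi = dC * R * T` with `dC` in mol m^-3 (1 mOsm = 1 mol m^-3),
#' R = 8.314 J mol^-1 K^-1, reported in mmHg (1 mmHg = 133.322 Pa).
#'
#' @param delta_osm_mosm osmotic concentration difference (mOsm).
#' @param temperature_k absolute temperature (K), default body
#'   temperature 310 K.
#' @return Osmotic pressure in mmHg.
#' @examples
#' osmotic_pressure(50) # about 967 mmHg
#' @export
osmotic_pressure <- function(delta_osm_mosm, temperature_k = 310) {
  stopifnot_positive(temperature_k = temperature_k)
  if (delta_osm_mosm < 0) stop("delta_osm_mosm must be non-negative",
                               call. = FALSE)
  pa <- delta_osm_mosm * 8.314 * temperature_k
  pa / 133.322
}

#' The full permeability derivation chain
#'
#' Runs slope -> Lp,trans -> per-membrane Lp -> per-true-area luminal Lp ->
#' required gradient in one call, returning every intermediate.
#'
#' @param slope_ul_min_mosm osmotic-challenge slope (ul min^-1 mOsm^-1).
#' @param area_apparent_cm2 apparent area (cm^2).
#' @param amplification fold surface amplification.
#' @param vp_ul_min observed secretion rate (ul min^-1).
#' @param plasma_osm_mosm plasma osmolality (mOsm) or NULL.
#' @param lp_trans_override optional trans-epithelial Lp (cm s^-1 Osm^-1)
#'   to use in place of `slope/area` (e.g. a published value retaining
#'   unrounded inputs).
#' @return An object of class `permeability_chain` with all links.
#' @examples
#' permeability_chain(0.023, 4.6, 12.4, 6.8, plasma_osm_mosm = 307)
#' @export
permeability_chain <- function(slope_ul_min_mosm, area_apparent_cm2,
                               amplification, vp_ul_min,
                               plasma_osm_mosm = NULL,
                               lp_trans_override = NULL) {
  lp_trans <- if (is.null(lp_trans_override)) {
    lp_from_slope(slope_ul_min_mosm, area_apparent_cm2)
  } else lp_trans_override
  lp_mem <- split_series_membranes(lp_trans)
  lp_lum <- lp_per_true_area(lp_mem, amplification)
  req <- required_gradient(vp_ul_min, area_apparent_cm2, lp_trans,
                           plasma_osm_mosm)
  structure(list(slope_ul_min_mosm = slope_ul_min_mosm,
                 area_apparent_cm2 = area_apparent_cm2,
                 amplification = amplification,
                 lp_trans_cm_s_osm = lp_trans,
                 lp_membrane_cm_s_osm = lp_mem,
                 lp_luminal_true_cm_s_osm = lp_lum,
                 requirement = req),
            class = "permeability_chain")
}

#' @export
print.permeability_chain <- function(x, ...) {
  cat("Osmotic water permeability chain\n")
  cat(sprintf("  slope                 : %.3g ul/min/mOsm over %.2g cm^2\n",
              x$slope_ul_min_mosm, x$area_apparent_cm2))
  cat(sprintf("  Lp trans-epithelial   : %.3g cm/s/Osm\n", x$lp_trans_cm_s_osm))
  cat(sprintf("  Lp per membrane       : %.3g cm/s/Osm\n",
              x$lp_membrane_cm_s_osm))
  cat(sprintf("  Lp luminal, true area : %.3g cm/s/Osm (amplification %.3g)\n",
              x$lp_luminal_true_cm_s_osm, x$amplification))
  print(x$requirement)
  invisible(x)
}
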