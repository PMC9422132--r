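# Unit conversions between the reported units (ul/min, mOsm, cm s-1 Osm-1)
# and the internal CGS system (cm3/s, osmol cm-3). All model arithmetic is
# done in CGS; the public API reports the field's conventional units.

#' Unit conversion helpers
#'
#' Small conversion utilities between the units used in reports
#' (microlitres per minute, milliosmolar) and the internal CGS system
#' (cm^3 s^-1, osmol cm^-3) used by the standing-gradient model.
#'
#' Conventions: 1 Osm = 1 osmol L^-1 = 1e-3 osmol cm^-3, so a water
#' permeability given in cm s^-1 Osm^-1 is multiplied by 1000 to act on
#' concentrations in osmol cm^-3.
#'
#' @param x numeric vector to convert.
#' @return Converted numeric vector.
#' @name units
#' @keywords internal
NULL

#' @rdname units
#' @export
ul_min_to_cm3_s <- function(x) x * 1e-3 / 60

#' @rdname units
#' @export
cm3_s_to_ul_min <- function(x) x * 60 * 1e3

#' @rdname units
#' @export
mosm_to_osmol_cm3 <- function(x) x * 1e-6

#' @rdname units
#' @export
osmol_cm3_to_mosm <- function(x) x * 1e6

#' @rdname units
#' @export
um_to_cm <- function(x) x * 1e-4

#' @rdname units
#' @export
cm_to_um <- function(x) x * 1e4

#' @rdname units
#' @export
um2_to_cm2 <- function(x) x * 1e-8

#' @rdname units
#' @export
cm2_to_um2 <- function(x) x * 1e8

# Lp in cm s-1 Osm-1 -> cm s-1 per (osmol cm-3)
lp_reported_to_cgs <- function(lp) lp * 1e3

stopifnot_positive <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
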