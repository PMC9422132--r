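# Morphometry of the choroid plexus luminal membrane: microvillar surface
# amplification, apparent and true membrane areas, and the hydraulically
# equivalent cylindrical channel used by the standing-gradient model.

#' Microvillus morphometry
#'
#' Container for electron-microscopy-derived microvillar dimensions and
#' areal density on the choroid plexus luminal membrane.
#'
#' @param length_um microvillus length (um).
#' @param base_radius_um cylindrical base radius (um).
#' @param tip_radius_um bulbous tip radius (um); must be at least the base
#'   radius.
#' @param density_per_um2 microvilli per um^2 of bulk (apparent) membrane.
#' @param brush_border_extent_um effective brush-border depth (um); the
#'   interdigitated brush border is shallower than the individual microvillus
#'   length, and serves as the default channel length of the functional unit.
#' @return An object of class `microvillus_morphometry`.
#' @examples
#' m <- microvillus_morphometry()
#' surface_amplification(m)
#' @export
microvillus_morphometry <- function(length_um = 1.71,
                                    base_radius_um = 0.06,
                                    tip_radius_um = 0.12,
                                    density_per_um2 = 18,
                                    brush_border_extent_um = 1.5) {
  stopifnot_positive(length_um = length_um, base_radius_um = base_radius_um,
                     tip_radius_um = tip_radius_um,
                     density_per_um2 = density_per_um2,
                     brush_border_extent_um = brush_border_extent_um)
  if (tip_radius_um < base_radius_um) {
    stop("tip_radius_um must be >= base_radius_um", call. = FALSE)
  }
  if (brush_border_extent_um > length_um) {
    stop("brush_border_extent_um must be <= length_um", call. = FALSE)
  }
  structure(list(length_um = length_um,
                 base_radius_um = base_radius_um,
                 tip_radius_um = tip_radius_um,
                 density_per_um2 = density_per_um2,
                 brush_border_extent_um = brush_border_extent_um),
            class = "microvillus_morphometry")
}

#' Gross tissue properties of the choroidal epithelium
#'
#' @param epithelium_mass_mg wet mass of choroid plexus epithelium (mg).
#' @param cell_density_g_per_cm3 tissue mass density (g cm^-3).
#' @param cell_height_um epithelial cell height (um).
#' @return An object of class `tissue_gross`.
#' @export
tissue_gross <- function(epithelium_mass_mg = 4.6,
                         cell_density_g_per_cm3 = 1.0,
                         cell_height_um = 10) {
  stopifnot_positive(epithelium_mass_mg = epithelium_mass_mg,
                     cell_density_g_per_cm3 = cell_density_g_per_cm3,
                     cell_height_um = cell_height_um)
  structure(list(epithelium_mass_mg = epithelium_mass_mg,
                 cell_density_g_per_cm3 = cell_density_g_per_cm3,
                 cell_height_um = cell_height_um),
            class = "tissue_gross")
}

#' Surface-area amplification by microvilli
#'
#' Fold-increase of luminal membrane area contributed by a lattice of
#' cylindrical microvilli: `1 - rho*pi*r^2 + rho*2*pi*r*l`, i.e. the flat
#' membrane minus the occluded microvillar footprints plus the microvillar
#' lateral walls. A hemispherical bulb cap of the tip radius can optionally
#' be added; the default is the plain cylinder approximation.
#'
#' @param m a [microvillus_morphometry()] object.
#' @param tip_cap logical; add a hemispherical cap term
#'   `rho * 2*pi*tip_radius^2` for the bulbous tip.
#' @return Dimensionless amplification factor (>= 1 for any realistic
#'   morphometry).
#' @examples
#' surface_amplification(microvillus_morphometry()) # about 12.4
#' @export
surface_amplification <- function(m, tip_cap = FALSE) {
  stopifnot(inherits(m, "microvillus_morphometry"))
  rho <- m$density_per_um2
  r <- m$base_radius_um
  l <- m$length_um
  amp <- 1 - rho * pi * r^2 + rho * 2 * pi * r * l
  if (tip_cap) {
    amp <- amp + rho * 2 * pi * m$tip_radius_um^2
  }
  amp
}

#' Apparent (cross-sectional) membrane area from tissue wet weight
#'
#' The apparent luminal surface area of the epithelial sheet is its volume
#' (mass / density) divided by the cell height.
#'
#' @param t a [tissue_gross()] object.
#' @return Area in cm^2.
#' @examples
#' apparent_area_from_mass(tissue_gross()) # 4.6 cm^2
#' @export
apparent_area_from_mass <- function(t) {
  stopifnot(inherits(t, "tissue_gross"))
  volume_cm3 <- t$epithelium_mass_mg * 1e-3 / t$cell_density_g_per_cm3
  volume_cm3 / um_to_cm(t$cell_height_um)
}

#' True membrane area from apparent area and amplification
#'
#' @param apparent_cm2 apparent area (cm^2).
#' @param amplification fold amplification from [surface_amplification()].
#' @return True membrane area in cm^2.
#' @export
true_area <- function(apparent_cm2, amplification) {
  stopifnot_positive(apparent_cm2 = apparent_cm2,
                     amplification = amplification)
  apparent_cm2 * amplification
}

#' Hydraulically equivalent channel geometry of the inter-microvillar space
#'
#' The functional unit is the void between four microvilli on a square
#' lattice with spacing `p = 1/sqrt(rho)`. Its cross-section
#' `a_v = p^2 - pi*r^2` is mapped to a circular cylinder: by default one of
#' equal cross-sectional area (diameter `d = 2*sqrt(a_v/pi)`); alternatively
#' one of equal hydraulic radius (`d = 2*a_v/(pi*r)`, the void's wetted
#' perimeter being the four quarter-cylinder walls `2*pi*r`).
#'
#' The per-unit wall area is the unit's share of the microvillar (true minus
#' apparent) membrane plus the void base; summed over all units it recovers
#' the true membrane area up to the microvillar tip faces.
#'
#' @param m a [microvillus_morphometry()] object.
#' @param apparent_cm2 apparent luminal area of the whole tissue (cm^2).
#' @param channel_length_um axial channel length (um); defaults to the
#'   brush-border extent, the microvillus length being the obvious
#'   alternative.
#' @param hydraulic equivalence rule, `"equal-area"` (default) or
#'   `"equal-radius"`.
#' @return An object of class `functional_unit_geometry` with fields
#'   `spacing_um`, `channel_diameter_um`, `channel_length_um`,
#'   `unit_cell_area_um2`, `void_area_um2`, `wall_area_um2`, `n_units`.
#' @examples
#' derive_unit_geometry(microvillus_morphometry(), apparent_cm2 = 4.6)
#' @export
derive_unit_geometry <- function(m, apparent_cm2,
                                 channel_length_um = m$brush_border_extent_um,
                                 hydraulic = c("equal-area", "equal-radius")) {
  stopifnot(inherits(m, "microvillus_morphometry"))
  stopifnot_positive(apparent_cm2 = apparent_cm2,
                     channel_length_um = channel_length_um)
  hydraulic <- match.arg(hydraulic)
  rho <- m$density_per_um2
  r <- m$base_radius_um
  p <- 1 / sqrt(rho)
  a_v <- p^2 - pi * r^2
  if (a_v <= 0) {
    stop("microvilli overlap: pi*r^2 >= lattice cell p^2", call. = FALSE)
  }
  d <- switch(hydraulic,
              "equal-area" = 2 * sqrt(a_v / pi),
              "equal-radius" = 2 * a_v / (pi * r))
  n_units <- apparent_cm2 / um2_to_cm2(p^2)
  amp <- surface_amplification(m)
  microvillar_um2 <- cm2_to_um2(apparent_cm2 * (amp - 1)) / n_units
  wall_area_um2 <- microvillar_um2 + a_v
  structure(list(spacing_um = p,
                 channel_diameter_um = d,
                 channel_length_um = channel_length_um,
                 unit_cell_area_um2 = p^2,
                 void_area_um2 = a_v,
                 wall_area_um2 = wall_area_um2,
                 n_units = n_units,
                 hydraulic = hydraulic),
            class = "functional_unit_geometry")
}

#' @export
print.functional_unit_geometry <- function(x, ...) {
  cat("Functional-unit geometry (", x$hydraulic, " equivalence)\n", sep = "")
  cat(sprintf("  lattice spacing p        : %.4f um\n", x$spacing_um))
  cat(sprintf("  channel diameter d       : %.4f um\n", x$channel_diameter_um))
  cat(sprintf("  channel length           : %.3f um\n", x$channel_length_um))
  cat(sprintf("  void cross-section       : %.5f um^2\n", x$void_area_um2))
  cat(sprintf("  wall area per unit       : %.5f um^2\n", x$wall_area_um2))
  cat(sprintf("  number of units          : %.3e\n", x$n_units))
  invisible(x)
}
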