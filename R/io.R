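# CSV readers/writers for the analysis inputs, YAML configuration with the
# packaged default constants, and the end-to-end headline reproduction that
# chains morphometry -> permeability -> standing gradient.

read_metadata_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    parts <- strsplit(kv, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      key <- trimws(parts[1])
      val <- trimws(paste(parts[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a perfusion CSV
#'
#' Expects columns `time_min`, `inflow_fluor`, `outflow_fluor`, with
#' metadata in leading `# key: value` comment lines
#' (`infusion_rate_ul_min`, `animal_id`, `condition`).
#'
#' @param path CSV file path.
#' @return A [perfusion_series()].
#' @export
read_perfusion_csv <- function(path) {
  meta <- read_metadata_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("time_min", "inflow_fluor", "outflow_fluor"), path)
  perfusion_series(df$time_min, df$inflow_fluor, df$outflow_fluor,
                   infusion_rate_ul_min = meta$infusion_rate_ul_min %||% 9,
                   animal_id = meta$animal_id %||% "unknown",
                   condition = meta$condition %||% "vehicle")
}

#' Write a perfusion CSV
#'
#' @param series a [perfusion_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perfusion_csv <- function(series, path) {
  stopifnot(inherits(series, "perfusion_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# infusion_rate_ul_min: %g",
                       series$infusion_rate_ul_min),
               sprintf("# animal_id: %s", series$animal_id),
               sprintf("# condition: %s", series$condition)), con)
  utils::write.csv(data.frame(time_min = series$time_min,
                              inflow_fluor = series$inflow_fluor,
                              outflow_fluor = series$outflow_fluor),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an efflux CSV
#'
#' Expects columns `time_s`, `rb_counts`, `mannitol_counts` (the latter
#' optional), with an optional `# label:` metadata line.
#'
#' @param path CSV file path.
#' @return An [efflux_series()].
#' @export
read_efflux_csv <- function(path) {
  meta <- read_metadata_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("time_s", "rb_counts"), path)
  efflux_series(df$time_s, df$rb_counts,
                if ("mannitol_counts" %in% names(df)) df$mannitol_counts,
                label = meta$label %||% "unknown")
}

#' Read a dose-response CSV
#'
#' Expects columns `dose_um` and `response`.
#'
#' @param path CSV file path.
#' @return Data frame with the two columns.
#' @export
read_dose_response_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("dose_um", "response"), path)
  df[c("dose_um", "response")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default analysis configuration
#'
#' The packaged physiological and morphometric constants used for the
#' headline reproduction, as shipped in
#' `system.file("extdata", "default_config.yaml", package = "csfosmosis")`.
#' Units are encoded in key names.
#'
#' @param path optional YAML file overriding the packaged defaults.
#' @return Nested named list of constants.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "csfosmosis")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("configuration file not found", call. = FALSE)
  }
  yaml::read_yaml(path)
}

#' End-to-end headline reproduction
#'
#' Chains the morphometry, permeability and standing-gradient stages with
#' the configured constants and returns every headline number: the surface
#' amplification, apparent and true areas, the Lp chain, the required
#' osmotic gradient, the isotonic ion-transfer rate, and the
#' standing-gradient prediction with its fraction of the observed secretion
#' rate. Deterministic for a fixed configuration.
#'
#' @param config list from [load_config()]; NULL loads the packaged
#'   defaults.
#' @param n_cells standing-gradient mesh size.
#' @return An object of class `headline_report` (nested list of results).
#' @examples
#' rep <- reproduce_headline()
#' rep$standing_gradient$fraction_percent
#' @export
reproduce_headline <- function(config = NULL, n_cells = 1000) {
  cfg <- config %||% load_config()
  m <- microvillus_morphometry(
    length_um = cfg$morphometry$length_um,
    base_radius_um = cfg$morphometry$base_radius_um,
    tip_radius_um = cfg$morphometry$tip_radius_um,
    density_per_um2 = cfg$morphometry$density_per_um2,
    brush_border_extent_um = cfg$morphometry$brush_border_extent_um)
  tg <- tissue_gross(
    epithelium_mass_mg = cfg$tissue$epithelium_mass_mg,
    cell_density_g_per_cm3 = cfg$tissue$cell_density_g_per_cm3,
    cell_height_um = cfg$tissue$cell_height_um)
  apparent <- apparent_area_from_mass(tg)
  amp <- surface_amplification(m)
  true_cm2 <- true_area(apparent, amp)
  geom <- derive_unit_geometry(m, apparent)
  chain <- permeability_chain(cfg$physiology$slope_ul_min_mosm, apparent,
                              amp, cfg$physiology$vp_ul_min,
                              plasma_osm_mosm = cfg$physiology$plasma_osm_mosm,
                              lp_trans_override =
                                cfg$physiology$lp_trans_published)
  rate <- ion_transfer_rate(cfg$physiology$vp_ul_min,
                            cfg$physiology$csf_osm_mosm,
                            cfg$physiology$csf_density_g_ml)
  problem <- standing_gradient_problem(
    geom,
    lp_wall_cm_s_osm = chain$lp_luminal_true_cm_s_osm,
    total_solute_rate_mmol_s = rate,
    bath_osm_mosm = cfg$physiology$csf_osm_mosm,
    diffusion_cm2_s = cfg$model$diffusion_cm2_s,
    reflection_coeff = cfg$model$reflection_coeff)
  sol <- solve_standing_gradient(problem, n_cells = n_cells)
  pred <- predicted_secretion(sol, geom$n_units, cfg$physiology$vp_ul_min)
  structure(list(config = cfg,
                 morphometry = m,
                 amplification = amp,
                 apparent_area_cm2 = apparent,
                 true_area_cm2 = true_cm2,
                 geometry = geom,
                 permeability = chain,
                 ion_transfer_rate_mmol_s = rate,
                 solution = sol,
                 standing_gradient = pred),
            class = "headline_report")
}

#' @export
print.headline_report <- function(x, ...) {
  cat("CSF secretion headline reproduction\n")
  cat(sprintf("  surface amplification : %.1f-fold (reported as %d-fold)\n",
              x$amplification, round(x$amplification)))
  cat(sprintf("  apparent / true area  : %.2g / %.2g cm^2\n",
              x$apparent_area_cm2, x$true_area_cm2))
  cat(sprintf("  ion transfer rate     : %.3g mmol/s\n",
              x$ion_transfer_rate_mmol_s))
  print(x$permeability)
  print(x$standing_gradient)
  invisible(x)
}

#' Write a headline report to JSON
#'
#' Full-precision flat JSON of the headline numbers; rounding is left to
#' presentation layers.
#'
#' @param report a [reproduce_headline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_headline_json <- function(report, path) {
  stopifnot(inherits(report, "headline_report"))
  out <- list(
    amplification_fold = report$amplification,
    apparent_area_cm2 = report$apparent_area_cm2,
    true_area_cm2 = report$true_area_cm2,
    lp_trans_cm_s_osm = report$permeability$lp_trans_cm_s_osm,
    lp_membrane_cm_s_osm = report$permeability$lp_membrane_cm_s_osm,
    lp_luminal_true_cm_s_osm = report$permeability$lp_luminal_true_cm_s_osm,
    delta_osm_req_mosm = report$permeability$requirement$delta_osm_req_mosm,
    ventricular_osm_mosm = report$permeability$requirement$ventricular_osm_mosm,
    ion_transfer_rate_mmol_s = report$ion_transfer_rate_mmol_s,
    q_total_ul_min = report$standing_gradient$q_total_ul_min,
    fraction_percent = report$standing_gradient$fraction_percent,
    max_excess_mosm = report$solution$max_excess_mosm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
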