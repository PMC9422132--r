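# Standing-gradient (Diamond-Bossert) model of the inter-microvillar space.
#
# One functional unit is a circular cylindrical channel of diameter d and
# length L, closed at the cell-base end (x = 0) and open to the ventricular
# CSF at the microvillar-tip mouth (x = L). Solute is pumped in through the
# walls at a uniform flux density phi; the resulting concentration excess
# draws water osmotically through the same walls, and the fluid is expelled
# at the mouth. Steady state, internal CGS units (cm, s, osmol cm^-3):
#
#   d/dx [ v C - D dC/dx ] = (s_eff/A_c) * phi        (solute balance)
#   dv/dx                  = (s_eff/A_c) * Lp * sigma * (C - C0)   (water)
#
# with v(0) = 0, no diffusive flux at the closed base, C(L) = C0. The base
# membrane's solute and water influx is folded into the distributed source
# through the effective wetted perimeter s_eff = pi*d + A_c/L, so the
# walls+base totals are conserved exactly.
#
# The discretization is a conservative finite-volume scheme (N cells,
# central advection - the Peclet number is tiny here) solved by Picard
# iteration on the velocity field; each pass is one tridiagonal solve.

#' Standing-gradient problem specification
#'
#' Assembles the boundary-value problem for one inter-microvillar functional
#' unit. The solute flux density is the whole-tissue solute turnover divided
#' by the total wall (lateral + base) membrane area of all units, per the
#' steady-state assumption that bulk CSF drainage removes solute exactly as
#' fast as it is secreted.
#'
#' @param geometry a [derive_unit_geometry()] result.
#' @param lp_wall_cm_s_osm osmotic water permeability of the channel walls
#'   and base, per true membrane area (cm s^-1 Osm^-1).
#' @param total_solute_rate_mmol_s whole-tissue solute transfer rate
#'   (mmol s^-1); see [ion_transfer_rate()]. Either this or
#'   `flux_density_mmol_s_cm2` must be given.
#' @param flux_density_mmol_s_cm2 solute influx per wall area
#'   (mmol s^-1 cm^-2), overriding the total-rate division.
#' @param bath_osm_mosm bulk CSF osmolarity C0 (mOsm).
#' @param diffusion_cm2_s solute diffusion coefficient in the channel
#'   (cm^2 s^-1); default 1.5e-5, aqueous NaCl at 37 C.
#' @param reflection_coeff osmotic reflection coefficient sigma in (0, 1].
#' @param partial_molar_vol_water_cm3_mol partial molar volume of water
#'   (cm^3 mol^-1); carried for unit bookkeeping when converting mole-based
#'   permeabilities, not used by the hydraulic formulation where Lp already
#'   maps osmolarity to volume flux.
#' @return An object of class `standing_gradient_problem`.
#' @examples
#' geom <- derive_unit_geometry(microvillus_morphometry(), 4.6)
#' p <- standing_gradient_problem(geom, lp_wall_cm_s_osm = 1.4e-5,
#'                                total_solute_rate_mmol_s = 3.48e-5)
#' @export
standing_gradient_problem <- function(geometry, lp_wall_cm_s_osm,
                                      total_solute_rate_mmol_s = NULL,
                                      flux_density_mmol_s_cm2 = NULL,
                                      bath_osm_mosm = 307,
                                      diffusion_cm2_s = 1.5e-5,
                                      reflection_coeff = 1,
                                      partial_molar_vol_water_cm3_mol = 18) {
  stopifnot(inherits(geometry, "functional_unit_geometry"))
  stopifnot_positive(lp_wall_cm_s_osm = lp_wall_cm_s_osm,
                     bath_osm_mosm = bath_osm_mosm,
                     diffusion_cm2_s = diffusion_cm2_s)
  if (reflection_coeff <= 0 || reflection_coeff > 1) {
    stop("reflection_coeff must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(flux_density_mmol_s_cm2)) {
    if (is.null(total_solute_rate_mmol_s)) {
      stop("supply total_solute_rate_mmol_s or flux_density_mmol_s_cm2",
           call. = FALSE)
    }
    if (total_solute_rate_mmol_s < 0) {
      stop("total_solute_rate_mmol_s must be non-negative", call. = FALSE)
    }
    total_wall_cm2 <- geometry$n_units * um2_to_cm2(geometry$wall_area_um2)
    flux_density_mmol_s_cm2 <- total_solute_rate_mmol_s / total_wall_cm2
  } else if (flux_density_mmol_s_cm2 < 0) {
    stop("flux_density_mmol_s_cm2 must be non-negative", call. = FALSE)
  }
  structure(list(geometry = geometry,
                 lp_wall_cm_s_osm = lp_wall_cm_s_osm,
                 flux_density_mmol_s_cm2 = flux_density_mmol_s_cm2,
                 bath_osm_mosm = bath_osm_mosm,
                 diffusion_cm2_s = diffusion_cm2_s,
                 reflection_coeff = reflection_coeff,
                 partial_molar_vol_water_cm3_mol =
                   partial_molar_vol_water_cm3_mol),
            class = "standing_gradient_problem")
}

# Internal CGS coefficients shared by the solver and the linearized oracle.
sg_coefficients <- function(p) {
  g <- p$geometry
  L <- um_to_cm(g$channel_length_um)
  d <- um_to_cm(g$channel_diameter_um)
  A_c <- pi * d^2 / 4
  s_eff <- pi * d + A_c / L
  phi_osmol <- p$flux_density_mmol_s_cm2 * 1e-3    # mmol -> osmol (1:1)
  list(L = L, A_c = A_c, s_eff = s_eff,
       C0 = mosm_to_osmol_cm3(p$bath_osm_mosm),
       D = p$diffusion_cm2_s,
       S_phi = s_eff / A_c * phi_osmol,
       S_lp = s_eff / A_c * lp_reported_to_cgs(p$lp_wall_cm_s_osm) *
         p$reflection_coeff)
}

# Tridiagonal solve (Thomas algorithm): a sub-, b main, c super-diagonal.
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- b[i] - a[i] * cp[i - 1]
      cp[i] <- c[i] / m
      dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Solve the standing-gradient boundary-value problem
#'
#' Solves the coupled advection-diffusion / osmotic-water system for one
#' functional unit on a uniform mesh with a conservative finite-volume
#' discretization and Picard iteration on the velocity field. The discrete
#' face fluxes telescope, so solute is conserved to the Picard tolerance.
#'
#' @param problem a [standing_gradient_problem()].
#' @param n_cells number of finite-volume cells.
#' @param tol Picard convergence tolerance on the relative concentration
#'   update.
#' @param max_iter maximum Picard iterations.
#' @return An object of class `standing_gradient_solution`: `x_um` (cell
#'   centers), `concentration_mosm`, `x_face_um`, `velocity_cm_s` (faces),
#'   `q_unit_cm3_s`, `max_excess_mosm`, `emergent_osm_mosm` (solute flux /
#'   water flux at the mouth), and `solver_report` (iterations, residuals,
#'   conservation checks).
#' @examples
#' geom <- derive_unit_geometry(microvillus_morphometry(), 4.6)
#' p <- standing_gradient_problem(geom, 1.4e-5, 3.48e-5)
#' s <- solve_standing_gradient(p)
#' s$q_unit_cm3_s
#' @export
solve_standing_gradient <- function(problem, n_cells = 1000, tol = 1e-12,
                                    max_iter = 500) {
  stopifnot(inherits(problem, "standing_gradient_problem"))
  co <- sg_coefficients(problem)
  N <- as.integer(n_cells)
  if (N < 4) stop("n_cells must be at least 4", call. = FALSE)
  h <- co$L / N
  C0 <- co$C0; D <- co$D
  Cc <- rep(C0, N)               # cell-center concentrations
  v_face <- numeric(N + 1)       # velocities at faces 0..N
  rhs_base <- rep(co$S_phi * h, N)
  S_lph <- co$S_lp * h
  # discrete face fluxes for a concentration iterate (faces 0..N)
  face_flux <- function(C, v) {
    Fj <- numeric(N + 1)
    j <- seq_len(N - 1)
    Fj[j + 1] <- v[j + 1] * (C[j] + C[j + 1]) / 2 - D * (C[j + 1] - C[j]) / h
    Fj[N + 1] <- v[N + 1] * C0 - 2 * D * (C0 - C[N]) / h
    Fj
  }
  # dimensionless water-solute feedback strength: the plain fixed-point
  # iteration on the velocity field converges fast when this is small
  # (the physiological regime); beyond O(1) coupling we switch to Newton
  # on the full discrete system
  kappa <- co$S_lp * co$L^2 * C0 / D
  iter <- 0L; delta <- Inf
  if (kappa <= 0.5) {
    while (iter < max_iter && delta > tol) {
      iter <- iter + 1L
      # velocity from current concentration (midpoint quadrature, v(0) = 0)
      v_face <- c(0, cumsum(S_lph * (Cc - C0)))
      vi <- v_face[2:N]            # interior faces 1..N-1
      vN <- v_face[N + 1]
      a <- c(0, -vi / 2 - D / h)                       # subdiagonal
      b <- c(vi, 0) / 2 - c(0, vi) / 2 + 2 * D / h     # main diagonal
      b[1] <- vi[1] / 2 + D / h                        # closed base, F_0 = 0
      b[N] <- 3 * D / h - vi[N - 1] / 2                # Dirichlet mouth
      cc <- c(vi / 2 - D / h, 0)                       # superdiagonal
      rhs <- rhs_base
      rhs[N] <- rhs[N] - vN * C0 + 2 * D * C0 / h
      C_new <- thomas_solve(a, b, cc, rhs)
      delta <- max(abs(C_new - Cc)) / C0
      Cc <- C_new
    }
  } else {
    while (iter < max_iter && delta > tol) {
      iter <- iter + 1L
      v <- c(0, cumsum(S_lph * (Cc - C0)))
      resid <- diff(face_flux(Cc, v)) - rhs_base
      # tridiagonal advection-diffusion part of the Jacobian
      J <- matrix(0, N, N)
      J[1, 1] <- v[2] / 2 + D / h
      J[1, 2] <- v[2] / 2 - D / h
      if (N > 2) {
        for (i in 2:(N - 1)) {
          J[i, i - 1] <- -(v[i] / 2 + D / h)
          J[i, i] <- v[i + 1] / 2 - v[i] / 2 + 2 * D / h
          J[i, i + 1] <- v[i + 1] / 2 - D / h
        }
      }
      J[N, N - 1] <- -(v[N] / 2 + D / h)
      J[N, N] <- 3 * D / h - v[N] / 2
      # velocity-coupling part: dv_j/dC_k = S_lp*h for k <= j
      w <- c((Cc[seq_len(N - 1)] + Cc[-1]) / 2, C0)    # dF_j/dv_j, faces 1..N
      for (i in seq_len(N)) {
        J[i, seq_len(i)] <- J[i, seq_len(i)] + S_lph * w[i]
        if (i > 1) {
          J[i, seq_len(i - 1)] <- J[i, seq_len(i - 1)] - S_lph * w[i - 1]
        }
      }
      dC <- solve(J, -resid)
      delta <- max(abs(dC)) / C0
      Cc <- Cc + dC
    }
  }
  if (delta > tol) {
    stop(sprintf(paste0("standing-gradient solver did not converge: ",
                        "relative update %.2e after %d iterations"),
                 delta, iter), call. = FALSE)
  }
  if (any(Cc < C0 * (1 - 1e-9))) {
    stop("model violation: concentration fell below the bath osmolarity",
         call. = FALSE)
  }
  v_face <- c(0, cumsum(co$S_lp * h * (Cc - C0)))
  vN <- v_face[N + 1]
  q_unit <- vN * co$A_c
  # conservation diagnostics
  input_per_channel <- co$S_phi * co$L * co$A_c
  mouth_flux <- (vN * C0 - D * (C0 - Cc[N]) / (h / 2)) * co$A_c
  solute_resid <- if (input_per_channel > 0) {
    abs(mouth_flux - input_per_channel) / input_per_channel
  } else abs(mouth_flux)
  # independent trapezoid quadrature of the osmotic influx for the water check
  C_face <- c(Cc[1], (Cc[-N] + Cc[-1]) / 2, C0)
  x_face <- seq(0, co$L, length.out = N + 1)
  influx <- co$S_lp * (C_face - C0)
  v_trap <- sum((influx[-1] + influx[-(N + 1)]) / 2) * h
  water_resid <- if (vN > 0) abs(v_trap - vN) / vN else 0
  emergent <- if (vN > 0) mouth_flux / (vN * co$A_c) else NA_real_
  structure(list(x_um = cm_to_um(seq(h / 2, co$L - h / 2, length.out = N)),
                 concentration_mosm = osmol_cm3_to_mosm(Cc),
                 x_face_um = cm_to_um(x_face),
                 velocity_cm_s = v_face,
                 q_unit_cm3_s = q_unit,
                 max_excess_mosm = osmol_cm3_to_mosm(max(Cc - C0)),
                 emergent_osm_mosm = if (is.na(emergent)) NA_real_ else
                   osmol_cm3_to_mosm(emergent),
                 solver_report = list(n_cells = N, iterations = iter,
                                      picard_residual = delta,
                                      solute_conservation = solute_resid,
                                      water_conservation = water_resid),
                 problem = problem),
            class = "standing_gradient_solution")
}

#' @export
print.standing_gradient_solution <- function(x, ...) {
  cat("Standing-gradient solution\n")
  cat(sprintf("  q per unit        : %.3e cm^3/s\n", x$q_unit_cm3_s))
  cat(sprintf("  max excess        : %.3g mOsm above bath\n",
              x$max_excess_mosm))
  cat(sprintf("  emergent osmolarity: %.3g mOsm\n", x$emergent_osm_mosm))
  r <- x$solver_report
  cat(sprintf("  mesh %d cells, %d Picard iterations, conservation %.1e (solute) %.1e (water)\n",
              r$n_cells, r$iterations, r$solute_conservation,
              r$water_conservation))
  invisible(x)
}

#' Closed-form linearized standing-gradient solution
#'
#' Independent oracle for the small-perturbation regime: dropping the
#' advective term from the solute balance gives `D c'' = -S_phi` with
#' `c'(0) = 0`, `c(L) = 0`, hence `c(x) = S_phi (L^2 - x^2) / (2D)` and
#' `v(L) = S_lp * S_phi * L^3 / (3D)`. Valid when the maximum excess is
#' much smaller than the bath osmolarity, which holds by a wide margin for
#' the choroid plexus parameterization.
#'
#' @param problem a [standing_gradient_problem()].
#' @param n_grid points for the returned profiles.
#' @return List with `x_um`, `concentration_mosm`, `velocity_cm_s`,
#'   `q_unit_cm3_s`, `max_excess_mosm`.
#' @export
standing_gradient_linearized <- function(problem, n_grid = 101) {
  stopifnot(inherits(problem, "standing_gradient_problem"))
  co <- sg_coefficients(problem)
  x <- seq(0, co$L, length.out = n_grid)
  c_ex <- co$S_phi * (co$L^2 - x^2) / (2 * co$D)
  v <- co$S_lp * co$S_phi * (co$L^2 * x - x^3 / 3) / (2 * co$D)
  vL <- co$S_lp * co$S_phi * co$L^3 / (3 * co$D)
  list(x_um = cm_to_um(x),
       concentration_mosm = osmol_cm3_to_mosm(co$C0 + c_ex),
       velocity_cm_s = v,
       q_unit_cm3_s = vL * co$A_c,
       max_excess_mosm = osmol_cm3_to_mosm(c_ex[1]))
}

#' Scale a per-unit flow to whole-tissue predicted secretion
#'
#' @param solution a [solve_standing_gradient()] result (or any list with
#'   `q_unit_cm3_s`).
#' @param n_units number of functional units over the tissue.
#' @param observed_vp_ul_min observed CSF secretion rate (ul min^-1).
#' @return An object of class `tissue_prediction`: `q_total_ul_min` and
#'   `fraction_percent` of the observed rate.
#' @export
predicted_secretion <- function(solution, n_units, observed_vp_ul_min) {
  stopifnot_positive(n_units = n_units,
                     observed_vp_ul_min = observed_vp_ul_min)
  q_total <- cm3_s_to_ul_min(solution$q_unit_cm3_s * n_units)
  structure(list(q_total_ul_min = q_total,
                 fraction_percent = 100 * q_total / observed_vp_ul_min,
                 observed_vp_ul_min = observed_vp_ul_min),
            class = "tissue_prediction")
}

#' @export
print.tissue_prediction <- function(x, ...) {
  cat(sprintf("Predicted local-osmosis flow %.4f ul/min = %.3g%% of the observed %.1f ul/min\n",
              x$q_total_ul_min, x$fraction_percent, x$observed_vp_ul_min))
  invisible(x)
}
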