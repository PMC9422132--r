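# Independent brute-force oracles kept deliberately separate from the
# implementation paths they check.

# OLS via explicit normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - ss_res / ss_tot)
}

# coarse grid search refinement for the Hill model on small instances
hill_oracle <- function(dose, response, ic50_grid, hill_grid) {
  best <- list(sse = Inf)
  for (ic in ic50_grid) for (hl in hill_grid) {
    f <- 1 / (1 + (ic / dose)^hl)
    # conditional linear least squares for the plateaus
    fit <- stats::lm(response ~ f)
    sse <- sum(stats::resid(fit)^2)
    if (sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(sse = sse, ic50 = ic, hill = hl,
                   y_min = unname(cf[1]), y_max = unname(cf[1] + cf[2]))
    }
  }
  best
}

study_geometry <- function() {
  derive_unit_geometry(microvillus_morphometry(), apparent_cm2 = 4.6)
}

study_problem <- function(geom = study_geometry()) {
  standing_gradient_problem(
    geom, lp_wall_cm_s_osm = 1.4e-5,
    total_solute_rate_mmol_s = ion_transfer_rate(6.8, 307, 1))
}
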