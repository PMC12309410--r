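#' Steady-state advective-conductive temperature profile
#'
#' One-dimensional steady heat transport through sediment with vertical
#' Darcy flow (Bredehoeft-Papadopulos solution):
#' \deqn{T(z) = T_{top} + (T_{bot} - T_{top}) \frac{e^{\beta z/L} - 1}
#'   {e^{\beta} - 1}}
#' where beta is the thermal Peclet number over the depth span L. beta > 0
#' curves the profile as for downward flow (recharge); beta < 0 as for
#' upward discharge; beta -> 0 recovers the linear conductive profile
#' (evaluated by series expansion below |beta| = 1e-6 to avoid 0/0).
#'
#' @param z Depth(s) below the top boundary, m, in `[0, L]`.
#' @param beta Peclet number (signed, dimensionless).
#' @param L Depth span between the boundary temperatures, m (> 0).
#' @param T_top,T_bottom Boundary temperatures, degrees C.
#' @return Temperature(s) in degrees C.
#' @export
forward_temperature <- function(z, beta, L, T_top, T_bottom) {
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  if (any(z < -1e-12) || any(z > L + 1e-12)) {
    stop("z must lie within [0, L]", call. = FALSE)
  }
  u <- pmin(pmax(z / L, 0), 1)
  if (abs(beta) < 1e-6) {
    frac <- u + beta * u * (u - 1) / 2  # first-order expansion about beta=0
  } else {
    frac <- expm1(beta * u) / expm1(beta)
  }
  T_top + (T_bottom - T_top) * frac
}

#' Invert a thermal profile for the Peclet number and seepage velocity
#'
#' Fits the steady advection-diffusion solution of [forward_temperature()]
#' to probe temperatures by least squares over beta. Boundary temperatures
#' are taken from the shallowest and deepest readings and L is their
#' separation; interior readings constrain the curvature. The Darcy
#' velocity follows as q = beta * lambda_s / (rho_cf * L), with the sign
#' convention that negative q means upward flow (discharge).
#'
#' @param profile A `thermal_profile` with >= 3 readings.
#' @param const [seep_constants()] supplying `lambda_s` (sediment thermal
#'   conductivity, W m-1 K-1) and `rho_cf` (pore-fluid volumetric heat
#'   capacity, J m-3 K-1).
#' @param beta_range Search interval for beta (default `c(-50, 50)`).
#' @return A `flow_solution`: list with `core_id`, `beta`, `q` (m/s), `L`,
#'   `T_top`, `T_bottom`, `lambda_s`, `rho_cf`, `rmse` (deg C), `n`,
#'   `converged`.
#' @export
invert_peclet <- function(profile, const = seep_constants(),
                          beta_range = c(-50, 50)) {
  d <- profile$data
  if (nrow(d) < 3) {
    stop("need >= 3 temperature readings to invert for beta", call. = FALSE)
  }
  z <- d$depth_m - d$depth_m[1]
  L <- z[length(z)]
  T_top <- d$temp_c[1]
  T_bottom <- d$temp_c[nrow(d)]
  sse <- function(beta) {
    sum((forward_temperature(z, beta, L, T_top, T_bottom) - d$temp_c)^2)
  }
  opt <- stats::optimize(sse, interval = beta_range, tol = 1e-12)
  beta <- opt$minimum
  # A linear profile should report exactly zero flow, not optimizer dust.
  if (sse(0) <= opt$objective + 1e-15) beta <- 0
  q <- velocity_from_peclet(beta, L, const$lambda_s, const$rho_cf)
  structure(list(
    core_id = profile$core_id, beta = beta, q = q, L = L,
    T_top = T_top, T_bottom = T_bottom,
    lambda_s = const$lambda_s, rho_cf = const$rho_cf,
    rmse = sqrt(sse(beta) / nrow(d)), n = nrow(d),
    converged = is.finite(beta) &&
      abs(beta) < max(abs(beta_range)) - 1e-6
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %s: beta = %.4g, q = %.3g m/s (%s), rmse = %.3g C\n",
    x$core_id, x$beta, x$q,
    if (x$q < 0) "upward discharge" else if (x$q > 0) "downward recharge"
    else "conductive", x$rmse))
  invisible(x)
}

#' Darcy seepage velocity from the Peclet number
#'
#' q = beta * lambda_s / (rho_cf * L). Negative values indicate upward
#' flow (discharge), matching the sign of beta. Dividing by porosity gives
#' the pore velocity instead of the Darcy flux.
#'
#' @param beta Peclet number (signed).
#' @param L Depth span, m (> 0).
#' @param lambda_s Sediment thermal conductivity, W m-1 K-1 (> 0).
#' @param rho_cf Pore-fluid volumetric heat capacity, J m-3 K-1 (> 0).
#' @param porosity Optional; when supplied, returns q / porosity (pore
#'   velocity) instead of the Darcy flux.
#' @return Velocity in m/s.
#' @export
velocity_from_peclet <- function(beta, L, lambda_s, rho_cf,
                                 porosity = NULL) {
  if (L <= 0 || lambda_s <= 0 || rho_cf <= 0) {
    stop("L, lambda_s and rho_cf must be > 0", call. = FALSE)
  }
  q <- beta * lambda_s / (rho_cf * L)
  if (!is.null(porosity)) {
    if (porosity <= 0 || porosity > 1) stop("porosity must be in (0, 1]",
                                            call. = FALSE)
    q <- q / porosity
  }
  q
}

#' Advective porewater solute flux
#'
#' Flux = q * c, with mM treated as exactly mol m-3 (dilute-solution
#' convention), reported in umol m-2 s-1. The sign follows the velocity:
#' negative = upward transport out of the sediment.
#'
#' @param q Darcy velocity, m/s (signed).
#' @param c_mM Solute concentration, mM (>= 0).
#' @return Flux in umol m-2 s-1 (bilinear in `q` and `c_mM`).
#' @export
porewater_flux <- function(q, c_mM) {
  if (any(c_mM < 0)) stop("concentration must be >= 0", call. = FALSE)
  q * c_mM * 1e6
}
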