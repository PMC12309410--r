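#' Rayleigh residual isotope composition
#'
#' Isotopic evolution of a shrinking substrate pool when the removed
#' material carries a constant offset epsilon:
#' \deqn{\delta_{res} = \delta_0 + \varepsilon \ln f}
#' Convention: epsilon = delta(removed N) - delta(bulk substrate), so a
#' negative epsilon (removal of isotopically light nitrogen, as during
#' hydrothermal ammonium loss) drives the residual heavier as f shrinks.
#'
#' @param delta0 Initial composition, permil.
#' @param epsilon Fractionation, permil (product minus substrate).
#' @param f Fraction of substrate remaining, in (0, 1]; vectorized.
#' @return Residual composition, permil.
#' @export
rayleigh_residual <- function(delta0, epsilon, f) {
  if (any(f <= 0) || any(f > 1)) stop("f must be in (0, 1]", call. = FALSE)
  if (!is.finite(epsilon)) stop("epsilon must be finite", call. = FALSE)
  delta0 + epsilon * log(f)
}

#' Mass-weighted isotope mixture
#'
#' @param mass Pool masses (>= 0, total > 0).
#' @param delta Pool compositions, permil.
#' @return Mass-weighted mean delta, permil; bounded by the input deltas
#'   and invariant under rescaling of all masses.
#' @export
mix_delta <- function(mass, delta) {
  if (length(mass) != length(delta)) {
    stop("mass and delta must have equal length", call. = FALSE)
  }
  if (any(mass < 0) || sum(mass) <= 0) {
    stop("masses must be >= 0 with positive total", call. = FALSE)
  }
  sum(mass * delta) / sum(mass)
}

#' Apparent fractionation between two phases
#'
#' @param delta_a,delta_b Compositions, permil (finite); vectorized.
#' @return delta_a - delta_b, permil.
#' @export
apparent_fractionation <- function(delta_a, delta_b) {
  if (any(!is.finite(delta_a)) || any(!is.finite(delta_b))) {
    stop("deltas must be finite", call. = FALSE)
  }
  delta_a - delta_b
}

#' Depth-paired porewater-sediment nitrogen isotope offsets
#'
#' Pairs each porewater d15N(NH4+) measurement with the nearest-depth bulk
#' sediment d15N within a tolerance and reports the apparent fractionation
#' (porewater minus sediment). Porewater samples with no sediment partner
#' within the tolerance are kept as flagged gaps (`NA` offset), never
#' silently dropped.
#'
#' @param porewater A `porewater_profile` (rows with `NA` d15n_nh4 are
#'   ignored).
#' @param sediment A `sediment_profile`.
#' @param tol_cm Maximum depth separation for a pair (default 1 cm).
#' @return Data frame with `depth_cm`, `d15n_pw`, `sed_depth_cm`,
#'   `d15n_sed`, `offset_permil`, `gap`.
#' @export
pair_fractionation <- function(porewater, sediment, tol_cm = 1) {
  pw <- porewater$data[is.finite(porewater$data$d15n_nh4), , drop = FALSE]
  sed <- sediment$data
  if (!nrow(pw)) {
    stop("no porewater d15N measurements to pair", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(pw)), function(i) {
    j <- which.min(abs(sed$depth_cm - pw$depth_cm[i]))
    gap <- abs(sed$depth_cm[j] - pw$depth_cm[i]) > tol_cm
    data.frame(
      depth_cm = pw$depth_cm[i],
      d15n_pw = pw$d15n_nh4[i],
      sed_depth_cm = if (gap) NA_real_ else sed$depth_cm[j],
      d15n_sed = if (gap) NA_real_ else sed$d15n[j],
      offset_permil = if (gap) NA_real_ else
        apparent_fractionation(pw$d15n_nh4[i], sed$d15n[j]),
      gap = gap
    )
  })
  do.call(rbind, out)
}
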