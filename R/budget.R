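#' Vent-endmember ammonium flux
#'
#' Total solute flux carried by the basin's hydrothermal fluid discharge:
#' Q (m3/s) times the endmember concentration (mM = mol m-3).
#'
#' @param Q Fluid flux, m3/s (>= 0); vectorized.
#' @param c_mM Endmember concentration, mM (>= 0).
#' @return Flux in mol/s.
#' @export
vent_flux <- function(Q, c_mM) {
  if (any(Q < 0) || any(c_mM < 0)) stop("Q and c must be >= 0",
                                        call. = FALSE)
  Q * c_mM
}

#' Basin-scale seepage flux from an areal flux
#'
#' Extrapolates an areal flux (nmol m-2 s-1) over the hydrothermally
#' active trough areas.
#'
#' @param F_areal Areal flux, nmol m-2 s-1; vectorized.
#' @param areas Areas in m2 (non-empty, all > 0).
#' @return Flux in mol/s.
#' @export
basin_seepage_flux <- function(F_areal, areas) {
  if (!length(areas)) stop("area list must be non-empty", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be > 0", call. = FALSE)
  F_areal * 1e-9 * sum(areas)
}

#' Seepage share of the total hydrothermal ammonium flux
#'
#' @param F_seep Seepage flux, mol/s (>= 0).
#' @param F_vent Vent flux, mol/s (> 0).
#' @return Percentage 100 * F_seep / F_vent.
#' @export
seepage_fraction <- function(F_seep, F_vent) {
  if (any(F_vent <= 0)) stop("vent flux must be > 0", call. = FALSE)
  100 * F_seep / F_vent
}

#' Biomass supportable by a nitrogen flux
#'
#' Converts a nitrogen flux to the dry carbon biomass it can sustain per
#' year under Redfield stoichiometry: F_N * (C:N) * M_C * sec_per_year,
#' in kg C/yr.
#'
#' @param F_N Nitrogen flux, mol N/s (>= 0); vectorized.
#' @param const [seep_constants()] supplying `redfield_C_to_N`, `M_C`,
#'   `sec_per_year`.
#' @return kg dry carbon per year.
#' @export
biomass_support <- function(F_N, const = seep_constants()) {
  if (any(F_N < 0)) stop("F_N must be >= 0", call. = FALSE)
  F_N * const$redfield_C_to_N * const$M_C * const$sec_per_year / 1000
}

#' Areal productivity supportable by a nitrogen flux
#'
#' Treats the basin as closed and fully mixed: the nitrogen flux, converted
#' to carbon by the Redfield ratio and spread over the basin area, gives
#' the additional primary productivity it could sustain.
#'
#' @param F_N Nitrogen flux, mol N/s (>= 0); vectorized.
#' @param basin_area Basin area, m2 (> 0).
#' @param const [seep_constants()].
#' @return mol C m-2 yr-1.
#' @export
productivity_support <- function(F_N, basin_area = NULL,
                                 const = seep_constants()) {
  if (is.null(basin_area)) basin_area <- const$basin_area
  if (basin_area <= 0) stop("basin_area must be > 0", call. = FALSE)
  if (any(F_N < 0)) stop("F_N must be >= 0", call. = FALSE)
  F_N * const$redfield_C_to_N * const$sec_per_year / basin_area
}

#' Productivity as a percentage of export production
#'
#' @param productivity mol C m-2 yr-1 (>= 0); vectorized.
#' @param export_prod Export production, mol C m-2 yr-1 (> 0).
#' @return Percent of export production.
#' @export
pct_export <- function(productivity, export_prod = NULL,
                       const = seep_constants()) {
  if (is.null(export_prod)) export_prod <- const$export_prod
  if (export_prod <= 0) stop("export_prod must be > 0", call. = FALSE)
  100 * productivity / export_prod
}

#' Vent-flux-supported share of export production
#'
#' Chains [productivity_support()] and [pct_export()] for the vent flux;
#' equals the seepage percentage scaled by F_vent / F_seep (degree-1
#' homogeneity).
#'
#' @param F_vent Vent flux, mol N/s (>= 0); vectorized.
#' @param basin_area Basin area, m2 (> 0).
#' @param export_prod Export production, mol C m-2 yr-1 (> 0).
#' @param const [seep_constants()].
#' @return Percent of export production.
#' @export
vent_pct_export <- function(F_vent, basin_area = NULL, export_prod = NULL,
                            const = seep_constants()) {
  pct_export(productivity_support(F_vent, basin_area, const),
             export_prod, const)
}

#' Assemble the full basin flux budget
#'
#' Runs the whole upscaling chain from a fitted nitrogen-loss model:
#' areal loss fluxes at the low/high sedimentation-rate bounds, basin
#' seepage fluxes over the trough areas, the vent-endmember flux at the
#' low/high fluid-flux bounds, seepage fractions, and the
#' biomass/productivity/export-fraction translations for both seepage and
#' venting. Unrounded values are retained throughout; rounding is left to
#' presentation.
#'
#' @param fit A `loss_model_fit` (or list with `f_loss`, `y0`).
#' @param const [seep_constants()].
#' @return A `flux_budget` list with components `areal` (nmol m-2 s-1),
#'   `basin_seepage` (mol/s), `vent` (mol/s), `seepage_fraction_pct`,
#'   `biomass_kg_C_yr`, `productivity_mol_C_m2_yr`, `pct_export`,
#'   `vent_pct_export`, each a `c(low, high)` pair, plus an `inputs`
#'   snapshot.
#' @export
flux_budget <- function(fit, const = seep_constants()) {
  SR <- c(low = const$SR_low, high = const$SR_high)
  areal <- areal_loss_flux(fit, SR, const$rho_dry, const)
  areas <- c(const$area_S, const$area_N)
  seep <- basin_seepage_flux(areal, areas)
  vent <- vent_flux(c(low = const$Q_low, high = const$Q_high),
                    const$c_endmember)
  prod_seep <- productivity_support(seep, const$basin_area, const)
  prod_vent <- productivity_support(vent, const$basin_area, const)
  structure(list(
    areal = areal,
    basin_seepage = seep,
    vent = vent,
    seepage_fraction_pct = c(low = seepage_fraction(seep[["low"]],
                                                    vent[["low"]]),
                             high = seepage_fraction(seep[["high"]],
                                                     vent[["high"]])),
    biomass_kg_C_yr = biomass_support(seep, const),
    productivity_mol_C_m2_yr = prod_seep,
    pct_export = pct_export(prod_seep, const$export_prod, const),
    vent_pct_export = pct_export(prod_vent, const$export_prod, const),
    inputs = list(f_loss = fit$f_loss, y0 = fit$y0,
                  SR = SR, rho_dry = const$rho_dry, areas = areas,
                  Q = c(const$Q_low, const$Q_high),
                  c_endmember = const$c_endmember,
                  basin_area = const$basin_area,
                  redfield_C_to_N = const$redfield_C_to_N,
                  export_prod = const$export_prod)
  ), class = "flux_budget")
}

#' @export
print.flux_budget <- function(x, ...) {
  f <- function(v) sprintf("%.3g-%.3g", v[[1]], v[[2]])
  cat("<flux_budget>\n")
  cat("  areal loss flux:     ", f(x$areal), "nmol m-2 s-1\n")
  cat("  basin seepage flux:  ", f(x$basin_seepage), "mol/s\n")
  cat("  vent flux:           ", f(x$vent), "mol/s\n")
  cat("  seepage fraction:    ", f(x$seepage_fraction_pct), "%\n")
  cat("  productivity:        ",
      sprintf("%.3g-%.3g", 1e3 * x$productivity_mol_C_m2_yr[[1]],
              1e3 * x$productivity_mol_C_m2_yr[[2]]), "mmol C m-2 yr-1\n")
  cat("  % of export (seep):  ", f(x$pct_export), "%\n")
  cat("  % of export (vent):  ", f(x$vent_pct_export), "%\n")
  invisible(x)
}
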