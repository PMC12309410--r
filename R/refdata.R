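#' The fourteen lanthanide rare-earth elements
#'
#' La through Lu in atomic-number order; Sc and Y are excluded from all REE
#' sums and ratios in this package.
#'
#' @return Character vector of 14 element symbols.
#' @export
ree_elements <- function() {
  c("La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
    "Er", "Tm", "Yb", "Lu")
}

# Average upper continental crust, ppm (after Rudnick & Gao 2003).
# Major elements converted from oxide wt% to elemental ppm.
.ucc_ppm <- c(
  Al = 81500, Fe = 39200, Ca = 25657, Na = 24259, K = 23244, Mg = 14955,
  Ti = 3836, Mn = 775, P = 655, S = 621, Ba = 628, Sr = 320,
  V = 97, Cr = 92, Zn = 67, Ni = 47, Cu = 28, Co = 17.3, Pb = 17,
  Th = 10.5, As = 4.8, U = 2.7, Mo = 1.1, Sb = 0.4, Se = 0.09,
  Cd = 0.09, Ag = 0.053,
  La = 31, Ce = 63, Pr = 7.1, Nd = 27, Sm = 4.7, Eu = 1.0, Gd = 4.0,
  Tb = 0.7, Dy = 3.9, Ho = 0.83, Er = 2.3, Tm = 0.30, Yb = 1.96, Lu = 0.31
)

# Post-Archean Australian Shale REE, ppm (Taylor & McLennan 1985).
.paas_ppm <- c(
  La = 38.2, Ce = 79.6, Pr = 8.83, Nd = 33.9, Sm = 5.55, Eu = 1.08,
  Gd = 4.66, Tb = 0.774, Dy = 4.68, Ho = 0.991, Er = 2.85, Tm = 0.405,
  Yb = 2.82, Lu = 0.433
)

# Standard seawater major-ion composition at salinity 35, g per kg solution.
.seawater_g_kg <- c(
  Cl = 19.353, Na = 10.781, Mg = 1.284, S = 0.905, Ca = 0.4119,
  K = 0.399, Br = 0.0673, Sr = 0.00794, B = 0.00446, F = 0.0013
)

#' Load a packaged reference composition
#'
#' Returns one of the reference tables used for normalization: average upper
#' continental crust (`"UCC"`, ppm), Post-Archean Australian Shale REEs
#' (`"PAAS"`, ppm), or standard seawater major ions (`"SEAWATER"`, g/kg
#' solution). Any table can be replaced from a two-column CSV
#' (`element,value`) to use a different compilation.
#'
#' @param name One of `"UCC"`, `"PAAS"`, `"SEAWATER"` (case-insensitive).
#' @param path Optional CSV file (`element,value` columns) overriding the
#'   packaged values for that table.
#' @return A `reference_composition`: list with `name` and named numeric
#'   `values`.
#' @export
load_reference <- function(name, path = NULL) {
  name <- toupper(name)
  if (!name %in% c("UCC", "PAAS", "SEAWATER")) {
    stop("unknown reference composition: ", name, call. = FALSE)
  }
  if (is.null(path)) {
    values <- switch(name,
      UCC = .ucc_ppm,
      PAAS = .paas_ppm,
      SEAWATER = .seawater_g_kg
    )
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("element", "value") %in% names(tab))) {
      stop("reference CSV must have columns 'element' and 'value'",
           call. = FALSE)
    }
    values <- stats::setNames(as.numeric(tab$value), tab$element)
  }
  ref <- structure(list(name = name, values = values),
                   class = "reference_composition")
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  v <- ref$values
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("reference composition '", ref$name,
         "' contains non-positive or non-finite values", call. = FALSE)
  }
  if (ref$name == "UCC" && !"Al" %in% names(v)) {
    stop("UCC table must contain Al", call. = FALSE)
  }
  if (ref$name == "PAAS" && !all(ree_elements() %in% names(v))) {
    stop("PAAS table must contain all 14 REEs", call. = FALSE)
  }
  invisible(ref)
}

#' @export
print.reference_composition <- function(x, ...) {
  cat("<reference_composition>", x$name, "-", length(x$values),
      "elements\n")
  invisible(x)
}

#' Physical and basin constants
#'
#' Bundles the molar masses, Redfield stoichiometry, sediment properties,
#' sedimentation-rate bounds, trough areas, hydrothermal fluid-flux bounds
#' and thermal-transport constants used throughout the flux calculations.
#' Every field can be overridden, either here or via the `[constants]` /
#' `[basin]` / `[fit]` / `[flow]` sections of a run-configuration file.
#'
#' Defaults: molar masses M_N = 14.007, M_C = 12.011 g/mol; Redfield C:N =
#' 106/16 (molar); year = 3.156e7 s; dry bulk density 0.4 g/cm3 and porosity
#' 0.8 (unconsolidated diatomaceous ooze); sedimentation rate 0.08-0.25
#' cm/yr; hydrothermally active trough areas 1e8 + 2e8 m2; whole-basin area
#' 1.405e10 m2; total hydrothermal fluid flux 10-12 m3/s with a 15.6 mM
#' NH4+ endmember; export production 4.8 mol C m-2 yr-1; sediment thermal
#' conductivity 0.9 W m-1 K-1; pore-fluid volumetric heat capacity
#' 4.18e6 J m-3 K-1.
#'
#' @param ... Name-value overrides of any default field.
#' @return A `seep_constants` list.
#' @export
seep_constants <- function(...) {
  const <- list(
    M_N = 14.007,            # g/mol
    M_C = 12.011,            # g/mol
    redfield_C_to_N = 106 / 16,
    sec_per_year = 3.156e7,  # s
    rho_dry = 0.4,           # g/cm3 dry bulk density
    porosity = 0.8,          # informational
    SR_low = 0.08,           # cm/yr
    SR_high = 0.25,          # cm/yr
    area_S = 1e8,            # m2, Southern Trough
    area_N = 2e8,            # m2, Northern Trough
    basin_area = 1.405e10,   # m2, whole basin
    Q_low = 10,              # m3/s
    Q_high = 12,             # m3/s
    c_endmember = 15.6,      # mM NH4+ vent endmember
    export_prod = 4.8,       # mol C m-2 yr-1
    lambda_s = 0.9,          # W m-1 K-1
    rho_cf = 4.18e6          # J m-3 K-1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(const))
    if (length(bad)) {
      stop("unknown constant(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    const[names(dots)] <- dots
  }
  num <- unlist(const)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all constants must be strictly positive and finite",
         call. = FALSE)
  }
  if (const$SR_low > const$SR_high) stop("SR_low > SR_high", call. = FALSE)
  if (const$Q_low > const$Q_high) stop("Q_low > Q_high", call. = FALSE)
  structure(const, class = "seep_constants")
}
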