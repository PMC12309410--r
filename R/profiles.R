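#' Sediment core profile
#'
#' Depth-ordered bulk geochemistry for one core: total organic carbon and
#' total nitrogen (wt%), their stable-isotope compositions, element
#' concentrations (canonically ppm) and, optionally, the porewater mass
#' fraction of the wet sediment (g porewater per g dry sediment, used for
#' seawater-salt corrections).
#'
#' @param core_id Core identifier.
#' @param data Data frame with columns `depth_cm` (sample midpoint, cm below
#'   seafloor, strictly increasing and > 0), `toc`, `tn` (wt%), `d13c`,
#'   `d15n` (permil), optionally `pw_mass_fraction`, plus one numeric column
#'   per element named by its symbol (ppm).
#' @return A `sediment_profile` object.
#' @export
sediment_profile <- function(core_id, data) {
  stopifnot(is.data.frame(data))
  need <- c("depth_cm", "toc", "tn", "d13c", "d15n")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("sediment profile missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  check_depths(data$depth_cm, positive = TRUE, what = core_id)
  if (any(data$toc < 0, na.rm = TRUE) || any(data$tn < 0, na.rm = TRUE)) {
    stop("toc/tn must be >= 0 in core ", core_id, call. = FALSE)
  }
  if (any(!is.finite(data$d13c)) || any(!is.finite(data$d15n))) {
    stop("d13c/d15n must be finite in core ", core_id, call. = FALSE)
  }
  els <- element_columns(data)
  for (el in els) {
    if (any(data[[el]] < 0, na.rm = TRUE)) {
      stop("negative concentration for ", el, " in core ", core_id,
           call. = FALSE)
    }
  }
  if (!is.null(data$pw_mass_fraction) &&
      any(data$pw_mass_fraction < 0, na.rm = TRUE)) {
    stop("pw_mass_fraction must be >= 0 in core ", core_id, call. = FALSE)
  }
  structure(list(core_id = as.character(core_id), data = data),
            class = "sediment_profile")
}

#' Porewater chemistry profile
#'
#' @param core_id Core identifier.
#' @param data Data frame with `depth_cm` (strictly increasing), `nh4_mM`
#'   (mmol NH4+ per litre, treated as exactly mol m-3) and optionally
#'   `d15n_nh4` (permil vs air; `NA` where not measured).
#' @return A `porewater_profile` object.
#' @export
porewater_profile <- function(core_id, data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c("depth_cm", "nh4_mM"), names(data))
  if (length(miss)) {
    stop("porewater profile missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)
  if (is.null(data$d15n_nh4)) data$d15n_nh4 <- NA_real_
  check_depths(data$depth_cm, positive = FALSE, what = core_id)
  if (any(data$nh4_mM < 0, na.rm = TRUE)) {
    stop("nh4_mM must be >= 0 in core ", core_id, call. = FALSE)
  }
  structure(list(core_id = as.character(core_id), data = data),
            class = "porewater_profile")
}

#' Thermal probe profile
#'
#' @param core_id Core identifier.
#' @param data Data frame with `depth_m` (m below seafloor, strictly
#'   increasing, at least 2 records) and `temp_c` (degrees C, > -2).
#' @return A `thermal_profile` object.
#' @export
thermal_profile <- function(core_id, data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c("depth_m", "temp_c"), names(data))
  if (length(miss)) {
    stop("thermal profile missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  if (nrow(data) < 2) {
    stop("thermal profile needs >= 2 records in core ", core_id,
         call. = FALSE)
  }
  check_depths(data$depth_m, positive = FALSE, what = core_id)
  if (any(data$temp_c <= -2)) {
    stop("temperatures must be > -2 C in core ", core_id, call. = FALSE)
  }
  structure(list(core_id = as.character(core_id), data = data),
            class = "thermal_profile")
}

check_depths <- function(depth, positive, what) {
  if (any(!is.finite(depth))) {
    stop("non-finite depth in core ", what, call. = FALSE)
  }
  if (positive && any(depth <= 0)) {
    stop("depths must be > 0 in core ", what, call. = FALSE)
  }
  if (length(depth) > 1 && any(diff(depth) <= 0)) {
    stop("depths must be strictly increasing in core ", what, call. = FALSE)
  }
  invisible(depth)
}

# Element concentration columns of a sediment data frame: those whose names
# are bare element symbols (1-2 letters, capitalised).
element_columns <- function(data) {
  nm <- names(data)
  nm[grepl("^[A-Z][a-z]?$", nm)]
}

#' @export
print.sediment_profile <- function(x, ...) {
  cat("<sediment_profile>", x$core_id, "-", nrow(x$data), "samples,",
      length(element_columns(x$data)), "elements,",
      sprintf("%.1f-%.1f cm\n", min(x$data$depth_cm), max(x$data$depth_cm)))
  invisible(x)
}

#' @export
print.porewater_profile <- function(x, ...) {
  cat("<porewater_profile>", x$core_id, "-", nrow(x$data), "samples, NH4+",
      sprintf("%.2f-%.2f mM\n", min(x$data$nh4_mM), max(x$data$nh4_mM)))
  invisible(x)
}

#' @export
print.thermal_profile <- function(x, ...) {
  cat("<thermal_profile>", x$core_id, "-", nrow(x$data), "readings,",
      sprintf("%.1f-%.1f C over %.2f m\n", min(x$data$temp_c),
              max(x$data$temp_c), diff(range(x$data$depth_m))))
  invisible(x)
}

#' @export
as.data.frame.sediment_profile <- function(x, ...) x$data

#' @export
as.data.frame.porewater_profile <- function(x, ...) x$data

#' @export
as.data.frame.thermal_profile <- function(x, ...) x$data
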