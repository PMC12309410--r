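#' Read core profiles from CSV
#'
#' Reads one of the three tabular schemas and converts units to the
#' package's canonical internal forms (element concentrations in ppm,
#' NH4+ in mM = mol m-3, probe depths in metres).
#'
#' Schemas (header names are mandatory):
#' * `sediment`: `core_id, depth_cm, toc_wt_pct, tn_wt_pct, d13c_permil,
#'   d15n_permil[, pw_mass_fraction]` plus one column per element named
#'   `<Symbol>_ppm`; aluminium may instead be supplied as `Al_wt_pct`.
#' * `porewater`: `core_id, depth_cm, nh4_mM[, d15n_nh4_permil]` (blanks
#'   allowed in the isotope column).
#' * `thermal`: `core_id, depth_cm, temp_c`.
#'
#' Rows must be ordered by strictly increasing depth within each core;
#' out-of-order or duplicated depths are rejected rather than silently
#' sorted.
#'
#' @param path CSV file.
#' @param schema `"sediment"`, `"porewater"` or `"thermal"`.
#' @return A single profile object if the file holds one core, otherwise a
#'   named list of profiles keyed by `core_id`.
#' @seealso [write_profiles()] for the inverse operation.
#' @export
read_profiles <- function(path, schema = c("sediment", "porewater",
                                           "thermal")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- switch(schema,
    sediment = c("core_id", "depth_cm", "toc_wt_pct", "tn_wt_pct",
                 "d13c_permil", "d15n_permil"),
    porewater = c("core_id", "depth_cm", "nh4_mM"),
    thermal = c("core_id", "depth_cm", "temp_c")
  )
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(schema, " schema missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$core_id), function(sub) {
    build_profile(sub, schema, core_id = sub$core_id[1])
  })
  if (length(out) == 1L) out[[1L]] else out[order(names(out))]
}

build_profile <- function(sub, schema, core_id) {
  if (schema == "sediment") {
    data <- data.frame(
      depth_cm = sub$depth_cm,
      toc = sub$toc_wt_pct,
      tn = sub$tn_wt_pct,
      d13c = sub$d13c_permil,
      d15n = sub$d15n_permil
    )
    if ("pw_mass_fraction" %in% names(sub)) {
      data$pw_mass_fraction <- sub$pw_mass_fraction
    }
    ppm_cols <- grep("^[A-Z][a-z]?_ppm$", names(sub), value = TRUE)
    for (cn in ppm_cols) {
      data[[sub("_ppm$", "", cn)]] <- sub[[cn]]
    }
    if ("Al_wt_pct" %in% names(sub)) {
      data$Al <- sub$Al_wt_pct * 1e4  # wt% -> ppm
    }
    sediment_profile(core_id, data)
  } else if (schema == "porewater") {
    data <- data.frame(depth_cm = sub$depth_cm, nh4_mM = sub$nh4_mM)
    data$d15n_nh4 <- if ("d15n_nh4_permil" %in% names(sub)) {
      as.numeric(sub$d15n_nh4_permil)
    } else NA_real_
    porewater_profile(core_id, data)
  } else {
    thermal_profile(core_id, data.frame(
      depth_m = sub$depth_cm / 100,  # canonical metres
      temp_c = sub$temp_c
    ))
  }
}

#' Write core profiles to CSV
#'
#' Inverse of [read_profiles()]: writes canonical units back to the on-disk
#' schema (elements as `<Symbol>_ppm`, probe depths as `depth_cm`), so a
#' read-write-read round trip reproduces the profile exactly.
#'
#' @param profiles A profile object or (possibly named) list of profiles of
#'   one schema.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, c("sediment_profile", "porewater_profile",
                           "thermal_profile"))) {
    profiles <- list(profiles)
  }
  rows <- lapply(profiles, profile_to_csv_rows)
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

profile_to_csv_rows <- function(p) {
  d <- p$data
  if (inherits(p, "sediment_profile")) {
    out <- data.frame(
      core_id = p$core_id, depth_cm = d$depth_cm,
      toc_wt_pct = d$toc, tn_wt_pct = d$tn,
      d13c_permil = d$d13c, d15n_permil = d$d15n
    )
    if (!is.null(d$pw_mass_fraction)) {
      out$pw_mass_fraction <- d$pw_mass_fraction
    }
    for (el in element_columns(d)) {
      out[[paste0(el, "_ppm")]] <- d[[el]]
    }
    out
  } else if (inherits(p, "porewater_profile")) {
    data.frame(core_id = p$core_id, depth_cm = d$depth_cm,
               nh4_mM = d$nh4_mM, d15n_nh4_permil = d$d15n_nh4)
  } else {
    data.frame(core_id = p$core_id, depth_cm = d$depth_m * 100,
               temp_c = d$temp_c)
  }
}

#' Read a run configuration file
#'
#' YAML file with optional sections `constants`, `basin`, `fit`, `flow`,
#' each holding name-value overrides of [seep_constants()] fields, plus
#' optional top-level `inputs` (paths to the three CSVs), `simulate`
#' (synthetic preset name) and `seed`. All four constant sections are merged
#' onto the defaults; section membership is organisational only.
#'
#' @param path YAML configuration file.
#' @return List with elements `constants` (a `seep_constants`), `inputs`,
#'   `simulate`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  overrides <- list()
  for (sec in c("constants", "basin", "fit", "flow")) {
    if (!is.null(raw[[sec]])) overrides <- c(overrides, raw[[sec]])
  }
  list(
    constants = do.call(seep_constants, overrides),
    inputs = raw$inputs,
    simulate = raw$simulate,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
}
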