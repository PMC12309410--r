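#' Al-normalized enrichment factor
#'
#' EF = (X/Al)_sample / (X/Al)_UCC, the sample's Al-normalized concentration
#' of element X relative to average upper continental crust. EF = 1 means
#' crustal abundance; the ratio is invariant under common dilution of all
#' sample concentrations (e.g. by migrated hydrocarbons or biogenic silica).
#'
#' @param x_ppm Sample concentration of the element (ppm).
#' @param al_ppm Sample Al concentration (ppm, > 0).
#' @param element Element symbol.
#' @param ucc UCC [reference composition][load_reference].
#' @return Dimensionless enrichment factor (vectorized over `x_ppm`/`al_ppm`).
#' @export
enrichment_factor <- function(x_ppm, al_ppm, element,
                              ucc = load_reference("UCC")) {
  if (any(al_ppm <= 0)) {
    stop("Al concentration must be > 0 for enrichment factors",
         call. = FALSE)
  }
  if (!element %in% names(ucc$values)) {
    stop("element ", element, " absent from ", ucc$name, " table",
         call. = FALSE)
  }
  if (!"Al" %in% names(ucc$values)) stop("UCC table lacks Al", call. = FALSE)
  (x_ppm / al_ppm) / (ucc$values[[element]] / ucc$values[["Al"]])
}

#' Shale-normalized europium anomaly
#'
#' Eu/Eu* = 2 Eu_SN / (Sm_SN + Gd_SN), where SN denotes PAAS normalization:
#' the europium excess over the linear interpolation of its neighbours.
#' Values > 1 indicate a hydrothermal or feldspar-derived Eu signal.
#'
#' @param eu_ppm,sm_ppm,gd_ppm Concentrations (ppm, >= 0).
#' @param paas PAAS [reference composition][load_reference].
#' @return Dimensionless anomaly; `NA` when Sm_SN + Gd_SN = 0.
#' @export
eu_anomaly <- function(eu_ppm, sm_ppm, gd_ppm,
                       paas = load_reference("PAAS")) {
  v <- paas$values
  eu_sn <- eu_ppm / v[["Eu"]]
  sm_sn <- sm_ppm / v[["Sm"]]
  gd_sn <- gd_ppm / v[["Gd"]]
  den <- sm_sn + gd_sn
  ifelse(den > 0, 2 * eu_sn / den, NA_real_)
}

#' REE sum and shale-normalized Pr/Yb ratio
#'
#' Sums the lanthanides present in `elements` and computes the
#' PAAS-normalized Pr/Yb ratio. Note the field convention followed here
#' labels (Pr/Yb)_SN an "HREE/LREE" indicator even though Pr is itself a
#' light REE; the ratio is computed exactly as written.
#'
#' @param elements Named numeric vector/list of element concentrations (ppm).
#' @param paas PAAS [reference composition][load_reference].
#' @return List with `sum_ree` (ppm, over REEs present) and `pr_yb_sn`
#'   (`NA` when Pr or Yb is missing or Yb = 0).
#' @export
ree_summary <- function(elements, paas = load_reference("PAAS")) {
  elements <- unlist(elements)
  ree <- intersect(ree_elements(), names(elements))
  if (!length(ree)) {
    stop("no REE concentrations present", call. = FALSE)
  }
  sum_ree <- sum(elements[ree])
  pr_yb <- NA_real_
  if (all(c("Pr", "Yb") %in% names(elements)) && elements[["Yb"]] > 0) {
    pr_yb <- (elements[["Pr"]] / paas$values[["Pr"]]) /
      (elements[["Yb"]] / paas$values[["Yb"]])
  }
  list(sum_ree = sum_ree, pr_yb_sn = pr_yb)
}

#' Carbon/nitrogen ratios
#'
#' C/N and its reciprocal N/C from TOC and TN contents. The default is the
#' mass (g/g) ratio; `mode = "molar"` multiplies C/N by M_N/M_C. When
#' TN = 0 the C/N ratio is undefined (`NA`) and N/C is 0; when both are 0
#' both are `NA`.
#'
#' @param toc_wt_pct,tn_wt_pct TOC and TN contents (wt%, >= 0); vectorized.
#' @param mode `"mass"` (default) or `"molar"`.
#' @param const [seep_constants()] supplying molar masses.
#' @return Data frame with columns `cn` and `nc`.
#' @export
cn_ratios <- function(toc_wt_pct, tn_wt_pct, mode = c("mass", "molar"),
                      const = seep_constants()) {
  mode <- match.arg(mode)
  if (any(toc_wt_pct < 0) || any(tn_wt_pct < 0)) {
    stop("toc/tn must be >= 0", call. = FALSE)
  }
  fac <- if (mode == "molar") const$M_N / const$M_C else 1
  cn <- ifelse(tn_wt_pct > 0, fac * toc_wt_pct / tn_wt_pct, NA_real_)
  nc <- ifelse(toc_wt_pct > 0, (tn_wt_pct / toc_wt_pct) / fac,
               ifelse(tn_wt_pct > 0, Inf, NA_real_))
  nc[tn_wt_pct == 0 & toc_wt_pct > 0] <- 0
  data.frame(cn = cn, nc = nc)
}

#' Seawater-salt correction of a measured concentration
#'
#' Unwashed lyophilized sediment retains porewater salts; the measured
#' concentration of a major seawater ion therefore includes
#' `pw_mass_fraction * C_sw` ppm-equivalents of sea salt, which this
#' subtracts. Negative corrected values are floored at zero and flagged
#' (attribute `floored`); elements absent from the seawater table pass
#' through unchanged with attribute `skipped = TRUE`.
#'
#' @param x_meas_ppm Measured concentration (ppm); vectorized.
#' @param element Element symbol.
#' @param pw_mass_fraction Porewater mass per dry-sediment mass (g/g, >= 0).
#' @param seawater Seawater [reference composition][load_reference] (g/kg).
#' @return Corrected ppm, with attributes `floored` (logical vector) and
#'   `skipped`.
#' @export
salt_correct <- function(x_meas_ppm, element, pw_mass_fraction,
                         seawater = load_reference("SEAWATER")) {
  if (any(pw_mass_fraction < 0)) {
    stop("pw_mass_fraction must be >= 0", call. = FALSE)
  }
  if (!element %in% names(seawater$values)) {
    return(structure(x_meas_ppm, skipped = TRUE,
                     floored = rep(FALSE, length(x_meas_ppm))))
  }
  corr <- x_meas_ppm - pw_mass_fraction * seawater$values[[element]] * 1e3
  floored <- corr < 0
  corr[floored] <- 0
  structure(corr, skipped = FALSE, floored = floored)
}

# 1.5xIQR outlier flags on a numeric vector (quartiles, type 7).
flag_outliers_iqr <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' Summarize bulk sediment isotope compositions
#'
#' Pools d13c and d15n across one or more sediment profiles and reports
#' mean, 1-sigma sd and n after flagging outliers. The default rule flags a
#' sample when either isotope falls outside 1.5xIQR of its pooled
#' distribution (union); flagged samples are reported, never silently
#' dropped. With fewer than 3 samples no outlier screening is attempted.
#'
#' @param profiles A `sediment_profile` or list of them.
#' @param outlier_rule `"iqr"` (default) or `"none"`.
#' @param k IQR multiplier for the fence (default 1.5).
#' @return List with `d13c` and `d15n` (each `mean`, `sd`), `n` (samples
#'   retained) and `outliers` (data frame of flagged samples).
#' @export
summarize_isotopes <- function(profiles, outlier_rule = c("iqr", "none"),
                               k = 1.5) {
  outlier_rule <- match.arg(outlier_rule)
  if (inherits(profiles, "sediment_profile")) profiles <- list(profiles)
  pooled <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(core_id = p$core_id, depth_cm = p$data$depth_cm,
               d13c = p$data$d13c, d15n = p$data$d15n)
  }))
  n_all <- nrow(pooled)
  flag <- rep(FALSE, n_all)
  if (outlier_rule == "iqr" && n_all >= 3) {
    flag <- flag_outliers_iqr(pooled$d13c, k) |
      flag_outliers_iqr(pooled$d15n, k)
  }
  keep <- pooled[!flag, , drop = FALSE]
  list(
    d13c = list(mean = mean(keep$d13c), sd = stats::sd(keep$d13c)),
    d15n = list(mean = mean(keep$d15n), sd = stats::sd(keep$d15n)),
    n = nrow(keep),
    outliers = pooled[flag, , drop = FALSE]
  )
}

#' Ordinary least-squares R-squared and slope sign
#'
#' @param x,y Numeric series (>= 3 finite pairs).
#' @return List with `r2` (in \[0, 1\]), `slope`, and `flag` (`TRUE` when x
#'   or y has zero variance, in which case `r2` is `NA`).
#' @export
linear_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r2 = NA_real_, slope = NA_real_, flag = TRUE))
  }
  r <- stats::cor(x, y)
  list(r2 = r^2,
       slope = r * stats::sd(y) / stats::sd(x),
       flag = FALSE)
}

#' Per-sample geochemical index table
#'
#' Computes, for each sample of a sediment profile: Al-normalized
#' enrichment factors for every element shared with the UCC table, the
#' shale-normalized Eu anomaly, the REE sum and (Pr/Yb)_SN ratio, C/N and
#' N/C ratios, and optionally seawater-salt-corrected concentrations
#' (requires `pw_mass_fraction`). Each row depends only on its own sample,
#' so row-wise and whole-table computation agree exactly.
#'
#' @param profile A `sediment_profile`.
#' @param mode C/N ratio mode, `"mass"` or `"molar"`.
#' @param salt_correct Logical: add `<El>_corr` columns for elements in the
#'   seawater table.
#' @param ucc,paas,seawater Reference compositions.
#' @param const [seep_constants()].
#' @return Data frame with one row per sample: `depth_cm`, `cn`, `nc`,
#'   `eu_anomaly`, `sum_ree`, `pr_yb_sn`, `ef_<El>` columns and optional
#'   `<El>_corr` columns.
#' @export
index_table <- function(profile, mode = "mass", salt_correct = FALSE,
                        ucc = load_reference("UCC"),
                        paas = load_reference("PAAS"),
                        seawater = load_reference("SEAWATER"),
                        const = seep_constants()) {
  d <- profile$data
  els <- element_columns(d)
  out <- data.frame(depth_cm = d$depth_cm)
  out <- cbind(out, cn_ratios(d$toc, d$tn, mode = mode, const = const))
  ree_present <- intersect(ree_elements(), els)
  if (all(c("Eu", "Sm", "Gd") %in% els)) {
    out$eu_anomaly <- eu_anomaly(d$Eu, d$Sm, d$Gd, paas)
  } else {
    out$eu_anomaly <- NA_real_
  }
  if (length(ree_present)) {
    ree_stats <- lapply(seq_len(nrow(d)), function(i) {
      ree_summary(unlist(d[i, ree_present, drop = FALSE]), paas)
    })
    out$sum_ree <- vapply(ree_stats, `[[`, numeric(1), "sum_ree")
    out$pr_yb_sn <- vapply(ree_stats, `[[`, numeric(1), "pr_yb_sn")
  } else {
    out$sum_ree <- NA_real_
    out$pr_yb_sn <- NA_real_
  }
  if ("Al" %in% els) {
    for (el in setdiff(intersect(els, names(ucc$values)), "Al")) {
      out[[paste0("ef_", el)]] <- enrichment_factor(d[[el]], d$Al, el, ucc)
    }
  }
  if (isTRUE(salt_correct)) {
    if (is.null(d$pw_mass_fraction)) {
      stop("salt correction requires pw_mass_fraction", call. = FALSE)
    }
    for (el in intersect(els, names(seawater$values))) {
      out[[paste0(el, "_corr")]] <-
        as.numeric(salt_correct(d[[el]], el, d$pw_mass_fraction, seawater))
    }
  }
  out
}
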