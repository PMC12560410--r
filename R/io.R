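#' Read titration series from a long-format CSV file
#'
#' Expects a comma-separated file with header columns `label`,
#' `temperature_K`, `conc`, `intensity` — one row per titration point, the
#' unquenched intensity carried by the `conc = 0` row of each group.
#' Rows are grouped by (label, temperature); concentrations are converted
#' from the configured input unit to mol/L.
#'
#' @param path CSV file path.
#' @param config An `analysis_config`; `concentration_input_unit` decides
#'   the conversion applied to the `conc` column.
#' @return A list of `titration_series`, one per (label, temperature)
#'   group, in file order of first appearance.
#' @export
read_titration <- function(path, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "temperature_K", "conc", "intensity")
  if (!all(need %in% names(df))) {
    stop("titration file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$intensity < 0)) stop("negative intensity in ", path)
  fac <- .unit_factor[[config$concentration_input_unit]]
  key <- paste(df$label, df$temperature_K, sep = "\r")
  lapply(unique(key), function(k) {
    g <- df[key == k, , drop = FALSE]
    zero <- g$conc == 0
    if (!any(zero)) {
      stop("no f0 (conc = 0) row for group '", g$label[1L], "' at ",
           g$temperature_K[1L], " K")
    }
    pts <- g[!zero, , drop = FALSE]
    if (nrow(pts) > 1L && any(diff(pts$conc) <= 0)) {
      stop("non-monotone concentrations for group '", g$label[1L], "' at ",
           g$temperature_K[1L], " K")
    }
    titration_series(
      temperature_K = g$temperature_K[1L],
      quencher_conc = pts$conc * fac,
      intensity = pts$intensity,
      f0 = g$intensity[zero][1L],
      label = g$label[1L]
    )
  })
}

#' Write titration series to the long-format CSV dialect read back by
#' [read_titration()]
#'
#' Concentrations are written in mol/L (the internal unit), with the f0 of
#' each series as its `conc = 0` row, at full double precision.
#'
#' @param series A `titration_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      label = s$label,
      temperature_K = s$temperature_K,
      conc = c(0, s$quencher_conc),
      intensity = c(s$f0, s$intensity)
    )
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("label,temperature_K,conc,intensity", con)
  writeLines(sprintf("%s,%s,%s,%s", rows$label,
                     format(rows$temperature_K, digits = 17),
                     format(rows$conc, digits = 17),
                     format(rows$intensity, digits = 17)), con)
  invisible(path)
}

#' Read a two-column spectrum CSV
#'
#' The first column is the axis, the second the intensity.  The axis kind
#' is taken from the header (a first column named `wavelength_nm` or
#' `wavenumber_cm1`) unless overridden by `axis_kind`.  A descending axis
#' is accepted and returned ascending.
#'
#' @param path CSV file path.
#' @param axis_kind Optional override: `"wavelength_nm"` or
#'   `"wavenumber_cm1"`.
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path, axis_kind = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectrum file must have two columns")
  if (nrow(df) < 5L) stop("spectrum has fewer than 5 points")
  if (is.null(axis_kind)) {
    axis_kind <- if (names(df)[1L] %in% c("wavelength_nm", "wavenumber_cm1")) {
      names(df)[1L]
    } else {
      "wavelength_nm"
    }
  }
  spectrum(df[[1L]], df[[2L]], axis_kind = axis_kind)
}

#' Write a spectrum to two-column CSV
#'
#' @param spec A `spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(spec$axis_kind, ",intensity"), con)
  writeLines(sprintf("%s,%s", format(spec$axis, digits = 17),
                     format(spec$intensity, digits = 17)), con)
  invisible(path)
}

# ---- report ---------------------------------------------------------------

# class-keyed manual dispatch: the generic stays internal, so S3 method
# registration would buy nothing
.report_record <- function(x) {
  switch(class(x)[1L],
    quench_result = .report_record_quench(x),
    binding_result = .report_record_binding(x),
    thermo_result = .report_record_thermo(x),
    competition_result = .report_record_competition(x),
    stop("cannot report an object of class ", class(x)[1L])
  )
}

.report_record_quench <- function(x) {
  list(
    kind = "stern_volmer",
    temperature_K = x$temperature_K,
    ksv_L_mol = x$ksv,
    corrected = x$corrected,
    r = x$fit$r,
    slope = x$fit$slope, slope_sd = x$fit$slope_sd,
    intercept = x$fit$intercept, intercept_sd = x$fit$intercept_sd,
    sd_residuals = x$fit$sd_residuals
  )
}

.report_record_binding <- function(x) {
  list(
    kind = "double_log",
    condition = x$label,
    temperature_K = x$temperature_K,
    log10_ka = x$log10_ka,
    ka_L_mol = x$ka,
    n_sites = x$n_sites,
    r = x$fit$r,
    slope = x$fit$slope, slope_sd = x$fit$slope_sd,
    intercept = x$fit$intercept, intercept_sd = x$fit$intercept_sd,
    sd_residuals = x$fit$sd_residuals
  )
}

.report_record_thermo <- function(x) {
  list(
    kind = "thermodynamics",
    delta_H_kJ_mol = x$delta_H / 1000,
    delta_S_J_mol_K = x$delta_S,
    delta_G_kJ_mol_by_T = as.list(x$delta_G_by_T / 1000),
    force_call = x$force_call,
    spontaneous = x$spontaneous,
    vant_hoff_r = x$vant_hoff_fit$r
  )
}

.report_record_competition <- function(x) {
  list(
    kind = "competition",
    condition = x$condition,
    log10_ka = x$log10_ka,
    ka_L_mol = x$ka,
    ka_ratio_to_blank = x$ka_ratio_to_blank,
    effect = x$effect,
    n_sites = x$n_sites,
    r = x$r
  )
}

.report_line <- function(rec) {
  switch(rec$kind,
    stern_volmer = sprintf(
      "  %5g K  Ksv = %10.4g L/mol  r = %.4f  slope %.4g +/- %.2g  intercept %.4g +/- %.2g  SDres %.4g",
      rec$temperature_K, rec$ksv_L_mol, rec$r, rec$slope, rec$slope_sd,
      rec$intercept, rec$intercept_sd, rec$sd_residuals),
    double_log = sprintf(
      "  %-14s %5g K  logKa = %.4f  Ka = %10.4g L/mol  n = %.3f  r = %.4f",
      rec$condition, rec$temperature_K, rec$log10_ka, rec$ka_L_mol,
      rec$n_sites, rec$r),
    thermodynamics = paste0(
      sprintf("  dH = %.3f kJ/mol  dS = %.2f J/mol/K  forces = %s  spontaneous = %s\n",
              rec$delta_H_kJ_mol, rec$delta_S_J_mol_K, rec$force_call,
              rec$spontaneous),
      paste(sprintf("    %5s K  dG = %.3f kJ/mol",
                    names(rec$delta_G_kJ_mol_by_T),
                    unlist(rec$delta_G_kJ_mol_by_T)), collapse = "\n")),
    competition = sprintf(
      "  %-14s logKa = %.4f  Ka = %10.4g L/mol  ratio = %.3f  effect = %s",
      rec$condition, rec$log10_ka, rec$ka_L_mol, rec$ka_ratio_to_blank,
      rec$effect)
  )
}

#' Write an analysis report
#'
#' Serialises any mix of Stern-Volmer, double-log binding, thermodynamic
#' and competition results as a machine-readable JSON file at `path`, plus
#' a human-readable table (one section per result kind, per-temperature
#' rows) at the same path with a `.txt` extension.
#'
#' @param results A single result object or a list of `quench_result`,
#'   `binding_result`, `thermo_result` and/or `competition_result` objects.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  known <- c("quench_result", "binding_result", "thermo_result",
             "competition_result")
  if (inherits(results, known)) results <- list(results)
  if (!is.list(results) || length(results) == 0L) {
    stop("write_report needs at least one result")
  }
  recs <- lapply(results, .report_record)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- vapply(recs, .report_line, character(1L))
  kinds <- vapply(recs, `[[`, character(1L), "kind")
  lines <- unlist(lapply(unique(kinds), function(k) {
    c(paste0("== ", k, " =="), txt[kinds == k], "")
  }))
  writeLines(lines, sub("\\.[A-Za-z0-9]+$", ".txt", path))
  invisible(path)
}
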