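#' Universal gas constant used throughout (J mol^-1 K^-1)
#'
#' Fixed at 8.314 so that enthalpies and Gibbs energies come out in joules
#' per mole from binding constants in L/mol.
#' @export
GAS_CONSTANT <- 8.314

#' Analysis configuration
#'
#' Bundles the small set of tunable thresholds shared by the pipeline
#' stages.  The gas constant is fixed and validated, not tunable.
#'
#' @param concentration_input_unit Unit of the `conc` column in titration
#'   files: `"M"`, `"mM"` or `"uM"`.  Internally everything is mol/L.
#' @param significance_ratio_threshold Half-width of the "unchanged" band
#'   for competition calls: a condition whose Ka ratio to blank satisfies
#'   `|1 - ratio| <= threshold` is called unchanged.  Default 0.25, chosen
#'   so a ~23% increase (typical of a non-displacing site probe) does not
#'   register as an effect.
#' @param mechanism_trend_min_points Minimum number of distinct
#'   temperatures required before a quenching-mechanism call is attempted.
#' @param stoichiometry_tol Half-width of the band around 1 inside which a
#'   fitted site number n is annotated as "approximately 1:1".
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(concentration_input_unit = c("M", "mM", "uM"),
                            significance_ratio_threshold = 0.25,
                            mechanism_trend_min_points = 3L,
                            stoichiometry_tol = 0.15) {
  concentration_input_unit <- match.arg(concentration_input_unit)
  stopifnot(
    is.numeric(significance_ratio_threshold),
    length(significance_ratio_threshold) == 1L,
    significance_ratio_threshold > 0, significance_ratio_threshold < 1,
    mechanism_trend_min_points >= 2L,
    stoichiometry_tol > 0, stoichiometry_tol < 1
  )
  structure(
    list(
      gas_constant_R = GAS_CONSTANT,
      concentration_input_unit = concentration_input_unit,
      significance_ratio_threshold = significance_ratio_threshold,
      mechanism_trend_min_points = as.integer(mechanism_trend_min_points),
      stoichiometry_tol = stoichiometry_tol
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The file may set any subset of the `analysis_config()` arguments; fields
#' not present keep their defaults.  A `gas_constant_R` entry, if present,
#' must equal 8.314 exactly.
#'
#' @param path Path to a YAML file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$gas_constant_R) && raw$gas_constant_R != GAS_CONSTANT) {
    stop("gas_constant_R must be 8.314 J/mol/K, got ", raw$gas_constant_R)
  }
  args <- raw[intersect(
    names(raw),
    c("concentration_input_unit", "significance_ratio_threshold",
      "mechanism_trend_min_points", "stoichiometry_tol")
  )]
  do.call(analysis_config, args)
}

# conversion factors to mol/L for the supported input units
.unit_factor <- c(M = 1, mM = 1e-3, uM = 1e-6)

#' One fluorescence titration at a fixed temperature and condition
#'
#' Holds the quencher concentration grid (mol/L), the fluorescence
#' intensities measured at each concentration, and the unquenched intensity
#' `f0` measured at zero quencher.
#'
#' @param temperature_K Absolute temperature in kelvin (> 0).
#' @param quencher_conc Strictly increasing, non-negative quencher
#'   concentrations in mol/L.
#' @param intensity Strictly positive fluorescence intensities, one per
#'   concentration (arbitrary units).
#' @param f0 Intensity at zero quencher (> 0).
#' @param label Condition tag, e.g. `"blank"`, `"diazepam"`, `"Co2+"`.
#' @param excitation_nm,emission_nm Optional instrument wavelengths.
#'
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(temperature_K, quencher_conc, intensity, f0,
                             label = "blank",
                             excitation_nm = NULL, emission_nm = NULL) {
  stopifnot(
    is.numeric(temperature_K), length(temperature_K) == 1L, temperature_K > 0,
    is.numeric(quencher_conc), is.numeric(intensity),
    length(quencher_conc) == length(intensity),
    is.numeric(f0), length(f0) == 1L, f0 > 0,
    is.character(label), length(label) == 1L
  )
  if (any(quencher_conc < 0)) {
    stop("quencher concentrations must be non-negative")
  }
  if (length(quencher_conc) > 1L && any(diff(quencher_conc) <= 0)) {
    stop("quencher concentrations must be strictly increasing")
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop("intensities must be finite and strictly positive")
  }
  structure(
    list(
      temperature_K = as.numeric(temperature_K),
      quencher_conc = as.numeric(quencher_conc),
      intensity = as.numeric(intensity),
      f0 = f0,
      label = label,
      excitation_nm = excitation_nm,
      emission_nm = emission_nm
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %s @ %g K, %d points, [Q] %.3g-%.3g M, f0 = %g\n",
    x$label, x$temperature_K, length(x$quencher_conc),
    min(x$quencher_conc), max(x$quencher_conc), x$f0
  ))
  invisible(x)
}

#' A one-dimensional spectrum
#'
#' Wavelength (nm) or wavenumber (cm^-1) grid with intensities, used for
#' emission bands, synchronous-fluorescence scans and infrared-style data.
#' The axis is stored ascending; descending input is reversed together with
#' its intensities.
#'
#' @param axis Strictly monotone numeric axis (no duplicates).
#' @param intensity Finite intensities, one per axis point.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm1"`.
#' @param delta_lambda Optional offset (nm) for synchronous scans.
#'
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(axis, intensity,
                     axis_kind = c("wavelength_nm", "wavenumber_cm1"),
                     delta_lambda = NULL) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(is.numeric(axis), is.numeric(intensity),
            length(axis) == length(intensity))
  if (anyDuplicated(axis)) stop("duplicate axis values in spectrum")
  if (any(!is.finite(axis)) || any(!is.finite(intensity))) {
    stop("spectrum axis and intensities must be finite")
  }
  d <- diff(axis)
  if (length(d) && all(d < 0)) {           # descending input: flip
    axis <- rev(axis); intensity <- rev(intensity)
  } else if (length(d) && any(d <= 0)) {
    stop("spectrum axis must be strictly monotone")
  }
  structure(
    list(axis = as.numeric(axis), intensity = as.numeric(intensity),
         axis_kind = axis_kind, delta_lambda = delta_lambda),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$axis_kind == "wavelength_nm") "nm" else "cm-1"
  cat(sprintf("<spectrum> %d points, %g-%g %s\n",
              length(x$axis), min(x$axis), max(x$axis), unit))
  invisible(x)
}

#' Straight-line fit summary
#'
#' Every regression in the pipeline (Stern-Volmer, double-log, van't Hoff,
#' mechanism trend) is an ordinary least-squares straight line; this wraps
#' `stats::lm` and keeps the statistics the binding literature tabulates:
#' slope and intercept with their standard deviations, the correlation
#' coefficient r, and the standard deviation of the residuals.
#'
#' @param x,y Numeric vectors of equal length (>= 2 points, x not constant).
#' @return An object of class `linear_fit` with fields `slope`, `intercept`,
#'   `slope_sd`, `intercept_sd`, `r`, `sd_residuals`, `n_points`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L)
  if (diff(range(x)) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; noiseless closure data hit that often
  cf <- suppressWarnings(summary(fit))$coefficients
  # with 2 points the fit is exact and lm reports NaN standard errors
  slope_sd <- if (nrow(cf) == 2L && ncol(cf) >= 2L) cf["x", "Std. Error"] else NA_real_
  intercept_sd <- if (ncol(cf) >= 2L) cf["(Intercept)", "Std. Error"] else NA_real_
  r <- if (stats::sd(y) == 0) {
    # flat response: perfectly fit by a horizontal line
    1
  } else {
    stats::cor(x, y)
  }
  sdres <- sqrt(sum(stats::residuals(fit)^2) / max(length(x) - 2L, 1L))
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      slope_sd = ifelse(is.nan(slope_sd), NA_real_, slope_sd),
      intercept_sd = ifelse(is.nan(intercept_sd), NA_real_, intercept_sd),
      r = r,
      sd_residuals = sdres,
      n_points = length(x)
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> slope %.6g +/- %.2g, intercept %.6g +/- %.2g, r = %.4f, n = %d\n",
    x$slope, x$slope_sd, x$intercept, x$intercept_sd, x$r, x$n_points
  ))
  invisible(x)
}
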