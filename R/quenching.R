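#' Inner-filter effect correction
#'
#' Corrects an observed fluorescence intensity for attenuation of the
#' excitation and emission beams by absorbing species in the cuvette:
#' `F_corrected = F_observed * 10^((A_ex + A_em) / 2)`, where `A_ex` and
#' `A_em` are the absorbances at the excitation and emission wavelengths.
#' The correction can only increase the intensity.
#'
#' @param f_observed Observed intensity (> 0).  Vectorised.
#' @param a_ex,a_em Absorbances at the excitation and emission wavelengths
#'   (>= 0); a negative value signals mis-ordered blank subtraction and is
#'   an error.
#' @return Corrected intensity, `>= f_observed`.
#' @export
ife_correct <- function(f_observed, a_ex, a_em) {
  stopifnot(is.numeric(f_observed), is.numeric(a_ex), is.numeric(a_em))
  if (any(f_observed <= 0)) stop("f_observed must be strictly positive")
  if (any(a_ex < 0) || any(a_em < 0)) {
    stop("negative absorbance: check blank subtraction")
  }
  f_observed * 10^((a_ex + a_em) / 2)
}

#' Stern-Volmer fit of a titration
#'
#' Fits the linear Stern-Volmer relation `F0/F = 1 + Ksv [Q]` by ordinary
#' least squares of `F0/F` on the quencher concentration in mol/L.  The
#' intercept is fitted freely (not pinned at 1) so the regression
#' statistics match how the quenching literature tabulates them; `Ksv` is
#' the slope, in L/mol.
#'
#' @param series A `titration_series` with at least 3 points.
#' @param corrected Logical flag recording whether the intensities were
#'   inner-filter corrected before fitting (bookkeeping only).
#' @return A `quench_result`: `temperature_K`, `ksv` (L/mol), `fit`
#'   (a `linear_fit`), `corrected`.
#' @export
stern_volmer_fit <- function(series, corrected = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$quencher_conc) < 3L) {
    stop("Stern-Volmer fit needs at least 3 titration points")
  }
  if (any(series$intensity >= series$f0 + 1e-9)) {
    warning("intensity above f0 (anti-quenching point); fitted anyway")
  }
  fit <- linear_fit(series$quencher_conc, series$f0 / series$intensity)
  structure(
    list(temperature_K = series$temperature_K, ksv = fit$slope,
         fit = fit, corrected = isTRUE(corrected)),
    class = "quench_result"
  )
}

#' @export
print.quench_result <- function(x, ...) {
  cat(sprintf("<quench_result> %g K: Ksv = %.4g L/mol (r = %.4f%s)\n",
              x$temperature_K, x$ksv, x$fit$r,
              if (x$corrected) ", IFE-corrected" else ""))
  invisible(x)
}

#' Classify the quenching mechanism from the temperature trend of Ksv
#'
#' Static quenching proceeds through a ground-state fluorophore-quencher
#' complex that higher temperature destabilises, so `Ksv` falls as `T`
#' rises; dynamic (collisional) quenching is diffusion-driven, so `Ksv`
#' rises with `T`.  The call is conservative: it requires both the sign of
#' the OLS slope of `Ksv` versus `T` and strict monotonicity across the
#' sorted temperatures; anything else is indeterminate.
#'
#' @param results List of `quench_result` at distinct temperatures (order
#'   irrelevant), at least `config$mechanism_trend_min_points` of them.
#' @param config An `analysis_config`.
#' @return A `mechanism_call`: `call` (`"static"`, `"dynamic"` or
#'   `"indeterminate"`), `trend_statistic` (slope of Ksv vs T, L/mol/K),
#'   `n_temperatures`.
#' @export
classify_mechanism <- function(results, config = analysis_config()) {
  stopifnot(is.list(results), inherits(config, "analysis_config"))
  temps <- vapply(results, `[[`, numeric(1L), "temperature_K")
  ksv <- vapply(results, `[[`, numeric(1L), "ksv")
  if (anyDuplicated(temps)) stop("duplicate temperatures in mechanism call")
  if (length(temps) < config$mechanism_trend_min_points) {
    stop("need at least ", config$mechanism_trend_min_points,
         " temperatures for a mechanism call")
  }
  ord <- order(temps)
  slope <- linear_fit(temps, ksv)$slope
  d <- diff(ksv[ord])
  call <- if (slope < 0 && all(d < 0)) {
    "static"
  } else if (slope > 0 && all(d > 0)) {
    "dynamic"
  } else {
    "indeterminate"
  }
  structure(
    list(call = call, trend_statistic = slope,
         n_temperatures = length(temps)),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (dKsv/dT = %.4g L/mol/K over %d temperatures)\n",
              x$call, x$trend_statistic, x$n_temperatures))
  invisible(x)
}

#' Relative difference in percent
#'
#' `100 * |a - b| / |b|`; used e.g. to quantify how much an inner-filter
#' correction moved a fitted quenching constant.
#'
#' @param a,b Numeric; `b` is the reference and must be nonzero.
#' @return Percent relative difference.
#' @export
relative_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(b == 0)) stop("reference value b must be nonzero")
  100 * abs(a - b) / abs(b)
}
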