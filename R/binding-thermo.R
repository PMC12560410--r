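#' Double-logarithmic (modified Stern-Volmer) binding fit
#'
#' Fits `log10((F0 - F)/F) = log10(Ka) + n * log10([Q])` by ordinary least
#' squares.  The intercept gives the binding constant `Ka` (L/mol) and the
#' slope the apparent number of binding sites `n`.  Points with `F >= f0`
#' have no defined left-hand side and are excluded with a warning.
#'
#' @param series A `titration_series`; needs >= 3 usable points.
#' @return A `binding_result`: `temperature_K`, `label`, `log10_ka`, `ka`,
#'   `n_sites`, `fit` (a `linear_fit`).
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  ok <- series$intensity < series$f0
  if (any(!ok)) {
    warning(sum(!ok), " point(s) with F >= f0 excluded from double-log fit")
  }
  if (sum(ok) < 3L) stop("double-log fit needs at least 3 points with F < f0")
  q <- series$quencher_conc[ok]
  f <- series$intensity[ok]
  fit <- linear_fit(log10(q), log10((series$f0 - f) / f))
  structure(
    list(
      temperature_K = series$temperature_K,
      label = series$label,
      log10_ka = fit$intercept,
      ka = 10^fit$intercept,
      n_sites = fit$slope,
      fit = fit
    ),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> %s @ %g K: Ka = %.4g L/mol (logKa = %.4f), n = %.3f\n",
              x$label, x$temperature_K, x$ka, x$log10_ka, x$n_sites))
  invisible(x)
}

#' Construct a binding_result directly from a binding constant
#'
#' Convenience for downstream comparisons when only (log10) Ka values are
#' known, e.g. tabulated constants, without refitting raw titrations.
#'
#' @param log10_ka Base-10 log of the binding constant (L/mol).
#' @param temperature_K Temperature of the determination.
#' @param label Condition tag.
#' @param n_sites,r Optional fitted stoichiometry and correlation
#'   coefficient, carried through to reports.
#' @return A `binding_result` with a `NULL` fit.
#' @export
binding_result <- function(log10_ka, temperature_K, label = "blank",
                           n_sites = NA_real_, r = NA_real_) {
  stopifnot(is.numeric(log10_ka), length(log10_ka) == 1L,
            temperature_K > 0)
  structure(
    list(temperature_K = temperature_K, label = label,
         log10_ka = log10_ka, ka = 10^log10_ka, n_sites = n_sites,
         fit = list(r = r, slope = n_sites, intercept = log10_ka,
                    slope_sd = NA_real_, intercept_sd = NA_real_,
                    sd_residuals = NA_real_, n_points = NA_integer_)),
    class = "binding_result"
  )
}

#' van't Hoff fit of binding constants versus temperature
#'
#' Ordinary least squares of `ln(Ka)` on `1/T`:
#' `ln Ka = -dH/(R T) + dS/R`, so `dH = -R * slope` and
#' `dS = R * intercept`, with `R = 8.314` J/mol/K.  Assumes dH and dS are
#' constant over the temperature window (the usual linear van't Hoff
#' approximation over a few tens of kelvin).
#'
#' @param points A data.frame with columns `temperature_K` and `ka`
#'   (L/mol), >= 3 distinct temperatures, all `ka > 0`.
#' @return A list: `delta_H` (J/mol), `delta_S` (J/mol/K), `fit` (a
#'   `linear_fit` of ln Ka on 1/T).
#' @export
vant_hoff_fit <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temperature_K", "ka") %in% names(points)))
  if (anyDuplicated(points$temperature_K)) {
    stop("duplicate temperatures in van't Hoff fit")
  }
  if (nrow(points) < 3L) stop("van't Hoff fit needs >= 3 temperatures")
  if (any(points$ka <= 0)) stop("binding constants must be positive")
  fit <- linear_fit(1 / points$temperature_K, log(points$ka))
  list(
    delta_H = -GAS_CONSTANT * fit$slope,
    delta_S = GAS_CONSTANT * fit$intercept,
    fit = fit
  )
}

#' Gibbs energy from a binding constant
#'
#' `dG = -R T ln(Ka)`, joules per mole; negative whenever `Ka > 1` L/mol,
#' i.e. for any spontaneous association.
#'
#' @param ka Binding constant (L/mol, > 0).  Vectorised.
#' @param temperature_K Absolute temperature (> 0).
#' @return dG in J/mol.
#' @export
gibbs_from_ka <- function(ka, temperature_K) {
  stopifnot(is.numeric(ka), is.numeric(temperature_K))
  if (any(ka <= 0) || any(temperature_K <= 0)) {
    stop("ka and temperature must be strictly positive")
  }
  -GAS_CONSTANT * temperature_K * log(ka)
}

#' Gibbs energy from enthalpy and entropy
#'
#' `dG = dH - T dS` (Gibbs-Helmholtz route).  On data lying exactly on the
#' van't Hoff line this coincides with [gibbs_from_ka()]; on real (noisy)
#' data the two routes differ slightly because dH and dS come from a fit.
#'
#' @param delta_H Enthalpy change, J/mol.
#' @param delta_S Entropy change, J/mol/K.
#' @param temperature_K Absolute temperature (> 0).
#' @return dG in J/mol.
#' @export
gibbs_from_enthalpy <- function(delta_H, delta_S, temperature_K) {
  stopifnot(is.numeric(delta_H), is.numeric(delta_S),
            all(temperature_K > 0))
  delta_H - temperature_K * delta_S
}

#' Classify the dominant binding forces from (dH, dS) signs
#'
#' The Ross-Subramanian sign rules for protein-ligand association:
#' both negative -> hydrogen bonding / van der Waals; both positive ->
#' hydrophobic; dH < 0 with dS > 0 -> electrostatic.  A zero component is
#' indeterminate.
#'
#' @param delta_H Enthalpy change, J/mol.
#' @param delta_S Entropy change, J/mol/K.
#' @return One of `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @export
classify_forces <- function(delta_H, delta_S) {
  stopifnot(is.numeric(delta_H), is.numeric(delta_S))
  if (delta_H == 0 || delta_S == 0) return("indeterminate")
  if (delta_H < 0 && delta_S < 0) return("hbond_vdw")
  if (delta_H > 0 && delta_S > 0) return("hydrophobic")
  if (delta_H < 0 && delta_S > 0) return("electrostatic")
  # dH > 0, dS < 0: doubly unfavourable, no conventional assignment
  "indeterminate"
}

#' Full thermodynamic analysis of per-temperature binding results
#'
#' Runs the van't Hoff fit on the supplied binding constants, computes the
#' per-temperature Gibbs energies via `-R T ln Ka` (each temperature's own
#' constant, not the fitted line), classifies the dominant forces from the
#' (dH, dS) signs, and flags spontaneity (all dG < 0).
#'
#' @param binding_results List of `binding_result` at >= 3 distinct
#'   temperatures.
#' @return A `thermo_result`: `delta_H` (J/mol), `delta_S` (J/mol/K),
#'   `delta_G_by_T` (named J/mol vector, names are temperatures),
#'   `vant_hoff_fit` (a `linear_fit`), `force_call`, `spontaneous`.
#' @export
thermo_analysis <- function(binding_results) {
  stopifnot(is.list(binding_results))
  temps <- vapply(binding_results, `[[`, numeric(1L), "temperature_K")
  ka <- vapply(binding_results, `[[`, numeric(1L), "ka")
  vh <- vant_hoff_fit(data.frame(temperature_K = temps, ka = ka))
  dG <- gibbs_from_ka(ka, temps)
  names(dG) <- format(temps)
  structure(
    list(
      delta_H = vh$delta_H,
      delta_S = vh$delta_S,
      delta_G_by_T = dG,
      vant_hoff_fit = vh$fit,
      force_call = classify_forces(vh$delta_H, vh$delta_S),
      spontaneous = all(dG < 0)
    ),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.3f kJ/mol, dS = %.2f J/mol/K, %s, spontaneous = %s\n",
              x$delta_H / 1000, x$delta_S, x$force_call, x$spontaneous))
  for (i in seq_along(x$delta_G_by_T)) {
    cat(sprintf("  %s K: dG = %.3f kJ/mol\n",
                names(x$delta_G_by_T)[i], x$delta_G_by_T[i] / 1000))
  }
  invisible(x)
}
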