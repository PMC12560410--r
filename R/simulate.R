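#' Specification of a synthetic titration experiment
#'
#' Defines the ground truth and design of a simulated quenching study.  The
#' defaults emulate a serum-albumin titration: five temperatures between
#' 285 and 308 K, six quencher concentrations from 30 to 180 uM, binding
#' governed by a fixed (dH, dS) through the van't Hoff relation, 1%
#' multiplicative detector noise.
#'
#' @param delta_H Binding enthalpy, J/mol (default -52434).
#' @param delta_S Binding entropy, J/mol/K (default -99.63).
#' @param temperatures Distinct temperatures in K.
#' @param conc_grid Positive increasing quencher concentrations, mol/L.
#' @param f0 Unquenched intensity (arbitrary units).
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   intensity noise (default 0.01; 0 for noiseless data).
#' @param mechanism `"static"` (ground-state complex; Ksv = Ka falls with
#'   T when dH < 0) or `"dynamic"` (collisional stand-in whose Ksv rises
#'   with T as `Ksv_ref * (T/285)^4`).
#' @param seed Master seed; each generated series draws from its own
#'   deterministic substream, so adding a condition never perturbs the
#'   noise of existing ones.
#' @param ife_absorbance_per_molar Optional `c(eps_ex, eps_em)` molar
#'   attenuation coefficients (L/mol per path) used to superimpose an
#'   inner-filter effect on the generated intensities.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(delta_H = -52434,
                            delta_S = -99.63,
                            temperatures = c(285, 290, 295, 303, 308),
                            conc_grid = seq(3e-5, 1.8e-4, length.out = 6),
                            f0 = 1000,
                            noise_cv = 0.01,
                            mechanism = c("static", "dynamic"),
                            seed = 1L,
                            ife_absorbance_per_molar = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(
    is.numeric(delta_H), is.numeric(delta_S),
    length(temperatures) >= 1L, !anyDuplicated(temperatures),
    all(conc_grid > 0), all(diff(conc_grid) > 0),
    f0 > 0, noise_cv >= 0,
    is.numeric(seed), length(seed) == 1L
  )
  if (!is.null(ife_absorbance_per_molar)) {
    stopifnot(length(ife_absorbance_per_molar) == 2L,
              all(ife_absorbance_per_molar >= 0))
  }
  structure(
    list(delta_H = delta_H, delta_S = delta_S,
         temperatures = as.numeric(temperatures),
         conc_grid = as.numeric(conc_grid),
         f0 = f0, noise_cv = noise_cv, mechanism = mechanism,
         seed = as.integer(seed),
         ife_absorbance_per_molar = ife_absorbance_per_molar),
    class = "simulation_spec"
  )
}

#' Read a simulation specification from YAML
#'
#' @param path YAML file whose keys mirror the [simulation_spec()]
#'   arguments.
#' @return A `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(simulation_spec)))]
  if (!is.null(args$conc_grid)) args$conc_grid <- as.numeric(args$conc_grid)
  if (!is.null(args$temperatures)) args$temperatures <- as.numeric(args$temperatures)
  do.call(simulation_spec, args)
}

#' Binding constant implied by the simulation thermodynamics
#'
#' `Ka(T) = exp(-dH/(R T) + dS/R)` — the van't Hoff relation run forward.
#' Strictly decreasing in T when dH < 0.
#'
#' @param spec A `simulation_spec`.
#' @param temperature_K Temperature in K (> 0).  Vectorised.
#' @return Ka in L/mol.
#' @export
ka_of_T <- function(spec, temperature_K) {
  stopifnot(inherits(spec, "simulation_spec"), all(temperature_K > 0))
  exp(-spec$delta_H / (GAS_CONSTANT * temperature_K) +
        spec$delta_S / GAS_CONSTANT)
}

# deterministic substream seed for a (label, temperature) series: a small
# polynomial hash folded into the master seed, kept inside 32-bit range
.substream_seed <- function(seed, label, temperature_K) {
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 131 + cc) %% 1000003
  h <- (h * 131 + round(temperature_K * 100)) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h) %% 2147483587L
}

#' Generate one synthetic titration series
#'
#' Ground truth is the 1:1 static-quenching model
#' `F([Q]) = f0 / (1 + Ksv(T) [Q])`, with `Ksv(T) = Ka(T)` from the spec's
#' thermodynamics for the static mechanism, or the increasing stand-in
#' `Ksv(T) = Ka(285) * (T/285)^4` for the dynamic mechanism.  Multiplicative
#' Gaussian noise `N(1, noise_cv)` is applied per titration point (f0 is
#' the noiseless reference), then optional inner-filter attenuation
#' `F -> F * 10^(-[Q](eps_ex + eps_em)/2)`.
#'
#' @param spec A `simulation_spec`.
#' @param temperature_K One of `spec$temperatures`.
#' @param label Condition tag for the series.
#' @param ka_scale Multiplier on Ka(T), used to emulate competing
#'   conditions that weaken or strengthen apparent binding.
#' @return A `titration_series`.
#' @export
generate_titration <- function(spec, temperature_K, label = "blank",
                               ka_scale = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!temperature_K %in% spec$temperatures) {
    stop("temperature ", temperature_K, " K is not in the simulation spec")
  }
  ksv <- if (spec$mechanism == "static") {
    ka_of_T(spec, temperature_K)
  } else {
    ka_of_T(spec, 285) * (temperature_K / 285)^4
  }
  ksv <- ksv * ka_scale
  q <- spec$conc_grid
  f <- spec$f0 / (1 + ksv * q)
  if (spec$noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.substream_seed(spec$seed, label, temperature_K))
    f <- f * stats::rnorm(length(f), mean = 1, sd = spec$noise_cv)
  }
  if (!is.null(spec$ife_absorbance_per_molar)) {
    eps <- spec$ife_absorbance_per_molar
    f <- f * 10^(-(q * eps[1L] + q * eps[2L]) / 2)
  }
  titration_series(
    temperature_K = temperature_K, quencher_conc = q, intensity = f,
    f0 = spec$f0, label = label
  )
}

# save/restore the global RNG state so generation does not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full temperature series of titrations
#'
#' One [generate_titration()] call per spec temperature, shared label.
#'
#' @param spec A `simulation_spec`.
#' @param label Condition tag.
#' @return List of `titration_series`, one per temperature.
#' @export
generate_temperature_series <- function(spec, label = "blank") {
  lapply(spec$temperatures, function(tt) {
    generate_titration(spec, tt, label = label)
  })
}

#' Generate a free/bound pair of Gaussian spectral bands
#'
#' The free spectrum is a unit-amplitude Gaussian at `center_free`; the
#' bound spectrum is shifted by `shift` and scaled by
#' `1 - quench_fraction`.  Used to emulate synchronous-fluorescence red
#' shifts (a few nm) and infrared amide-band displacements (tens of cm^-1).
#'
#' @param center_free Band centre of the free species, axis units.
#' @param shift Signed displacement of the bound band.
#' @param width Gaussian standard deviation (> 0), axis units.
#' @param quench_fraction Amplitude loss of the bound band, in \[0, 1\].
#' @param grid Numeric axis; must cover both centres +/- 3 widths.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm1"`.
#' @return List with elements `free` and `bound`, both `spectrum`.
#' @export
generate_spectrum_pair <- function(center_free, shift, width, quench_fraction,
                                   grid,
                                   axis_kind = c("wavelength_nm", "wavenumber_cm1")) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(width > 0, quench_fraction >= 0, quench_fraction <= 1,
            is.numeric(grid), length(grid) >= 5L)
  centers <- c(center_free, center_free + shift)
  if (min(grid) > min(centers) - 3 * width ||
      max(grid) < max(centers) + 3 * width) {
    stop("grid must cover both band centres +/- 3 widths")
  }
  gauss <- function(center, amp) amp * exp(-(grid - center)^2 / (2 * width^2))
  list(
    free = spectrum(grid, gauss(center_free, 1), axis_kind = axis_kind),
    bound = spectrum(grid, gauss(center_free + shift, 1 - quench_fraction),
                     axis_kind = axis_kind)
  )
}

#' Generate a competition dataset (blank plus scaled-Ka conditions)
#'
#' The blank series uses the spec's own Ka(T); each named condition uses
#' `Ka(T) * ratio`, emulating a site marker or ion that weakens
#' (ratio < 1) or strengthens (ratio > 1) the apparent binding.  Every
#' series draws its noise from its own substream of the master seed.
#'
#' @param spec A `simulation_spec`.
#' @param ratio_map Named numeric vector of positive Ka ratios, e.g.
#'   `c(diazepam = 0.19, indomethacin = 1.2)`.  May be empty (blank only).
#' @param temperature_K Temperature of the competition assay; defaults to
#'   the first spec temperature.
#' @return List of `titration_series`: the blank first, then one per
#'   condition in `ratio_map` order.
#' @export
generate_competition_dataset <- function(spec, ratio_map = numeric(0),
                                         temperature_K = spec$temperatures[1L]) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (length(ratio_map)) {
    stopifnot(!is.null(names(ratio_map)), all(ratio_map > 0))
  }
  out <- list(generate_titration(spec, temperature_K, label = "blank"))
  for (cond in names(ratio_map)) {
    out[[length(out) + 1L]] <- generate_titration(
      spec, temperature_K, label = cond, ka_scale = ratio_map[[cond]]
    )
  }
  out
}
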