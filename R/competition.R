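#' Compare binding constants across conditions against a blank
#'
#' For each condition (a site probe, a metal ion, ...) the ratio of its
#' binding constant to the blank's is computed and classified: `unchanged`
#' if `|1 - ratio| <= significance_ratio_threshold` (boundary inclusive),
#' else `decrease` or `increase` by the sign.  All determinations must be
#' at the same temperature.
#'
#' @param blank A `binding_result` for the ligand-protein pair alone.
#' @param conditions List of `binding_result`, one per competing condition.
#' @param config An `analysis_config`; supplies the ratio threshold.
#' @return List of `competition_result`: `condition`, `log10_ka`, `ka`,
#'   `ka_ratio_to_blank`, `effect`, `n_sites`, `r`.
#' @export
compare_conditions <- function(blank, conditions, config = analysis_config()) {
  stopifnot(inherits(blank, "binding_result"), is.list(conditions),
            inherits(config, "analysis_config"))
  if (inherits(conditions, "binding_result")) conditions <- list(conditions)
  temps <- vapply(conditions, `[[`, numeric(1L), "temperature_K")
  if (any(temps != blank$temperature_K)) {
    stop("all conditions must be at the blank's temperature (",
         blank$temperature_K, " K)")
  }
  thr <- config$significance_ratio_threshold
  lapply(conditions, function(cond) {
    # ratio via the log difference: exact, and identical to ka/ka_blank
    ratio <- 10^(cond$log10_ka - blank$log10_ka)
    effect <- if (abs(1 - ratio) <= thr) {
      "unchanged"
    } else if (ratio < 1) {
      "decrease"
    } else {
      "increase"
    }
    structure(
      list(condition = cond$label, log10_ka = cond$log10_ka, ka = cond$ka,
           ka_ratio_to_blank = ratio, effect = effect,
           n_sites = cond$n_sites, r = cond$fit$r),
      class = "competition_result"
    )
  })
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("<competition_result> %s: Ka ratio %.3f -> %s\n",
              x$condition, x$ka_ratio_to_blank, x$effect))
  invisible(x)
}

#' Assign the preferential binding site from probe displacement
#'
#' Serum albumin carries two principal drug pockets, Sudlow site I
#' (subdomain IIA; warfarin, indomethacin) and site II (subdomain IIIA;
#' diazepam, ibuprofen).  A ligand bound in one pocket is displaced by that
#' pocket's marker: its apparent Ka drops.  The site is assigned when
#' probes of exactly one site show a `decrease`; any other pattern (both,
#' neither) is ambiguous.
#'
#' @param results List of `competition_result` from [compare_conditions()].
#' @param probe_site_map Named character vector mapping condition labels to
#'   `"site_I"` / `"site_II"`.
#' @return A `site_assignment`: `site` (`"site_I"`, `"site_II"` or
#'   `"ambiguous"`) and `displacing_probe` (labels showing displacement).
#' @export
assign_site <- function(results, probe_site_map) {
  stopifnot(is.list(results))
  if (length(probe_site_map) == 0L || is.null(names(probe_site_map))) {
    stop("probe_site_map must be a non-empty named vector")
  }
  conds <- vapply(results, `[[`, character(1L), "condition")
  effects <- vapply(results, `[[`, character(1L), "effect")
  mapped <- conds %in% names(probe_site_map)
  sites <- probe_site_map[conds[mapped]]
  dec <- effects[mapped] == "decrease"
  dec_sites <- unique(sites[dec])
  site <- if (length(dec_sites) == 1L && dec_sites %in% c("site_I", "site_II")) {
    dec_sites
  } else {
    "ambiguous"
  }
  structure(
    list(site = unname(site),
         displacing_probe = if (any(dec)) conds[mapped][dec] else character(0L)),
    class = "site_assignment"
  )
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment> %s%s\n", x$site,
              if (length(x$displacing_probe)) {
                paste0(" (displaced by ", paste(x$displacing_probe, collapse = ", "), ")")
              } else ""))
  invisible(x)
}

#' Common-ion effect on the binding constant
#'
#' Same machinery as [compare_conditions()]: each ion condition's Ka is
#' ratioed to the blank and classified as increase / decrease / unchanged.
#' Provided as its own entry point because ion effects are reported per ion
#' rather than folded into a site assignment.
#'
#' @inheritParams compare_conditions
#' @param ion_conditions List of `binding_result`, one per ion.
#' @return List of `competition_result`.
#' @export
ion_effect <- function(blank, ion_conditions, config = analysis_config()) {
  compare_conditions(blank, ion_conditions, config)
}
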