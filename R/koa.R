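# Thermodynamic layer: log K_OA from the solvation free energy, and the
# aggregation-corrected apparent log K_OA built from a census.

#' log K_OA from the gas-to-octanol solvation free energy
#'
#' `log K_OA = -Delta-G_OA / (2.303 R T)` with R = 8.314 J mol^-1 K^-1. The
#' decadic conversion constant 2.303 is used literally (not ln 10 to full
#' precision); the difference is below 0.01%.
#'
#' @param dg_oa solvation free energy gas -> n-octanol, kJ/mol (favorable
#'   transfer negative).
#' @param temperature absolute temperature, K.
#' @return dimensionless log K_OA.
#' @examples
#' logkoa_from_dg(-40, 298)  # ~7.01
#' @export
logkoa_from_dg <- function(dg_oa, temperature = 298.15) {
  if (any(temperature <= 0)) abort("'temperature' must be positive")
  -dg_oa * 1000 / (2.303 * GAS_CONSTANT_J * temperature)
}

#' Inverse of [logkoa_from_dg()]
#'
#' @param log_koa dimensionless log K_OA.
#' @inheritParams logkoa_from_dg
#' @return Delta-G_OA in kJ/mol.
#' @export
dg_from_logkoa <- function(log_koa, temperature = 298.15) {
  if (any(temperature <= 0)) abort("'temperature' must be positive")
  -log_koa * 2.303 * GAS_CONSTANT_J * temperature / 1000
}

# per-molecule Delta-G of a species_thermo entry, kJ/mol
dg_per_molecule <- function(th) if (th$per_molecule) th$dg_oa else th$dg_oa / th$size

#' Aggregation-corrected apparent log K_OA
#'
#' Combines the percent-of-molecules census of the n-octanol phase with
#' per-species solvation free energies into an apparent partition
#' coefficient. Two estimators are provided:
#'
#' * `fraction-weighted-log` (default): the molecule-fraction-weighted mean
#'   of the per-species log K_OA values, each evaluated on the per-molecule
#'   solvation free energy (an s-mer's Delta-G_OA is divided by s unless the
#'   thermo entry is flagged `per_molecule`).
#' * `monomer-fraction`: the thermodynamic aggregation correction
#'   `log K_OA,monomer - log10(f_monomer)`, i.e. the total octanol-phase
#'   burden over the gas-phase monomer concentration.
#'
#' Both values are computed and stored; `mode` selects which is reported as
#' `apparent_log_koa`.
#'
#' @param fractions named numeric vector of percentages by species (names
#'   matching the thermo entries' `species`), summing to 100 within 0.1.
#' @param thermo list of [species_thermo()] entries.
#' @param temperature absolute temperature, K.
#' @param mode `"fraction-weighted-log"` or `"monomer-fraction"`.
#' @param chemical_id optional label carried into the estimate.
#' @return object of class `koa_estimate`: `apparent_log_koa`, `mode`,
#'   `by_mode` (both estimates), `fractions` (as unit fractions),
#'   `per_species_logkoa`, `temperature`, `chemical_id`.
#' @examples
#' th <- list(species_thermo("monomer", -41.0),
#'            species_thermo("dimer", -90.0))
#' apparent_logkoa(c(monomer = 86.9, dimer = 13.1), th)
#' @export
apparent_logkoa <- function(fractions, thermo, temperature = 298.15,
                            mode = c("fraction-weighted-log", "monomer-fraction"),
                            chemical_id = NA_character_) {
  mode <- match.arg(mode)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    abort("'fractions' must be named by species")
  fractions <- fractions[fractions > 0]
  if (abs(sum(fractions) - 100) > 0.1)
    abort("species percentages must sum to 100 (got %.2f)", sum(fractions))
  th_names <- vapply(thermo, `[[`, character(1), "species")
  missing <- setdiff(names(fractions), th_names)
  if (length(missing))
    abort("no solvation free energy supplied for species: %s",
          paste(missing, collapse = ", "))
  f <- fractions / sum(fractions)  # unit fractions
  logk <- vapply(names(f), function(s) {
    th <- thermo[[match(s, th_names)]]
    logkoa_from_dg(dg_per_molecule(th), temperature)
  }, numeric(1))
  weighted <- sum(f * logk)
  monomer_mode <- if ("monomer" %in% names(f)) {
    logk[["monomer"]] - log10(f[["monomer"]])
  } else {
    NA_real_
  }
  by_mode <- c(`fraction-weighted-log` = weighted,
               `monomer-fraction` = monomer_mode)
  structure(list(chemical_id = chemical_id,
                 apparent_log_koa = unname(by_mode[[mode]]),
                 mode = mode, by_mode = by_mode,
                 fractions = f, per_species_logkoa = logk,
                 temperature = temperature),
            class = "koa_estimate")
}

#' @export
print.koa_estimate <- function(x, ...) {
  cat(sprintf("<koa_estimate>%s apparent log K_OA = %.2f (%s mode, T = %g K)\n",
              if (is.na(x$chemical_id)) "" else paste0(" ", x$chemical_id),
              x$apparent_log_koa, x$mode, x$temperature))
  for (s in names(x$fractions))
    cat(sprintf("  %-8s f = %.3f, log K_OA = %.2f\n",
                s, x$fractions[[s]], x$per_species_logkoa[[s]]))
  invisible(x)
}

#' Apparent log K_OA along a concentration series
#'
#' One estimate per concentration row. When the dimer's per-molecule
#' solvation free energy is more favorable than the monomer's, the apparent
#' log K_OA must not increase as concentration decreases; a violation of that
#' expectation is flagged.
#'
#' @param profile data.frame sorted by decreasing `concentration` (mol/L)
#'   with species percentage columns (`monomer`, `dimer`, ...).
#' @param thermo list of [species_thermo()] entries.
#' @param temperature absolute temperature, K.
#' @param mode estimator mode, see [apparent_logkoa()].
#' @param chemical_id optional label.
#' @return data.frame (`concentration`, `apparent_log_koa`); attributes
#'   `estimates` (the `koa_estimate` objects) and `trend_violation` (logical,
#'   `NA` when the monotonicity expectation does not apply).
#' @export
concentration_profile <- function(profile, thermo, temperature = 298.15,
                                  mode = c("fraction-weighted-log", "monomer-fraction"),
                                  chemical_id = NA_character_) {
  mode <- match.arg(mode)
  if (!nrow(profile)) abort("empty concentration table")
  if (is.unsorted(rev(profile$concentration)))
    abort("concentration rows must be sorted by decreasing concentration")
  species_cols <- intersect(c(CENSUS_SPECIES,
                              vapply(thermo, `[[`, character(1), "species")),
                            names(profile))
  ests <- lapply(seq_len(nrow(profile)), function(i) {
    f <- unlist(profile[i, species_cols, drop = FALSE])
    apparent_logkoa(f, thermo, temperature, mode, chemical_id)
  })
  vals <- vapply(ests, `[[`, numeric(1), "apparent_log_koa")
  out <- data.frame(concentration = profile$concentration,
                    apparent_log_koa = vals)
  th_names <- vapply(thermo, `[[`, character(1), "species")
  violation <- NA
  if (all(c("monomer", "dimer") %in% th_names) && nrow(profile) > 1L) {
    dg1 <- dg_per_molecule(thermo[[match("monomer", th_names)]])
    dg2 <- dg_per_molecule(thermo[[match("dimer", th_names)]])
    if (dg2 < dg1)  # dimer more favorable: values must not rise on dilution
      violation <- any(diff(vals) > 1e-9)
  }
  attr(out, "estimates") <- ests
  attr(out, "trend_violation") <- violation
  if (isTRUE(violation))
    warning("apparent log K_OA increases on dilution despite a more favorable dimer",
            call. = FALSE)
  out
}
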