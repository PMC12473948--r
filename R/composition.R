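# Concentration <-> molecule-count arithmetic that defines the simulation box
# compositions and the dilution series used in the concentration study.

#' Apparent saturated solubility in n-octanol from S_W and K_OW
#'
#' At distribution equilibrium K_OW = C_O/C_W = S_O/S_W, so the apparent
#' saturated concentration in the n-octanol phase is `s_w * 10^log_kow`.
#'
#' @param s_w saturated water solubility, mol/L (> 0).
#' @param log_kow decadic log of the n-octanol--water partition coefficient.
#' @return S_O in mol/L.
#' @examples
#' saturated_octanol_solubility(1.91e-6, 4.90)  # ~0.151 mol/L
#' @export
saturated_octanol_solubility <- function(s_w, log_kow) {
  if (!is.numeric(s_w) || any(is.na(s_w)) || any(s_w <= 0))
    abort("'s_w' must be positive")
  s_w * 10^log_kow
}

#' Solute molecule count for a box of n-octanol
#'
#' Converts a molar concentration into the number of solute molecules to
#' dissolve among `n_octanol` solvent molecules, assuming ideal dilution
#' (the solute does not change the solvent volume): the mole ratio equals the
#' concentration over the molarity of pure n-octanol. The count is rounded
#' half-up to the nearest integer.
#'
#' @param concentration solute concentration, mol/L (>= 0).
#' @param n_octanol number of n-octanol molecules (> 0).
#' @param octanol_molarity molarity of the pure solvent, mol/L; the default
#'   6.344 corresponds to density 0.8262 g/cm^3 and molar mass 130.23 g/mol.
#' @return integer molecule count.
#' @examples
#' molecule_count(1.51e-1, 1000)  # 24
#' molecule_count(9.67e-2, 4000)  # 61
#' @export
molecule_count <- function(concentration, n_octanol,
                           octanol_molarity = OCTANOL_MOLARITY) {
  if (!is.numeric(concentration) || any(is.na(concentration)) || any(concentration < 0))
    abort("'concentration' must be >= 0")
  if (!is.numeric(n_octanol) || any(n_octanol <= 0))
    abort("'n_octanol' must be positive")
  if (!is.numeric(octanol_molarity) || any(octanol_molarity <= 0))
    abort("'octanol_molarity' must be positive")
  as.integer(round_half_up(concentration / octanol_molarity * n_octanol))
}

#' Dilution series of a saturated solution
#'
#' Divides a saturation concentration by each divisor (e.g. 1, 2, 4, 8, 16,
#' 32 for the saturation down to one-thirty-second series). Full precision is
#' retained in `concentration`; `display` carries the half-up 3-decimal
#' rounding used in reports.
#'
#' @param s_o saturation concentration, mol/L.
#' @param fractions numeric divisors, each >= 1.
#' @return data.frame with columns `divisor`, `concentration`, `display`.
#' @examples
#' dilution_series(1.51e-1, c(1, 2, 4, 8, 16, 32))
#' @export
dilution_series <- function(s_o, fractions = c(1, 2, 4, 8, 16, 32)) {
  if (!is.numeric(s_o) || length(s_o) != 1L || is.na(s_o) || s_o < 0)
    abort("'s_o' must be a nonnegative number")
  if (!is.numeric(fractions) || any(is.na(fractions)) || any(fractions <= 0))
    abort("dilution divisors must be positive")
  if (any(fractions < 1)) abort("dilution divisors must be >= 1")
  conc <- s_o / fractions
  data.frame(divisor = fractions, concentration = conc,
             display = round_half_up(conc, 3))
}

#' Box composition for one chemical
#'
#' Combines [saturated_octanol_solubility()] and [molecule_count()] into the
#' n(chemical):n(n-octanol) composition of a simulation box at a given
#' fraction of saturation.
#'
#' @param record a [chemical_record()].
#' @param n_octanol number of solvent molecules (default 1000).
#' @param divisor saturation divisor (1 = saturated).
#' @param octanol_molarity see [molecule_count()].
#' @return data.frame row: `chemical_id`, `s_o`, `concentration`, `n_solute`,
#'   `n_octanol`.
#' @export
box_composition <- function(record, n_octanol = 1000, divisor = 1,
                            octanol_molarity = OCTANOL_MOLARITY) {
  s_o <- saturated_octanol_solubility(record$s_w, record$log_kow)
  conc <- s_o / divisor
  data.frame(chemical_id = record$id, s_o = s_o, concentration = conc,
             n_solute = molecule_count(conc, n_octanol, octanol_molarity),
             n_octanol = as.integer(n_octanol),
             stringsAsFactors = FALSE)
}

#' Composition manifest for a registry of chemicals
#'
#' One [box_composition()] row per chemical; the saturated 1000-octanol
#' manifest reproduces the published maximal-molecule-number table.
#'
#' @param registry a `chem_registry` from [load_chemicals()].
#' @inheritParams box_composition
#' @param path optional TSV output path.
#' @return data.frame, invisibly written to `path` when given.
#' @export
composition_manifest <- function(registry, n_octanol = 1000, divisor = 1,
                                 octanol_molarity = OCTANOL_MOLARITY,
                                 path = NULL) {
  out <- do.call(rbind, lapply(unclass(registry), box_composition,
                               n_octanol = n_octanol, divisor = divisor,
                               octanol_molarity = octanol_molarity))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
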