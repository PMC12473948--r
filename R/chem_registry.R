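# Registry of pollutant physicochemical records and per-species thermodynamic
# input. The shipped fixture (inst/extdata/chemicals.yaml) carries the five
# study chemicals: PCB-4, phenanthrene, PBDE-28, PCN-5 and PCDD-1.

CHEM_REQUIRED <- c("id", "s_w", "log_kow")
CHEM_OPTIONAL <- c("name", "molar_mass", "exp_log_koa", "n_aromatic_rings", "s_o_reported")

#' A single pollutant's physicochemical record
#'
#' @param id short chemical name, e.g. `"PCB-4"`.
#' @param s_w saturated water solubility, mol/L; must be positive.
#' @param log_kow decadic log of the n-octanol--water partition coefficient.
#' @param molar_mass molar mass, g/mol (optional).
#' @param exp_log_koa numeric vector of experimental log K_OA determinations
#'   (optional; required for [average_experimental_logkoa()]).
#' @param n_aromatic_rings number of aromatic rings (>= 1).
#' @param name free-text chemical name (optional).
#' @param s_o_reported literature value of the apparent saturated n-octanol
#'   solubility, mol/L (optional; kept alongside the value recomputed from
#'   `s_w` and `log_kow`).
#' @return an object of class `chemical_record`.
#' @seealso [load_chemicals()], [saturated_octanol_solubility()]
#' @export
chemical_record <- function(id, s_w, log_kow, molar_mass = NA_real_,
                            exp_log_koa = numeric(), n_aromatic_rings = NA_integer_,
                            name = NA_character_, s_o_reported = NA_real_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    abort("chemical record: 'id' must be a non-empty string")
  if (!is.numeric(s_w) || length(s_w) != 1L || is.na(s_w) || s_w <= 0)
    abort("chemical record '%s': 's_w' must be a positive number", id)
  if (!is.numeric(log_kow) || length(log_kow) != 1L || is.na(log_kow))
    abort("chemical record '%s': 'log_kow' must be a number", id)
  if (length(exp_log_koa) && !is.numeric(exp_log_koa))
    abort("chemical record '%s': 'exp_log_koa' must be numeric", id)
  if (!is.na(n_aromatic_rings) && n_aromatic_rings < 1)
    abort("chemical record '%s': 'n_aromatic_rings' must be >= 1", id)
  structure(
    list(id = id, s_w = s_w, log_kow = log_kow, molar_mass = as.numeric(molar_mass),
         exp_log_koa = as.numeric(exp_log_koa),
         n_aromatic_rings = as.integer(n_aromatic_rings),
         name = name, s_o_reported = as.numeric(s_o_reported)),
    class = "chemical_record"
  )
}

#' @export
print.chemical_record <- function(x, ...) {
  cat(sprintf("<chemical_record> %s  S_W = %.3g mol/L  log K_OW = %.2f\n",
              x$id, x$s_w, x$log_kow))
  if (length(x$exp_log_koa))
    cat(sprintf("  experimental log K_OA: %s\n", paste(x$exp_log_koa, collapse = ", ")))
  invisible(x)
}

#' Load the chemicals registry from a structured config
#'
#' Reads a YAML file with a top-level `chemicals:` list, validates each record
#' and returns them keyed by id. Unknown fields are dropped with a warning.
#' The packaged fixture mirrors the published property and experimental
#' log K_OA tables column for column.
#'
#' @param source path to a YAML file, or an already-parsed list with a
#'   `chemicals` element. Defaults to the packaged fixture.
#' @return a named list of [chemical_record()] objects, class `chem_registry`.
#' @examples
#' reg <- load_chemicals()
#' reg[["PCB-4"]]$s_w
#' @export
load_chemicals <- function(source = system.file("extdata", "chemicals.yaml",
                                                package = "octaggr")) {
  cfg <- if (is.character(source)) {
    if (!file.exists(source)) abort("chemicals config not found: %s", source)
    yaml::read_yaml(source)
  } else {
    source
  }
  recs <- cfg$chemicals %||% list()
  out <- list()
  for (rec in recs) {
    miss <- setdiff(CHEM_REQUIRED, names(rec))
    if (length(miss))
      abort("chemical record '%s': missing mandatory field(s) %s",
            rec$id %||% "<unnamed>", paste(miss, collapse = ", "))
    unknown <- setdiff(names(rec), c(CHEM_REQUIRED, CHEM_OPTIONAL))
    if (length(unknown)) {
      warning(sprintf("chemical record '%s': ignoring unknown field(s) %s",
                      rec$id, paste(unknown, collapse = ", ")), call. = FALSE)
      rec <- rec[setdiff(names(rec), unknown)]
    }
    out[[rec$id]] <- chemical_record(
      id = rec$id, s_w = rec$s_w, log_kow = rec$log_kow,
      molar_mass = rec$molar_mass %||% NA_real_,
      exp_log_koa = unlist(rec$exp_log_koa) %||% numeric(),
      n_aromatic_rings = rec$n_aromatic_rings %||% NA_integer_,
      name = rec$name %||% NA_character_,
      s_o_reported = rec$s_o_reported %||% NA_real_
    )
  }
  structure(out, class = "chem_registry")
}

#' @export
print.chem_registry <- function(x, ...) {
  cat(sprintf("<chem_registry> %d chemical(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.chem_registry <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(r) {
    data.frame(id = r$id, s_w = r$s_w, log_kow = r$log_kow,
               molar_mass = r$molar_mass,
               n_exp_log_koa = length(r$exp_log_koa),
               n_aromatic_rings = r$n_aromatic_rings,
               s_o_reported = r$s_o_reported,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize a chemicals registry back to YAML
#'
#' Inverse of [load_chemicals()]: the written file re-loads to an identical
#' registry.
#'
#' @param registry a `chem_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chemicals <- function(registry, path) {
  recs <- lapply(unclass(registry), function(r) {
    out <- list(id = r$id, s_w = r$s_w, log_kow = r$log_kow)
    if (!is.na(r$molar_mass)) out$molar_mass <- r$molar_mass
    if (length(r$exp_log_koa)) out$exp_log_koa <- as.list(r$exp_log_koa)
    if (!is.na(r$n_aromatic_rings)) out$n_aromatic_rings <- r$n_aromatic_rings
    if (!is.na(r$name)) out$name <- r$name
    if (!is.na(r$s_o_reported)) out$s_o_reported <- r$s_o_reported
    out
  })
  yaml::write_yaml(list(chemicals = unname(recs)), path, precision = 12)
  invisible(path)
}

#' Average of experimental log K_OA determinations
#'
#' When several experimental log K_OA values are reported for a chemical, the
#' arithmetic mean is taken as the representative experimental value, rounded
#' half-up to two decimals.
#'
#' @param record a [chemical_record()] with a non-empty `exp_log_koa`.
#' @return the mean, rounded to 2 decimals.
#' @examples
#' r <- chemical_record("Phenanthrene", 6.03e-6, 4.57,
#'                      exp_log_koa = c(7.45, 7.57, 7.88, 7.68))
#' average_experimental_logkoa(r)  # 7.65
#' @export
average_experimental_logkoa <- function(record) {
  vals <- if (inherits(record, "chemical_record")) record$exp_log_koa else record
  if (!length(vals))
    abort("no experimental log K_OA values to average%s",
          if (inherits(record, "chemical_record")) sprintf(" for '%s'", record$id) else "")
  round_half_up(mean(vals), 2)
}

#' Per-species solvation thermodynamics
#'
#' Holds the Gibbs free energy of solvation from the gas phase to n-octanol
#' (Delta-G_OA) for one aggregate species (monomer, dimer, trimer, ...).
#' Favorable transfer into octanol is negative. Values may be supplied in
#' kJ/mol or kcal/mol; internally everything is canonicalized to kJ/mol.
#'
#' @param species species label: `"monomer"`, `"dimer"`, `"trimer"`, or
#'   `"k-mer"` for any k.
#' @param dg_oa solvation free energy, in `unit`.
#' @param unit `"kJ/mol"` (default) or `"kcal/mol"`.
#' @param per_molecule if `TRUE`, `dg_oa` is already per constituent molecule;
#'   otherwise it is for the whole aggregate and estimators divide by the
#'   aggregate size.
#' @param size aggregate size; inferred from `species` when omitted.
#' @return an object of class `species_thermo` with `dg_oa` in kJ/mol.
#' @export
species_thermo <- function(species, dg_oa, unit = c("kJ/mol", "kcal/mol"),
                           per_molecule = FALSE, size = NULL) {
  unit <- match.arg(unit)
  if (is.null(size)) {
    size <- switch(species, monomer = 1L, dimer = 2L, trimer = 3L,
                   {
                     m <- regmatches(species, regexec("^([0-9]+)-mer$", species))[[1]]
                     if (length(m) == 2L) as.integer(m[2]) else
                       abort("cannot infer aggregate size from species '%s'; give 'size'", species)
                   })
  }
  size <- as.integer(size)
  if (size < 1L) abort("species_thermo: aggregate size must be >= 1")
  if (!is.numeric(dg_oa) || length(dg_oa) != 1L || is.na(dg_oa))
    abort("species_thermo: 'dg_oa' must be a number")
  dg_kj <- if (unit == "kcal/mol") dg_oa * KCAL_TO_KJ else dg_oa
  structure(list(species = species, size = size, dg_oa = dg_kj,
                 per_molecule = isTRUE(per_molecule)),
            class = "species_thermo")
}

#' @export
print.species_thermo <- function(x, ...) {
  cat(sprintf("<species_thermo> %s (size %d): Delta-G_OA = %.3f kJ/mol%s\n",
              x$species, x$size, x$dg_oa,
              if (x$per_molecule) " (per molecule)" else ""))
  invisible(x)
}
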