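# Readers and writers for the three supported coordinate formats: multi-frame
# XYZ (comment line carries time and box), GRO (fixed column, nm) and PDB
# (MODEL/ENDMDL with CRYST1 boxes). Internal unit is Angstrom; GRO's nm are
# converted at the boundary. Molecule grouping is always supplied explicitly
# (block-based for XYZ, residue-based for GRO/PDB, or fully explicit) rather
# than inferred by bond perception.

# ---- grouping specs ---------------------------------------------------------

load_grouping <- function(grouping) {
  if (is.character(grouping)) {
    if (!file.exists(grouping)) abort("grouping spec not found: %s", grouping)
    grouping <- yaml::read_yaml(grouping)
  }
  if (!is.list(grouping)) abort("grouping spec must be a list or a YAML path")
  grouping
}

# Build a mol_topology from a grouping spec plus parsed file metadata.
# `residues`: data.frame(resid, resname) per atom for GRO/PDB, else NULL.
resolve_grouping <- function(grouping, n_atoms, elements = NULL, residues = NULL) {
  g <- load_grouping(grouping)
  mode <- g$mode %||% {
    if (!is.null(g$molecules)) "explicit"
    else if (!is.null(g$atoms_per_molecule)) "block"
    else if (!is.null(residues)) "residue"
    else abort("cannot infer grouping mode; give 'mode'")
  }
  mols <- switch(mode,
    explicit = lapply(g$molecules, function(m) {
      list(id = m$id %||% NULL, atoms = as.integer(unlist(m$atoms)),
           elements = unlist(m$elements) %||% NULL,
           rings = lapply(m$rings %||% list(), function(r) as.integer(unlist(r))))
    }),
    block = {
      apm <- as.integer(g$atoms_per_molecule)
      if (apm < 1L) abort("grouping: atoms_per_molecule must be >= 1")
      n_mol <- as.integer(g$n_molecules %||% (n_atoms %/% apm))
      if (n_mol < 1L) abort("grouping: no molecules defined")
      rings_local <- lapply(g$rings %||% list(), function(r) as.integer(unlist(r)))
      lapply(seq_len(n_mol), function(i) {
        atoms <- ((i - 1L) * apm + 1L):(i * apm)
        list(id = sprintf("mol%d", i), atoms = atoms,
             elements = if (!is.null(g$elements)) unlist(g$elements) else NULL,
             rings = lapply(rings_local, function(r) atoms[r]))
      })
    },
    residue = {
      if (is.null(residues))
        abort("residue grouping requires a format that carries residue records")
      keep <- g$include %||% unique(residues$resname)
      idx <- which(residues$resname %in% keep)
      if (!length(idx)) abort("grouping: no atoms match include = %s",
                              paste(keep, collapse = ", "))
      by_res <- split(idx, residues$resid[idx])
      ring_spec <- g$rings %||% list()
      named_rings <- length(ring_spec) && !is.null(names(ring_spec))
      lapply(names(by_res), function(rid) {
        atoms <- sort(by_res[[rid]])
        rn <- residues$resname[atoms[1]]
        local <- if (named_rings) ring_spec[[rn]] %||% list() else ring_spec
        rings <- lapply(local, function(r) {
          r <- as.integer(unlist(r))
          if (any(r < 1L | r > length(atoms)))
            abort("grouping: ring index out of range for residue %s%s", rn, rid)
          atoms[r]
        })
        list(id = sprintf("%s%s", rn, rid), atoms = atoms, rings = rings)
      })
    },
    abort("unknown grouping mode '%s'", mode)
  )
  all_atoms <- unlist(lapply(mols, `[[`, "atoms"))
  if (any(all_atoms < 1L) || any(all_atoms > n_atoms))
    abort("grouping references atom indices outside 1..%d", n_atoms)
  if (!is.null(elements)) {
    for (i in seq_along(mols))
      if (is.null(mols[[i]]$elements))
        mols[[i]]$elements <- elements[mols[[i]]$atoms]
  }
  mol_topology(mols)
}

# ---- XYZ --------------------------------------------------------------------

parse_xyz <- function(lines, path) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      abort("%s:%d: expected an atom count, got '%s'", path, i, lines[i])
    if (i + 1L + n > length(lines))
      abort("%s:%d: truncated frame (%d atoms declared)", path, i, n)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time=\\s*([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment, regexec(
      "box=\\s*([-0-9.eE+]+)[, ]+([-0-9.eE+]+)[, ]+([-0-9.eE+]+)", comment))[[1]]
    if (length(bx) != 4L)
      abort("%s:%d: XYZ comment line must carry 'box=Lx,Ly,Lz'", path, i + 1L)
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else length(frames)
    box <- as.numeric(bx[2:4])
    rows <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      abort("%s:%d: malformed XYZ atom record '%s'", path, i + 1L + bad[1], rows[bad[1]])
    elements <- vapply(toks, `[[`, character(1), 1L)
    coords <- suppressWarnings(
      matrix(as.numeric(unlist(lapply(toks, function(t) t[2:4]))),
             ncol = 3, byrow = TRUE))
    if (anyNA(coords)) abort("%s: non-numeric coordinate in frame at line %d", path, i)
    frames[[length(frames) + 1L]] <-
      list(frame = traj_frame(time, box, coords), elements = elements)
    i <- i + 2L + n
  }
  if (!length(frames)) abort("%s: no frames found", path)
  frames
}

# ---- GRO --------------------------------------------------------------------

parse_gro <- function(lines, path) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1L)
      abort("%s:%d: expected an atom count, got '%s'", path, i + 1L, lines[i + 1L])
    if (i + 2L + n > length(lines)) abort("%s:%d: truncated GRO frame", path, i)
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else length(frames)
    rows <- lines[(i + 2L):(i + 1L + n)]
    num <- function(row, a, b, ln) {
      v <- suppressWarnings(as.numeric(substr(row, a, b)))
      if (is.na(v)) abort("%s:%d: malformed GRO record '%s'", path, ln, row)
      v
    }
    resid <- integer(n); resname <- character(n); atomname <- character(n)
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      row <- rows[k]; ln <- i + 1L + k
      if (nchar(row) < 44L) abort("%s:%d: GRO record too short", path, ln)
      resid[k] <- as.integer(num(row, 1, 5, ln))
      resname[k] <- trimws(substr(row, 6, 10))
      atomname[k] <- trimws(substr(row, 11, 15))
      coords[k, ] <- c(num(row, 21, 28, ln), num(row, 29, 36, ln), num(row, 37, 44, ln))
      # velocity columns (45-68), if present, are parsed and discarded
    }
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])
    if (anyNA(boxline) || !length(boxline) %in% c(3L, 9L))
      abort("%s:%d: malformed GRO box line", path, i + 2L + n)
    if (length(boxline) == 9L && any(abs(boxline[4:9]) > 1e-9))
      abort("%s:%d: triclinic boxes are not supported (orthorhombic only)",
            path, i + 2L + n)
    box <- boxline[1:3] * 10  # nm -> Angstrom
    elements <- sub("[0-9'].*$", "", atomname)
    frames[[length(frames) + 1L]] <- list(
      frame = traj_frame(time, box, coords * 10), elements = elements,
      residues = data.frame(resid = resid, resname = resname,
                            stringsAsFactors = FALSE))
    i <- i + 3L + n
  }
  if (!length(frames)) abort("%s: no frames found", path)
  frames
}

# ---- PDB --------------------------------------------------------------------

parse_pdb <- function(lines, path) {
  frames <- list()
  box <- NULL; time <- NA_real_
  cur <- NULL  # accumulating atom rows of current model
  flush_model <- function() {
    if (is.null(cur) || !nrow(cur)) return()
    if (is.null(box)) abort("%s: no CRYST1 record before coordinates", path)
    t <- if (is.na(time)) length(frames) else time
    frames[[length(frames) + 1L]] <<- list(
      frame = traj_frame(t, box, as.matrix(cur[, c("x", "y", "z")])),
      elements = cur$element,
      residues = data.frame(resid = cur$resid, resname = cur$resname,
                            stringsAsFactors = FALSE))
    cur <<- NULL; time <<- NA_real_
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (rec == "CRYST1") {
      vals <- suppressWarnings(as.numeric(c(substr(line, 7, 15), substr(line, 16, 24),
                                            substr(line, 25, 33), substr(line, 34, 40),
                                            substr(line, 41, 47), substr(line, 48, 54))))
      if (anyNA(vals)) abort("%s:%d: malformed CRYST1 record", path, ln)
      if (any(abs(vals[4:6] - 90) > 1e-6))
        abort("%s:%d: non-orthorhombic cell (angles must be 90)", path, ln)
      box <- vals[1:3]
    } else if (grepl("^REMARK", line) && grepl("TIME=", line)) {
      tm <- regmatches(line, regexec("TIME=\\s*([-0-9.eE+]+)", line))[[1]]
      if (length(tm) == 2L) time <- as.numeric(tm[2])
    } else if (substr(rec, 1, 5) == "MODEL") {
      flush_model()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38), substr(line, 39, 46),
                                           substr(line, 47, 54))))
      if (anyNA(xyz)) abort("%s:%d: malformed ATOM record", path, ln)
      el <- trimws(substr(line, 77, 78))
      if (!nzchar(el)) el <- sub("[0-9'].*$", "", trimws(substr(line, 13, 16)))
      row <- data.frame(
        x = xyz[1], y = xyz[2], z = xyz[3],
        resid = suppressWarnings(as.integer(substr(line, 23, 26))),
        resname = trimws(substr(line, 18, 20)), element = el,
        stringsAsFactors = FALSE)
      cur <- if (is.null(cur)) row else rbind(cur, row)
    } else if (rec == "ENDMDL" || rec == "END   " || trimws(rec) == "END") {
      flush_model()
    }
  }
  flush_model()
  if (!length(frames)) abort("%s: no frames found", path)
  frames
}

# ---- public API -------------------------------------------------------------

#' Read a molecular trajectory
#'
#' Parses a multi-frame coordinate file and attaches a molecule grouping.
#' Atoms not covered by the grouping (e.g. solvent residues excluded via the
#' `include` key of a residue grouping) stay in the coordinate arrays but
#' belong to no molecule and are ignored by all analyses. GRO velocity
#' columns are accepted and discarded.
#'
#' @param path input file.
#' @param format `"xyz"`, `"gro"` or `"pdb"`.
#' @param grouping grouping spec: a YAML path or list. Modes: `block`
#'   (`atoms_per_molecule`, optional `n_molecules`, `rings` as local index
#'   lists) for XYZ-style files; `residue` (optional `include` resnames,
#'   `rings` local per residue, optionally named by resname) for GRO/PDB;
#'   `explicit` (`molecules` with global `atoms`/`rings`).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("xyz", "gro", "pdb"), grouping) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("trajectory file not found: %s", path)
  lines <- readLines(path)
  parsed <- switch(format,
                   xyz = parse_xyz(lines, path),
                   gro = parse_gro(lines, path),
                   pdb = parse_pdb(lines, path))
  first <- parsed[[1]]
  topo <- resolve_grouping(grouping, n_atoms = nrow(first$frame$coords),
                           elements = first$elements,
                           residues = first$residues)
  trajectory(topo, lapply(parsed, `[[`, "frame"))
}

#' Write a molecular trajectory
#'
#' Inverse of [read_trajectory()]; coordinates round-trip to the format's
#' precision (XYZ/PDB: 0.001 A; GRO: 0.001 nm = 0.01 A).
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"xyz"`, `"gro"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "gro", "pdb")) {
  format <- match.arg(format)
  if (!inherits(traj, "trajectory")) abort("'traj' must be a trajectory")
  if (!length(traj$frames)) abort("trajectory has no frames")
  n_atoms <- max(unlist(lapply(traj$topology$molecules, `[[`, "atoms")))
  # per-atom element / molecule labels
  element <- rep("X", n_atoms); molnum <- rep(0L, n_atoms); molname <- rep("UNK", n_atoms)
  for (i in seq_along(traj$topology$molecules)) {
    m <- traj$topology$molecules[[i]]
    molnum[m$atoms] <- i
    molname[m$atoms] <- "MOL"
    element[m$atoms] <- m$elements %||% rep("C", length(m$atoms))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    xyz <- f$coords[seq_len(n_atoms), , drop = FALSE]
    if (format == "xyz") {
      writeLines(as.character(n_atoms), con)
      writeLines(sprintf("time=%.4f box=%.4f,%.4f,%.4f",
                         f$time, f$box[1], f$box[2], f$box[3]), con)
      writeLines(sprintf("%-2s %12.4f %12.4f %12.4f",
                         element, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    } else if (format == "gro") {
      writeLines(sprintf("octaggr t= %.5f", f$time), con)
      writeLines(as.character(n_atoms), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         molnum %% 100000L, molname,
                         substr(element, 1, 5), seq_len(n_atoms) %% 100000L,
                         xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f",
                         f$box[1] / 10, f$box[2] / 10, f$box[3] / 10), con)
    } else {
      writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                         f$box[1], f$box[2], f$box[3], 90, 90, 90), con)
      writeLines(sprintf("REMARK   TIME= %.4f", f$time), con)
      writeLines("MODEL", con)
      writeLines(sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         seq_len(n_atoms) %% 100000L, substr(element, 1, 4),
                         molname, "A", molnum %% 10000L,
                         xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, element), con)
      writeLines("ENDMDL", con)
    }
  }
  invisible(path)
}
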