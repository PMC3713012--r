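#' Construct a molecule in a common superposition frame
#'
#' A `Molecule` bundles an identifier, an optional one-letter sequence, an
#' atom table and a `frame_tag` labelling the superposition frame. All
#' molecules compared in one analysis must share the same `frame_tag`:
#' every downstream comparison (RMSD, grid fields, similarity) assumes the
#' structures are already superposed and never re-fits them.
#'
#' @param id molecule label, e.g. `"22"` or `"ELS"`.
#' @param atoms data frame with columns `element`, `name`, `residue_name`,
#'   `residue_index`, `chain_id`, `x`, `y`, `z` and optionally
#'   `vdw_radius`, `partial_charge` (filled by [assign_parameters()]).
#' @param sequence optional one-letter amino-acid string.
#' @param frame_tag label of the shared reference frame.
#' @return an object of class `Molecule`.
#' @export
new_molecule <- function(id, atoms, sequence = NULL, frame_tag = "frame") {
  required <- c("element", "name", "residue_name", "residue_index",
                "chain_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) > 0L && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- NA_real_
  if (!"partial_charge" %in% names(atoms)) atoms$partial_charge <- NA_real_
  atoms$is_hydrogen <- toupper(atoms$element) == "H"
  structure(
    list(id = as.character(id), sequence = sequence,
         atoms = atoms, frame_tag = frame_tag),
    class = "Molecule"
  )
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule %s: %d atoms, frame '%s'>\n",
              x$id, nrow(x$atoms), x$frame_tag))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `Molecule`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Heavy-atom coordinate matrix
#'
#' @param mol a `Molecule`.
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[!a$is_hydrogen, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

pdb_guess_element <- function(name) {
  # strip leading digits (e.g. "1HG1"), element = first letter; two-letter
  # elements are rare in peptides and resolved by the explicit PDB column
  nm <- sub("^[0-9]+", "", trimws(name))
  toupper(substr(nm, 1L, 1L))
}

parse_atom_record <- function(line, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  line <- pad(line, 80)
  xs <- substr(line, 31, 38); ys <- substr(line, 39, 46); zs <- substr(line, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  resseq <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (any(is.na(c(x, y, z))) || is.na(resseq)) {
    stop(sprintf("malformed ATOM record at line %d: '%s'",
                 lineno, trimws(line)), call. = FALSE)
  }
  element <- trimws(substr(line, 77, 78))
  name <- trimws(substr(line, 13, 16))
  if (element == "") element <- pdb_guess_element(name)
  list(
    element = element,
    name = name,
    residue_name = trimws(substr(line, 18, 20)),
    residue_index = resseq,
    chain_id = substr(line, 22, 22),
    x = x, y = y, z = z
  )
}

#' Read molecules from a PDB file
#'
#' Parses `ATOM`/`HETATM` records. Multi-entry files are split into one
#' molecule per entry on `MODEL`, `END`/`ENDMDL` or `TER`-followed-by-new-
#' molecule boundaries, so dock-style concatenated files (many peptides in
#' one PDB, one after the other) are read directly. Coordinates are taken
#' verbatim; no re-fitting is performed.
#'
#' @param path PDB file path.
#' @param model_index optional single entry to return (1-based).
#' @param frame_tag frame label stamped on all returned molecules.
#' @return list of `Molecule` objects.
#' @export
read_pdb <- function(path, model_index = NULL, frame_tag = "frame") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)

  entries <- list()
  current <- list()
  current_id <- NULL
  n_entry <- 0L
  flush <- function() {
    if (length(current) > 0L) {
      n_entry <<- n_entry + 1L
      id <- if (!is.null(current_id)) current_id else as.character(n_entry)
      atoms <- do.call(rbind, lapply(current, function(a) {
        data.frame(a, stringsAsFactors = FALSE)
      }))
      entries[[length(entries) + 1L]] <<-
        new_molecule(id, atoms, frame_tag = frame_tag)
    }
    current <<- list()
    current_id <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    rec <- toupper(substr(ln, 1, 6))
    if (startsWith(rec, "MODEL")) {
      flush()
      id <- trimws(substr(ln, 7, 80))
      if (nzchar(id)) current_id <- id
    } else if (startsWith(rec, "END")) {  # END or ENDMDL
      flush()
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      current[[length(current) + 1L]] <- parse_atom_record(ln, i)
    } else if (startsWith(rec, "COMPND") || startsWith(rec, "REMARK")) {
      nm <- regmatches(ln, regexpr("(?i)name[ :=]+\\S+", ln, perl = TRUE))
      if (length(nm) == 1L && is.null(current_id) && length(current) == 0L) {
        current_id <- sub("(?i)name[ :=]+", "", nm, perl = TRUE)
      }
    }
  }
  flush()
  if (length(entries) == 0L) stop("no ATOM/HETATM records in ", path)
  if (!is.null(model_index)) {
    if (model_index < 1L || model_index > length(entries)) {
      stop("model_index out of range (file has ", length(entries), " entries)")
    }
    return(entries[model_index])
  }
  entries
}

#' Write molecules to a PDB file
#'
#' Entries are separated by `MODEL`/`ENDMDL` records carrying the molecule
#' id; coordinates are written with 3 decimals (PDB precision).
#'
#' @param mols a `Molecule` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    out <- c(out, sprintf("MODEL %s", mol$id))
    a <- mol$atoms
    for (i in seq_len(nrow(a))) {
      nm <- a$name[i]
      nm_field <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      out <- c(out, sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, nm_field, a$residue_name[i], a$chain_id[i], a$residue_index[i],
        a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]))
    }
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Built-in atomic parameter table
#'
#' Self-contained van der Waals radius / partial charge table. Radii are
#' element-based (Bondi-type values); charges default to zero unless a
#' residue- and atom-specific row is supplied. This stands in for a full
#' force-field parameter set, which is configurable via
#' [read_parameter_table()] for reproduction work on real structures.
#'
#' @return a `ParameterTable` (list with `rows` and `element_defaults`).
#' @export
default_parameter_table <- function() {
  structure(
    list(
      rows = data.frame(residue_name = character(0), atom_name = character(0),
                        radius = numeric(0), charge = numeric(0),
                        stringsAsFactors = FALSE),
      element_defaults = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                           S = 1.80, P = 1.80),
      fallback_radius = 1.70
    ),
    class = "ParameterTable"
  )
}

#' Read an atomic parameter table from CSV
#'
#' Expected columns: `residue_name`, `atom_name`, `radius`, `charge`.
#'
#' @param path CSV file.
#' @return a `ParameterTable`.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "radius", "charge")
  if (!all(need %in% names(df))) {
    stop("parameter CSV needs columns: ", paste(need, collapse = ", "))
  }
  tbl <- default_parameter_table()
  tbl$rows <- df[, need]
  tbl
}

#' Assign van der Waals radii and partial charges to a molecule
#'
#' Atoms are matched on (residue_name, atom_name); unmatched atoms fall
#' back to the element-default radius and zero charge, with a warning
#' counting the defaults. Every atom always ends up with a radius.
#'
#' @param mol a `Molecule`.
#' @param table a `ParameterTable` (default [default_parameter_table()]).
#' @return the molecule with `vdw_radius`/`partial_charge` filled in;
#'   attribute `n_defaulted` counts atoms that used element defaults.
#' @export
assign_parameters <- function(mol, table = default_parameter_table()) {
  a <- mol$atoms
  n_def <- 0L
  if (nrow(a) > 0L) {
    key <- paste(a$residue_name, a$name, sep = "|")
    tkey <- paste(table$rows$residue_name, table$rows$atom_name, sep = "|")
    idx <- match(key, tkey)
    hit <- !is.na(idx)
    a$vdw_radius[hit] <- table$rows$radius[idx[hit]]
    a$partial_charge[hit] <- table$rows$charge[idx[hit]]
    if (any(!hit)) {
      el <- toupper(a$element[!hit])
      r <- unname(table$element_defaults[el])
      r[is.na(r)] <- table$fallback_radius
      a$vdw_radius[!hit] <- r
      a$partial_charge[!hit] <- 0
      n_def <- sum(!hit)
      # charge-carrying tables are the exception in the synthetic track,
      # so only warn when a table with explicit rows failed to cover
      if (nrow(table$rows) > 0L) {
        warning(sprintf("%d atom(s) of molecule %s fell back to element defaults",
                        n_def, mol$id))
      }
    }
  }
  mol$atoms <- a
  attr(mol, "n_defaulted") <- n_def
  mol
}

backbone_names <- c("N", "CA", "C", "O")

select_atoms <- function(mol, selection, exclude_residues = NULL,
                         include_atoms = NULL) {
  a <- mol$atoms
  keep <- switch(selection,
    backbone = a$name %in% backbone_names,
    heavy = !a$is_hydrogen,
    all = rep(TRUE, nrow(a)),
    stop("unknown selection: ", selection)
  )
  if (!is.null(include_atoms)) {
    extra <- paste(a$residue_index, a$name) %in%
      paste(include_atoms$residue_index, include_atoms$atom_name)
    keep <- keep | extra
  }
  if (!is.null(exclude_residues)) keep <- keep & !(a$residue_index %in% exclude_residues)
  a[keep, , drop = FALSE]
}

#' RMSD between two superposed molecules
#'
#' Root-mean-square deviation over paired atoms, computed WITHOUT
#' re-superposition: the structures are assumed to be docked in the same
#' rigid receptor frame, so applying a Kabsch fit would discard the very
#' displacement being measured. Atoms are paired by residue index plus
#' atom name.
#'
#' @param molA,molB molecules sharing a `frame_tag`.
#' @param selection `"backbone"` (N, CA, C, O), `"heavy"` (non-hydrogen)
#'   or `"all"`.
#' @param exclude_residues residue indices dropped from the selection
#'   (e.g. a substitution site).
#' @param include_atoms data frame (`residue_index`, `atom_name`) of extra
#'   atoms to include beyond the named selection (e.g. a single side-chain
#'   beta carbon).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(molA, molB, selection = c("backbone", "heavy", "all"),
                 exclude_residues = NULL, include_atoms = NULL) {
  selection <- match.arg(selection)
  if (!identical(molA$frame_tag, molB$frame_tag)) {
    stop("molecules are not in the same superposition frame")
  }
  a <- select_atoms(molA, selection, exclude_residues, include_atoms)
  b <- select_atoms(molB, selection, exclude_residues, include_atoms)
  ka <- paste(a$residue_index, a$name)
  kb <- paste(b$residue_index, b$name)
  idx <- match(ka, kb)
  if (any(is.na(idx)) || length(ka) != length(kb)) {
    missing <- unique(c(setdiff(ka, kb), setdiff(kb, ka)))
    stop("unpairable atom selection; unmatched atoms: ",
         paste(missing, collapse = ", "))
  }
  d <- as.matrix(a[, c("x", "y", "z")]) -
       as.matrix(b[idx, c("x", "y", "z")])
  sqrt(mean(rowSums(d^2)))
}
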