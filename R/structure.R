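# Structure container: an atom table plus one coordinate matrix per frame.

#' Atomic masses for common elements
#'
#' Standard atomic weights (Da) for the elements that occur in protein,
#' nucleic-acid and common ligand/ion structures.
#' @keywords internal
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  "NA" = 22.990, CL = 35.45, K = 39.098, MN = 54.938, CU = 63.546,
  I = 126.904, F = 18.998, BR = 79.904, MO = 95.95, CO = 58.933, NI = 58.693
)

#' Assign atomic masses from element symbols
#'
#' Masses are looked up from the element symbol when present; otherwise the
#' element is inferred from the atom name (digits stripped, first character),
#' which resolves e.g. `"CA"` (alpha carbon) to carbon and `"1HB"` to
#' hydrogen. Unrecognised elements fall back to the mass of carbon with a
#' warning.
#'
#' @param elety character vector of atom names.
#' @param elesy character vector of element symbols (may be `NA`).
#' @return numeric vector of masses in Da.
#' @keywords internal
atom_masses <- function(elety, elesy = NULL) {
  sym <- toupper(trimws(if (is.null(elesy)) rep(NA_character_, length(elety)) else elesy))
  sym[!is.na(sym) & !nzchar(sym)] <- NA_character_
  miss <- is.na(sym) | !(sym %in% names(.element_masses))
  if (any(miss)) {
    guess <- toupper(gsub("[0-9']", "", elety[miss]))
    # two-letter element names in atom names are rare outside ions; try the
    # full stripped name first (FE, ZN, ...), then the first character
    g2 <- ifelse(guess %in% names(.element_masses), guess, substr(guess, 1, 1))
    sym[miss] <- g2
  }
  unknown <- !(sym %in% names(.element_masses))
  if (any(unknown)) {
    warning("unrecognised element for atom(s) ",
            paste(unique(elety[unknown]), collapse = ", "),
            "; assigning carbon mass")
    sym[unknown] <- "C"
  }
  unname(.element_masses[sym])
}

#' Construct a structure object
#'
#' A `structure3d` bundles an atom identity table with one or more coordinate
#' frames (models). All frames share the same atom list, so a multi-model PDB
#' doubles as a trajectory.
#'
#' @param atoms data frame with columns `serial`, `elety` (atom name), `elesy`
#'   (element symbol, may be `NA`), `resid` (residue name), `chain`, `resno`
#'   (residue number as printed in the PDB), `insert` (insertion code, `""` if
#'   none), `o` (occupancy), `b` (B-factor) and `mass` (Da). Missing `mass` is
#'   filled from the element.
#' @param xyz a single N x 3 matrix or a list of N x 3 matrices (one per
#'   frame), coordinates in Angstrom.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz) {
  if (is.matrix(xyz)) xyz <- list(xyz)
  stopifnot(is.list(xyz), length(xyz) >= 1L, is.data.frame(atoms))
  n <- nrow(atoms)
  for (k in seq_along(xyz)) {
    m <- xyz[[k]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n)
      stop("frame ", k, " is not an ", n, " x 3 coordinate matrix")
    if (!all(is.finite(m)))
      stop("frame ", k, " contains non-finite coordinates")
    dimnames(xyz[[k]]) <- NULL
  }
  defaults <- list(serial = seq_len(n), elesy = NA_character_,
                   resid = "ALA", chain = "A", insert = "",
                   o = 1, b = 0)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep(defaults[[nm]], length.out = n)
  if (is.null(atoms$elety)) stop("atoms must have an 'elety' (atom name) column")
  if (is.null(atoms$resno)) stop("atoms must have a 'resno' column")
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$mass)) atoms$mass <- atom_masses(atoms$elety, atoms$elesy)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  key <- atom_key(atoms)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, residue, insertion, name): ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "structure3d")
}

#' @rdname structure3d
#' @param x a `structure3d`.
#' @export
n_frames <- function(x) length(x$xyz)

#' @rdname structure3d
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Extract the coordinates of one frame
#' @param x a `structure3d`.
#' @param frame frame index (1-based).
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(x, frame = 1L) {
  if (frame < 1L || frame > n_frames(x))
    stop("frame ", frame, " out of range (structure has ", n_frames(x), ")")
  x$xyz[[frame]]
}

# identity key used for pairing and uniqueness: chain|resno|insert|atom-name
atom_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
}

# residue-level key
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", n_atoms(x), "atoms,", n_frames(x), "frame(s),",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Subset a structure to a set of atoms
#' @param x a `structure3d`.
#' @param idx increasing integer atom indices.
#' @return a `structure3d` with the selected atoms in all frames.
#' @export
subset_atoms <- function(x, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= n_atoms(x)))
  structure3d(x$atoms[idx, , drop = FALSE],
              lapply(x$xyz, function(m) m[idx, , drop = FALSE])
  )
}
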