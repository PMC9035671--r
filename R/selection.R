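# Declarative atom selections and cross-structure atom pairing.

#' Build a declarative atom selection
#'
#' Criteria combine by AND; `NULL` means "no restriction". Residue numbers may
#' be given as any integer vector (use `a:b` for ranges).
#'
#' @param chain chains to keep (character vector) or `NULL`.
#' @param resno residue numbers to keep (integer vector) or `NULL`.
#' @param elety atom names to keep, e.g. `"CA"`, or `NULL`.
#' @param heavy_only drop hydrogens (default `TRUE`; the elastic-network and
#'   contact analyses operate on heavy atoms).
#' @return an object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resno = NULL, elety = NULL,
                           heavy_only = TRUE) {
  structure(list(chain = chain, resno = resno, elety = elety,
                 heavy_only = isTRUE(heavy_only)),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection:", format_selection(x), "\n")
  invisible(x)
}

format_selection <- function(sel) {
  parts <- character(0)
  if (!is.null(sel$chain)) parts <- c(parts, paste0("chain %in% {", paste(sel$chain, collapse = ","), "}"))
  if (!is.null(sel$resno)) parts <- c(parts, paste0("resno in [", min(sel$resno), ",", max(sel$resno), "]"))
  if (!is.null(sel$elety)) parts <- c(parts, paste0("name %in% {", paste(sel$elety, collapse = ","), "}"))
  if (sel$heavy_only) parts <- c(parts, "heavy atoms only")
  if (length(parts) == 0L) "all atoms" else paste(parts, collapse = " & ")
}

is_hydrogen <- function(atoms) {
  abs(atoms$mass - .element_masses[["H"]]) < 0.5
}

#' Resolve a selection to atom indices
#'
#' @param x a [structure3d()].
#' @param selection an [atom_selection()] or `NULL` for all atoms (heavy atoms
#'   only by default).
#' @return strictly increasing integer indices into the atom table (frame-0
#'   atom order). Empty resolutions are an error.
#' @export
resolve_selection <- function(x, selection = NULL) {
  stopifnot(inherits(x, "structure3d"))
  if (is.null(selection)) selection <- atom_selection()
  stopifnot(inherits(selection, "atom_selection"))
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & a$resno %in% selection$resno
  if (!is.null(selection$elety)) keep <- keep & a$elety %in% selection$elety
  if (selection$heavy_only) keep <- keep & !is_hydrogen(a)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selection matched no atoms: ", format_selection(selection))
  idx
}

#' Pair atoms common to two structures
#'
#' Atoms are paired by (chain, residue number, insertion code, atom name)
#' identity, restricted to `selection` on each side. Atoms present in only one
#' structure are dropped, which accommodates states modelled over slightly
#' different residue sets.
#'
#' @param a,b [structure3d()] objects.
#' @param selection an [atom_selection()] applied to both sides, or `NULL`.
#' @return an `atom_pairing`: list with equal-length index vectors `idx_a`,
#'   `idx_b` and the shared identity `key`.
#' @export
pair_common_atoms <- function(a, b, selection = NULL) {
  ia <- resolve_selection(a, selection)
  ib <- resolve_selection(b, selection)
  ka <- atom_key(a$atoms)[ia]
  kb <- atom_key(b$atoms)[ib]
  common <- intersect(ka, kb)
  if (length(common) == 0L)
    stop("no atoms common to both structures under the given selection")
  ma <- ia[match(common, ka)]
  # keep frame order of structure a
  o <- order(ma)
  ma <- ma[o]
  common <- common[o]
  mb <- ib[match(common, kb)]
  structure(list(idx_a = ma, idx_b = mb, key = common),
            class = "atom_pairing")
}

#' @export
print.atom_pairing <- function(x, ...) {
  cat("atom_pairing:", length(x$idx_a), "paired atoms\n")
  invisible(x)
}
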