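# PDB reading/writing, layered on bio3d with an explicit altloc policy and
# mass assignment.

#' Read a PDB file (single- or multi-model)
#'
#' MODEL/ENDMDL blocks delimit frames; all models must list the same atoms in
#' the same order. Alternate locations are resolved by keeping, for each
#' (chain, residue, insertion, atom-name) identity, the altloc with the
#' highest occupancy (ties broken by file order). Masses are assigned from the
#' element column, falling back to the element implied by the atom name.
#' UNK residues are retained.
#'
#' @param path path to a PDB-format text file.
#' @param keep_hetatm keep HETATM records (ligands, ions, waters). Default TRUE.
#' @return a [structure3d()].
#' @export
read_pdb <- function(path, keep_hetatm = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!keep_hetatm) at$keep_type <- at$type == "ATOM"
  keep <- if (keep_hetatm) rep(TRUE, nrow(at)) else at$type == "ATOM"
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyz_mat <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  if (ncol(xyz_mat) != 3L * nrow(at))
    stop("inconsistent atom lists across MODEL blocks in '", path, "'")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0

  # altloc policy: highest occupancy wins, tie -> first occurrence in file
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  keep <- keep & seq_len(nrow(at)) %in% sel
  idx <- which(keep)
  if (length(idx) == 0L) stop("no atoms retained from '", path, "'")

  atoms <- data.frame(
    serial = at$eleno[idx], elety = at$elety[idx], elesy = at$elesy[idx],
    resid = at$resid[idx], chain = at$chain[idx], resno = at$resno[idx],
    insert = at$insert[idx], o = at$o[idx], b = at$b[idx],
    stringsAsFactors = FALSE
  )
  atoms$chain[is.na(atoms$chain)] <- " "
  frames <- lapply(seq_len(nmod), function(k) {
    m <- matrix(xyz_mat[k, ], ncol = 3L, byrow = TRUE)
    m[idx, , drop = FALSE]
  })
  structure3d(atoms, frames)
}

#' Write a structure as a PDB file
#'
#' Multi-frame structures are emitted as MODEL/ENDMDL blocks; coordinates are
#' formatted to three decimals (the PDB field precision).
#'
#' @param x a [structure3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  rng <- range(unlist(lapply(x$xyz, range)))
  if (any(abs(rng) >= 10000))
    stop("coordinate magnitude ", max(abs(rng)),
         " exceeds the PDB field width (|x| < 10000)")
  a <- x$atoms
  flat <- vapply(x$xyz, function(m) as.vector(t(m)), numeric(3L * n_atoms(x)))
  # one row per model: bio3d emits MODEL/ENDMDL blocks for multi-row xyz
  xyz <- if (n_frames(x) > 1L) t(flat) else as.vector(flat)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", n_atoms(x)),
    eleno = a$serial, elety = a$elety, resid = a$resid,
    chain = a$chain, resno = a$resno,
    insert = ifelse(nzchar(a$insert), a$insert, NA),
    o = a$o, b = a$b, elesy = a$elesy, verbose = FALSE
  )
  invisible(path)
}
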