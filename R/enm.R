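# Elastic network construction and Hessian assembly (anisotropic network
# model: springs between all atom pairs within a distance cutoff).

#' Build an elastic network from a structure
#'
#' One spring per atom pair within `cutoff`, with uniform force constant and
#' rest length equal to the observed distance. The default selection keeps
#' all heavy atoms (ligand atoms included); pass
#' `atom_selection(elety = "CA")` for a C-alpha network.
#'
#' @param x a [structure3d()].
#' @param selection an [atom_selection()] or `NULL` for all heavy atoms.
#' @param cutoff interaction cutoff in Angstrom (default 10).
#' @param force_constant uniform spring constant (default 1; mode eigenvalues
#'   scale linearly with it, so downstream overlap/transition analyses are
#'   unaffected by the choice).
#' @param frame frame to take coordinates from (default 1).
#' @return an `elastic_network`: node coordinates, masses, atom table, spring
#'   list `(i, j, r0, k)` with `i < j`, and the cutoff.
#' @export
build_network <- function(x, selection = NULL, cutoff = 10,
                          force_constant = 1, frame = 1L) {
  stopifnot(inherits(x, "structure3d"), cutoff > 0, force_constant > 0)
  idx <- resolve_selection(x, selection)
  if (length(idx) < 2L) stop("network needs at least 2 atoms")
  coords <- frame_coords(x, frame)[idx, , drop = FALSE]
  atoms <- x$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  springs <- neighbor_pairs(coords, cutoff)
  if (any(springs$d <= 0))
    stop("zero inter-atomic distance between selected atoms ",
         springs$i[springs$d <= 0][1], " and ", springs$j[springs$d <= 0][1])
  springs$k <- force_constant
  names(springs) <- c("i", "j", "r0", "k")
  structure(list(coords = coords, mass = atoms$mass, atoms = atoms,
                 springs = springs, cutoff = cutoff),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("elastic_network:", nrow(x$coords), "nodes,", nrow(x$springs),
      "springs, cutoff", x$cutoff, "A\n")
  invisible(x)
}

#' Assemble the (mass-weighted) Hessian of an elastic network
#'
#' For spring (i, j) with rest separation vector `r`, the off-diagonal 3x3
#' super-element is `-(k / r0^2) * (r %o% r)`; diagonal super-elements make
#' each row-block sum to zero, so uniform translations are annihilated
#' exactly. With `mass_weighted = TRUE` the operator is conjugated by
#' `M^(-1/2)` on both sides. Stored sparse: memory scales with the number of
#' springs, not N^2.
#'
#' @param network an `elastic_network`.
#' @param mass_weighted conjugate by the inverse square-root mass matrix
#'   (default `TRUE`).
#' @return a symmetric sparse `Matrix` of order 3N.
#' @export
assemble_hessian <- function(network, mass_weighted = TRUE) {
  stopifnot(inherits(network, "elastic_network"))
  sp <- network$springs
  n <- nrow(network$coords)
  ns <- nrow(sp)
  rij <- network$coords[sp$j, , drop = FALSE] - network$coords[sp$i, , drop = FALSE]
  w <- sp$k / sp$r0^2
  # 3x3 super-elements, one per spring: -w * (r %o% r)
  ab <- expand.grid(a = 1:3, b = 1:3)
  # per spring, the 9 entries -w r_a r_b in (a,b) grid order
  vals9 <- vapply(seq_len(ns), function(s)
    -w[s] * rij[s, ab$a] * rij[s, ab$b], numeric(9L))      # 9 x ns
  off_i <- rep(3L * (sp$i - 1L), each = 9L) + ab$a
  off_j <- rep(3L * (sp$j - 1L), each = 9L) + ab$b
  sym_i <- rep(3L * (sp$j - 1L), each = 9L) + ab$a
  sym_j <- rep(3L * (sp$i - 1L), each = 9L) + ab$b
  dia_ii <- rep(3L * (sp$i - 1L), each = 9L)
  dia_jj <- rep(3L * (sp$j - 1L), each = 9L)
  v <- as.vector(vals9)
  rows <- c(off_i, sym_i, dia_ii + ab$a, dia_jj + ab$a)
  cols <- c(off_j, sym_j, dia_ii + ab$b, dia_jj + ab$b)
  vals <- c(v, v, -v, -v)   # symmetric blocks; diagonals cancel row sums
  H <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(3L * n, 3L * n))
  if (mass_weighted) {
    s <- rep(1 / sqrt(network$mass), each = 3L)
    H <- Matrix::Diagonal(x = s) %*% H %*% Matrix::Diagonal(x = s)
  }
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
}
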