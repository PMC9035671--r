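# Normal modes by rotation-translation-block (RTB) reduction of the
# mass-weighted Hessian.

#' Block assignments for an elastic network
#'
#' @param network an `elastic_network`.
#' @param by `"residue"` (default; one block per chain/residue/insertion) or
#'   `"atom"` (one block per atom, which makes the RTB reduction exact: the
#'   block basis then spans the full Cartesian space).
#' @return integer vector assigning each node to a block (1..B).
#' @export
make_blocks <- function(network, by = c("residue", "atom")) {
  by <- match.arg(by)
  if (by == "atom") return(seq_len(nrow(network$coords)))
  key <- residue_key(network$atoms)
  as.integer(factor(key, levels = unique(key)))
}

# mass-orthonormalized rigid (translation + rotation) basis of one block,
# expressed in mass-weighted coordinates psi = M^(1/2) u.
# Returns a 3n_b x r matrix, r <= 6 (rank-truncated for single-atom or
# collinear blocks).
.block_basis <- function(coords, mass, rank_tol = 1e-10) {
  nb <- nrow(coords)
  cb <- colSums(coords * mass) / sum(mass)
  rel <- sweep(coords, 2L, cb)
  sq <- sqrt(mass)
  V <- matrix(0, 3L * nb, 6L)
  for (al in 1:3) {                      # translations
    V[seq(al, 3L * nb, by = 3L), al] <- sq
  }
  # rotations: u_a = e_al x (x_a - c_b)
  ex <- rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0))
  ey <- rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0))
  ez <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))
  gens <- list(ex, ey, ez)
  for (al in 1:3) {
    u <- rel %*% t(gens[[al]])           # n_b x 3, rows e_al x rel_a
    V[, 3L + al] <- as.vector(t(u * sq))
  }
  s <- svd(V)
  keep <- s$d > rank_tol * max(s$d)
  s$u[, keep, drop = FALSE]
}

#' Compute low-frequency normal modes (RTB)
#'
#' Each block contributes its rigid translations and rotations about its mass
#' centre (mass-orthonormalised, rank-truncated for degenerate blocks); the
#' mass-weighted Hessian is projected into this subspace, the reduced
#' symmetric eigenproblem is solved densely, eigenvectors are lifted back to
#' 3N Cartesian displacements, the six rigid-body modes are discarded, and
#' the `n_modes` lowest remaining modes are returned. With one-atom blocks
#' the reduction is exact and the result equals the full-Hessian
#' diagonalisation.
#'
#' @param network an `elastic_network` (must be connected).
#' @param blocks integer block assignment per node (default: one residue per
#'   block via [make_blocks()]).
#' @param n_modes number of non-rigid modes to return (default 100).
#' @param mass_weighted use atomic masses (default `TRUE`); `FALSE` sets unit
#'   masses for comparability with mass-free elastic-network conventions.
#' @return a `mode_set`: eigenvalues `values` (ascending, units k/m),
#'   `frequencies` (sqrt of values), mode matrix `vectors` (3N x m Cartesian
#'   displacements, orthonormal under the mass metric), `n_zero` discarded
#'   near-zero modes, equilibrium coordinates, masses, atom table, block
#'   assignment and provenance.
#' @export
compute_modes <- function(network, blocks = NULL, n_modes = 100L,
                          mass_weighted = TRUE) {
  stopifnot(inherits(network, "elastic_network"))
  n <- nrow(network$coords)
  if (is.null(blocks)) blocks <- make_blocks(network)
  stopifnot(length(blocks) == n, all(blocks >= 1L))
  comp <- network_components(network)
  if (comp > 1L)
    stop("elastic network is disconnected (", comp,
         " components); modes are only defined for a connected network")
  net <- network
  if (!mass_weighted) net$mass <- rep(1, n)
  H <- assemble_hessian(net, mass_weighted = TRUE)

  # assemble the sparse projection P (3N x sum of block ranks)
  ublocks <- sort(unique(blocks))
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  col0 <- 0L
  for (b in ublocks) {
    idx <- which(blocks == b)
    B <- .block_basis(net$coords[idx, , drop = FALSE], net$mass[idx])
    r <- ncol(B)
    rows <- as.vector(outer(1:3, 3L * (idx - 1L), `+`))
    trip_i[[length(trip_i) + 1L]] <- rep(rows, times = r)
    trip_j[[length(trip_j) + 1L]] <- rep(col0 + seq_len(r), each = length(rows))
    trip_x[[length(trip_x) + 1L]] <- as.vector(B)
    col0 <- col0 + r
  }
  P <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(3L * n, col0))
  # rigid-body dimension of the whole system: 6 for a non-collinear 3-D
  # network, 5 for collinear ones (no rotation about the axis)
  nr <- ncol(.block_basis(net$coords, net$mass))
  if (n_modes > col0 - nr)
    stop("n_modes = ", n_modes, " exceeds the ", col0 - nr,
         " non-rigid block degrees of freedom")
  Hred <- as.matrix(Matrix::t(P) %*% H %*% P)
  Hred <- (Hred + t(Hred)) / 2
  eig <- eigen(Hred, symmetric = TRUE)
  ord <- order(eig$values)
  lam <- eig$values[ord]
  Y <- eig$vectors[, ord, drop = FALSE]
  # zero-mode guard: exactly nr near-zero modes for a connected network
  if (col0 > nr && abs(lam[nr]) >= 1e-6 * abs(lam[nr + 1L]))
    stop("rigid-body mode separation failed: |lambda_", nr, "|/lambda_",
         nr + 1L, " = ", format(abs(lam[nr]) / abs(lam[nr + 1L])))
  keep <- seq(nr + 1L, min(col0, nr + n_modes))
  psi <- P %*% Y[, keep, drop = FALSE]           # mass-weighted displacements
  U <- as.matrix(psi) / rep(sqrt(net$mass), each = 3L)  # Cartesian
  structure(list(
    values = lam[keep],
    frequencies = sqrt(pmax(lam[keep], 0)),
    vectors = U,
    n_zero = nr,
    zero_values = lam[seq_len(nr)],
    coords = net$coords,
    mass = net$mass,
    atoms = net$atoms,
    blocks = blocks,
    provenance = list(cutoff = network$cutoff, mass_weighted = mass_weighted,
                      n_blocks = length(ublocks), reduced_dim = col0)
  ), class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", length(x$values), "modes over", nrow(x$coords), "atoms",
      sprintf("(lambda_1 = %.4g, lambda_%d = %.4g)\n",
              x$values[1], length(x$values), x$values[length(x$values)]))
  invisible(x)
}

#' Number of connected components of a network
#' @param network an `elastic_network`.
#' @return integer component count.
#' @export
network_components <- function(network) {
  n <- nrow(network$coords)
  sp <- network$springs
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(sp) > 0L)
    g <- igraph::add_edges(g, as.vector(rbind(sp$i, sp$j)))
  igraph::components(g)$no
}

#' Number of modes in a mode set
#' @param modes a `mode_set`.
#' @export
n_modes <- function(modes) length(modes$values)
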