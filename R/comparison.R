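# Comparison of conformational states: pairwise RMSD matrices, mode-subspace
# overlap, and least-squares decomposition of a transition into modes.

#' Pairwise superposed RMSD matrix over a selection
#'
#' For each pair of states, atoms common under (chain, residue, atom-name)
#' identity are paired, superposed and the RMSD recorded. The default
#' selection is C-alpha atoms.
#'
#' @param states list of [structure3d()] objects (names become labels).
#' @param selection an [atom_selection()]; default C-alpha only.
#' @return symmetric numeric matrix of RMSDs in Angstrom with zero diagonal.
#' @export
rmsd_matrix <- function(states, selection = atom_selection(elety = "CA")) {
  stopifnot(is.list(states), length(states) >= 2L)
  labels <- names(states)
  if (is.null(labels)) labels <- paste0("state", seq_along(states))
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pr <- pair_common_atoms(states[[i]], states[[j]], selection)
      if (length(pr$idx_a) < 3L)
        stop("fewer than 3 common atoms between states ", labels[i],
             " and ", labels[j])
      xi <- frame_coords(states[[i]])[pr$idx_a, , drop = FALSE]
      xj <- frame_coords(states[[j]])[pr$idx_b, , drop = FALSE]
      M[i, j] <- M[j, i] <- superpose(xj, xi)$rmsd
    }
  }
  M
}

# pair the atoms of two mode sets by identity, restricted to a selection
.pair_mode_atoms <- function(modesA, modesB, selection) {
  sa <- structure3d(modesA$atoms, modesA$coords)
  sb <- structure3d(modesB$atoms, modesB$coords)
  pair_common_atoms(sa, sb, selection)
}

# restrict a 3N x m mode matrix to the xyz rows of the given atom indices
.restrict_modes <- function(vectors, idx) {
  rows <- as.vector(outer(1:3, 3L * (idx - 1L), `+`))
  vectors[rows, , drop = FALSE]
}

# orthonormal basis of the column span, rank-tolerant (pivoted QR)
.orthonormal_basis <- function(X, tol = 1e-10) {
  qrx <- qr(X, LAPACK = TRUE)
  d <- abs(diag(qr.R(qrx)))
  rank <- sum(d > tol * max(d))
  if (rank < 1L) stop("rank collapse: restricted mode basis has rank 0")
  qr.Q(qrx)[, seq_len(rank), drop = FALSE]
}

#' Per-mode subspace overlap between two mode sets
#'
#' Each mode vector of set a, restricted to the C-alpha components of the
#' paired atoms and renormalised, is projected onto the orthonormalised span
#' of set b's restricted vectors; the overlap is the sum of squared
#' projections, between 0 (disjoint) and 1 (contained). Both directions are
#' computed. Structures are assumed to have been superposed before mode
#' computation.
#'
#' @param modesA,modesB `mode_set` objects.
#' @param selection atoms used for the comparison (default C-alpha).
#' @param k_average number of leading modes over which to report the average
#'   overlap (default 10, capped at the available modes).
#' @return an `overlap_profile`: per-mode overlaps `a_onto_b`, `b_onto_a`,
#'   eigenvalues of both sets, the leading-K averages and the paired-atom
#'   count.
#' @export
subspace_overlap <- function(modesA, modesB,
                             selection = atom_selection(elety = "CA"),
                             k_average = 10L) {
  stopifnot(inherits(modesA, "mode_set"), inherits(modesB, "mode_set"))
  pr <- .pair_mode_atoms(modesA, modesB, selection)
  Ua <- .restrict_modes(modesA$vectors, pr$idx_a)
  Ub <- .restrict_modes(modesB$vectors, pr$idx_b)
  overlaps <- function(U, basis) {
    nrm <- sqrt(colSums(U^2))
    if (any(nrm <= 0)) stop("a restricted mode vector has zero norm")
    Un <- sweep(U, 2L, nrm, `/`)
    colSums(crossprod(basis, Un)^2)
  }
  Qa <- .orthonormal_basis(Ua)
  Qb <- .orthonormal_basis(Ub)
  a_onto_b <- overlaps(Ua, Qb)
  b_onto_a <- overlaps(Ub, Qa)
  ka <- min(k_average, length(a_onto_b))
  kb <- min(k_average, length(b_onto_a))
  structure(list(
    a_onto_b = a_onto_b, b_onto_a = b_onto_a,
    values_a = modesA$values, values_b = modesB$values,
    k_average = k_average,
    mean_a_onto_b = mean(a_onto_b[seq_len(ka)]),
    mean_b_onto_a = mean(b_onto_a[seq_len(kb)]),
    n_paired = length(pr$idx_a)
  ), class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf(paste0("overlap_profile: %d/%d modes over %d paired atoms; ",
                     "mean overlap (first %d): a->b %.3f, b->a %.3f\n"),
              length(x$a_onto_b), length(x$b_onto_a), x$n_paired,
              x$k_average, x$mean_a_onto_b, x$mean_b_onto_a))
  invisible(x)
}

#' Decompose a conformational transition into normal-mode contributions
#'
#' The target is superposed onto the mode set's equilibrium structure over
#' paired C-alpha atoms; the resulting displacement is fitted by the linear
#' combination of the restricted mode vectors that minimises the residual
#' (least squares). The cumulative curve reports the remaining RMSD after
#' including the first k modes in ascending frequency order (`rmsd_k[1]`,
#' "mode 0", is the initial superposed RMSD). Per-mode contributions are
#' reported two ways: the marginal decrease at the mode's frequency rank, and
#' the solo decrease the mode achieves alone.
#'
#' @param modes a `mode_set` computed on the starting state.
#' @param target a [structure3d()] for the end state (frame 1 used).
#' @param selection atoms used for the fit (default C-alpha).
#' @param n_modes number of modes to use (default: all in `modes`).
#' @return a `transition_fit` object; see Details.
#' @export
transition_fit <- function(modes, target,
                           selection = atom_selection(elety = "CA"),
                           n_modes = NULL) {
  stopifnot(inherits(modes, "mode_set"), inherits(target, "structure3d"))
  m <- if (is.null(n_modes)) length(modes$values) else as.integer(n_modes)
  if (m > length(modes$values))
    stop("n_modes = ", m, " exceeds the ", length(modes$values),
         " available modes")
  sa <- structure3d(modes$atoms, modes$coords)
  pr <- pair_common_atoms(sa, target, selection)
  np <- length(pr$idx_a)
  if (np < 3L) stop("fewer than 3 paired atoms for the transition fit")
  xa <- modes$coords[pr$idx_a, , drop = FALSE]
  xb <- frame_coords(target)[pr$idx_b, , drop = FALSE]
  same <- max(abs(xa - xb)) == 0
  if (same) {
    xb_fit <- xb
    rmsd0 <- 0
  } else {
    sup <- superpose(xb, xa)
    xb_fit <- sup$coords
    rmsd0 <- sup$rmsd
  }
  d <- as.vector(t(xb_fit - xa))
  U <- .restrict_modes(modes$vectors, pr$idx_a)[, seq_len(m), drop = FALSE]

  # ordered (unpivoted) QR: Q[, 1:k] spans the first k modes, so the
  # cumulative curve is the exact nested-subspace projection residual
  qru <- qr(U)
  Rd <- abs(diag(qr.R(qru)))
  ok <- Rd > 1e-10 * max(Rd)
  Q <- qr.Q(qru)
  p <- as.vector(crossprod(Q, d))
  p[!ok] <- 0           # columns linearly dependent on earlier modes
  rmsd_k <- sqrt(pmax(rmsd0^2 - cumsum(c(0, p^2)) / np, 0))
  coef <- qr.coef(qru, d)
  coef[is.na(coef)] <- 0
  # the closed form cancels catastrophically when the fit is near-perfect;
  # the direct residual of the full fit is accurate there
  rmsd_k[m + 1L] <- min(rmsd_k[m + 1L],
                        sqrt(sum((d - U %*% coef)^2) / np))

  nrm <- sqrt(colSums(U^2))
  solo_proj <- as.vector(crossprod(sweep(U, 2L, pmax(nrm, 1e-300), `/`), d))
  solo <- rmsd0 - sqrt(pmax(rmsd0^2 - solo_proj^2 / np, 0))
  total <- rmsd0 - rmsd_k[m + 1L]
  structure(list(
    coefficients = coef,
    rmsd_k = rmsd_k,                    # length m+1; [1] is "mode 0"
    rmsd0 = rmsd0,
    rmsd_final = rmsd_k[m + 1L],
    marginal = -diff(rmsd_k),
    solo = solo,
    fraction_reduced = if (rmsd0 > 0) total / rmsd0 else 0,
    n_paired = np,
    pairing = pr,
    target_fitted = xb_fit,
    modes = modes,
    n_modes = m
  ), class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(paste0("transition_fit: %d modes, %d paired atoms; RMSD %.3f",
                     " -> %.3f A (%.1f%% reduced)\n"),
              x$n_modes, x$n_paired, x$rmsd0, x$rmsd_final,
              100 * x$fraction_reduced))
  invisible(x)
}

#' Generate a transition path from a mode decomposition
#'
#' Frames interpolate from the starting structure toward the mode-fitted
#' displacement. `"linear"` scales the summed displacement field; `"screw"`
#' applies the per-block screw transform of the field at each amplitude
#' increment, preserving block geometry.
#'
#' @param fit a [transition_fit()].
#' @param n_frames number of frames (default 20).
#' @param extrapolation `"linear"` or `"screw"`.
#' @return a multi-frame [structure3d()] over the mode-set atoms; frame 1 is
#'   the starting structure.
#' @export
transition_path <- function(fit, n_frames = 20L,
                            extrapolation = c("linear", "screw")) {
  stopifnot(inherits(fit, "transition_fit"), n_frames >= 2L)
  extrapolation <- match.arg(extrapolation)
  modes <- fit$modes
  D <- modes$vectors[, seq_len(fit$n_modes), drop = FALSE] %*% fit$coefficients
  s <- seq(0, 1, length.out = n_frames)
  if (extrapolation == "linear") {
    Dm <- matrix(D, ncol = 3L, byrow = TRUE)
    frames <- lapply(s, function(si) modes$coords + si * Dm)
  } else {
    screws <- fit_block_screw(modes$coords, as.vector(D), modes$mass,
                              modes$blocks)
    frames <- lapply(s, function(si)
      apply_block_screw(modes$coords, screws, si))
  }
  .mode_structure(modes, frames)
}
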