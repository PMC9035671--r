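# Finite-amplitude extrapolation of a normal mode: standard linear
# displacement, and per-block screw (rotation + translation) transforms that
# preserve block geometry at large amplitude.

# periodic amplitude schedule: frame t (0-based) gets A * sin(2 pi t / n)
.amplitude_schedule <- function(n_frames) {
  t <- seq_len(n_frames) - 1L
  sin(2 * pi * t / n_frames)
}

# scale so the maximum-displacement frame has the requested all-atom RMSD
.amplitude_scale <- function(u, n_atoms, amplitude_rmsd, schedule) {
  rms_u <- sqrt(sum(u^2) / n_atoms)
  amplitude_rmsd / (rms_u * max(abs(schedule)))
}

.mode_structure <- function(modes, frames) {
  structure3d(modes$atoms, frames)
}

#' Linear extrapolation of a mode as a periodic trajectory
#'
#' Frames follow `x(t) = x0 + A sin(2 pi t / n_frames) u`, with `A` chosen so
#' the maximum-displacement frame lies at the requested all-atom RMSD from
#' the equilibrium structure. Frame 1 (phase 0) equals the input exactly.
#'
#' @param modes a `mode_set`.
#' @param mode_index which mode (1 = lowest frequency).
#' @param amplitude_rmsd peak all-atom RMSD from equilibrium, in Angstrom.
#' @param n_frames number of frames in one period (default 20).
#' @return a multi-frame [structure3d()] over the network atoms.
#' @export
extrapolate_mode_linear <- function(modes, mode_index, amplitude_rmsd,
                                    n_frames = 20L) {
  stopifnot(inherits(modes, "mode_set"),
            mode_index >= 1L, mode_index <= n_modes(modes),
            amplitude_rmsd >= 0)
  u <- modes$vectors[, mode_index]
  n <- nrow(modes$coords)
  s <- .amplitude_schedule(n_frames)
  A <- if (amplitude_rmsd == 0) 0 else .amplitude_scale(u, n, amplitude_rmsd, s)
  U <- matrix(u, ncol = 3L, byrow = TRUE)
  frames <- lapply(s, function(si) modes$coords + (A * si) * U)
  .mode_structure(modes, frames)
}

#' Fit per-block rigid velocity fields to a displacement field
#'
#' For each block, least-squares fit of the mode displacement by
#' `u_a = v + omega x (x_a - c)` about the block mass centre `c`.
#'
#' @param coords N x 3 equilibrium coordinates.
#' @param u displacement field, length 3N (atom-major xyz) or N x 3 matrix.
#' @param mass node masses.
#' @param blocks integer block assignment.
#' @return list of per-block fits: `v`, `omega`, `center`, `idx`, and the
#'   relative residual of the rigid fit.
#' @export
fit_block_screw <- function(coords, u, mass, blocks) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(u) == nrow(coords), length(blocks) == nrow(coords))
  lapply(sort(unique(blocks)), function(b) {
    idx <- which(blocks == b)
    x <- coords[idx, , drop = FALSE]
    ub <- u[idx, , drop = FALSE]
    cb <- colSums(x * mass[idx]) / sum(mass[idx])
    rel <- sweep(x, 2L, cb)
    nb <- length(idx)
    # design: u_a = v - rel_a x omega  => columns [I3 | -skew(rel_a)]
    A <- matrix(0, 3L * nb, 6L)
    rhs <- as.vector(t(ub))
    for (a in seq_len(nb)) {
      r <- rel[a, ]
      rowi <- 3L * (a - 1L) + 1:3
      A[rowi, 1:3] <- diag(3)
      A[rowi, 4:6] <- -rbind(c(0, -r[3], r[2]),
                             c(r[3], 0, -r[1]),
                             c(-r[2], r[1], 0))
    }
    fit <- qr(A)
    beta <- qr.coef(fit, rhs)
    beta[is.na(beta)] <- 0
    resid <- rhs - A %*% beta
    list(v = beta[1:3], omega = beta[4:6], center = cb, idx = idx,
         rel_residual = sqrt(sum(resid^2) / max(sum(rhs^2), 1e-300)))
  })
}

#' Apply per-block screw transforms at a finite amplitude
#'
#' For a block with fitted translation `v` and angular velocity `omega`, the
#' screw transform at amplitude `a` rotates the block by angle `a |omega|`
#' about the axis through `c + (omega x v)/|omega|^2` along `omega`, plus a
#' translation `a (v . omega_hat) omega_hat` along the axis. Blocks with
#' `|omega|` below `tol` translate by `a v`. At infinitesimal amplitude this
#' reproduces the linear field `v + omega x (x - c)` to first order.
#'
#' @param coords N x 3 equilibrium coordinates.
#' @param screws result of [fit_block_screw()].
#' @param amplitude scalar amplitude `a`.
#' @param tol angular-velocity threshold for the pure-translation branch.
#' @return displaced N x 3 coordinates.
#' @export
apply_block_screw <- function(coords, screws, amplitude, tol = 1e-12) {
  out <- coords
  for (s in screws) {
    x <- coords[s$idx, , drop = FALSE]
    w <- s$omega
    wn <- sqrt(sum(w^2))
    if (wn < tol) {
      out[s$idx, ] <- sweep(x, 2L, amplitude * s$v, `+`)
      next
    }
    what <- w / wn
    p <- s$center + crossv(w, s$v) / wn^2      # point on the screw axis
    theta <- amplitude * wn
    R <- rotation_about_axis(what, theta)
    pitch <- amplitude * sum(s$v * what) * what
    y <- sweep(x, 2L, p)
    y <- y %*% t(R)
    out[s$idx, ] <- sweep(y, 2L, p + pitch, `+`)
  }
  out
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about unit axis
rotation_about_axis <- function(axis, theta) {
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Nonlinear (screw) extrapolation of a mode as a periodic trajectory
#'
#' The mode displacement field is decomposed per block into instantaneous
#' rotational and translational components; each frame applies the resulting
#' screw transforms at the scheduled amplitude, which preserves intra-block
#' geometry exactly at any amplitude. Amplitude schedule and scaling follow
#' [extrapolate_mode_linear()]; frame 1 (phase 0) equals the input exactly.
#'
#' @inheritParams extrapolate_mode_linear
#' @param blocks block assignment (default: the blocks stored in the mode
#'   set).
#' @return a multi-frame [structure3d()].
#' @export
extrapolate_mode_nonlinear <- function(modes, mode_index, amplitude_rmsd,
                                       n_frames = 20L, blocks = NULL) {
  stopifnot(inherits(modes, "mode_set"),
            mode_index >= 1L, mode_index <= n_modes(modes),
            amplitude_rmsd >= 0)
  if (is.null(blocks)) blocks <- modes$blocks
  u <- modes$vectors[, mode_index]
  n <- nrow(modes$coords)
  s <- .amplitude_schedule(n_frames)
  A <- if (amplitude_rmsd == 0) 0 else .amplitude_scale(u, n, amplitude_rmsd, s)
  screws <- fit_block_screw(modes$coords, u, modes$mass, blocks)
  frames <- lapply(s, function(si)
    apply_block_screw(modes$coords, screws, A * si))
  .mode_structure(modes, frames)
}
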