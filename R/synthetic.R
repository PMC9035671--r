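# Synthetic structures, conformer pairs with known mode ground truth, and
# trajectories with prescribed contact schedules. All generators take an
# explicit seed and restore the caller's RNG state, so runs are reproducible
# and no global state leaks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.ca_atoms <- function(n, chain = "A", resno = NULL, elety = "CA",
                      resid = "ALA") {
  if (is.null(resno)) resno <- seq_len(n)
  data.frame(serial = seq_len(n), elety = elety, elesy = "C", resid = resid,
             chain = chain, resno = resno, insert = "", o = 1, b = 0,
             stringsAsFactors = FALSE)
}

#' Ideal helical C-alpha trace
#'
#' Residue i sits at angle `(i-1) * twist` and height `(i-1) * rise` on a
#' cylinder of the given radius (defaults approximate an alpha-helix:
#' rise 1.5 A, twist 100 degrees, radius 2.3 A). Optional dummy side-chain
#' atoms (CB, CG, ...) are placed radially outward at 1.5 A spacing.
#'
#' @param n_residues number of residues (>= 2).
#' @param rise per-residue rise in Angstrom.
#' @param twist per-residue twist in degrees.
#' @param radius helix radius in Angstrom.
#' @param atoms_per_residue 1 for a pure C-alpha trace, up to 4 adds CB, CG,
#'   CD.
#' @param chain chain identifier.
#' @return a [structure3d()].
#' @export
make_helix <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                       atoms_per_residue = 1L, chain = "A") {
  stopifnot(n_residues >= 2L, atoms_per_residue >= 1L, atoms_per_residue <= 4L)
  names_per <- c("CA", "CB", "CG", "CD")[seq_len(atoms_per_residue)]
  th <- (seq_len(n_residues) - 1L) * twist * pi / 180
  z <- (seq_len(n_residues) - 1L) * rise
  rows <- list(); coords <- list()
  for (i in seq_len(n_residues)) {
    for (k in seq_len(atoms_per_residue)) {
      r <- radius + (k - 1L) * 1.5
      coords[[length(coords) + 1L]] <- c(r * cos(th[i]), r * sin(th[i]), z[i])
    }
  }
  atoms <- data.frame(
    serial = seq_len(n_residues * atoms_per_residue),
    elety = rep(names_per, n_residues), elesy = "C", resid = "ALA",
    chain = chain, resno = rep(seq_len(n_residues), each = atoms_per_residue),
    insert = "", o = 1, b = 0, stringsAsFactors = FALSE
  )
  structure3d(atoms, do.call(rbind, coords))
}

# compact random cluster of n points, pairwise separation >= min_sep
.random_cluster <- function(n, sd, min_sep = 1.5, max_tries = 2000L) {
  pts <- matrix(NA_real_, n, 3L)
  pts[1L, ] <- stats::rnorm(3L, sd = sd)
  for (i in seq(2L, n)) {
    for (tr in seq_len(max_tries)) {
      cand <- stats::rnorm(3L, sd = sd)
      d2 <- rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2L, cand)^2)
      if (min(d2) >= min_sep^2) { pts[i, ] <- cand; break }
      if (tr == max_tries) stop("could not place cluster point ", i)
    }
  }
  pts
}

#' Two compact domains joined by a linker
#'
#' Generates a C-alpha structure whose lowest non-rigid elastic-network mode
#' is an inter-domain (hinge-like) motion: two compact random clusters of
#' `n_per_domain` residues each, connected by a straight linker of
#' `linker_length` residues spaced 3.8 A apart. Deterministic given `seed`.
#'
#' @param n_per_domain residues per domain (>= 10).
#' @param linker_length number of linker residues (default 4).
#' @param seed RNG seed.
#' @return a [structure3d()] with attribute `domains`, an integer vector
#'   (1, 2, or 0 for linker residues).
#' @export
make_two_domain_hinge <- function(n_per_domain, linker_length = 4L, seed = 1L) {
  stopifnot(n_per_domain >= 10L, linker_length >= 1L)
  with_seed(seed, {
    sdv <- 1.2 * n_per_domain^(1 / 3)
    d1 <- .random_cluster(n_per_domain, sd = sdv)
    d2 <- .random_cluster(n_per_domain, sd = sdv)
    # face-to-face gap of 2.5 A per linker segment: short enough that every
    # linker residue also contacts domain atoms, keeping the network
    # generically rigid (exactly 6 zero modes)
    sep <- max(d1[, 1L]) - min(d2[, 1L]) + (linker_length + 1L) * 2.5
    d2 <- sweep(d2, 2L, c(sep, 0, 0), `+`)
    # zigzag linker between the closest faces of the two domains; the
    # perpendicular offsets keep spring directions at each linker residue
    # non-collinear (a straight chain would add spurious zero-energy modes)
    a <- d1[which.max(d1[, 1L]), ]
    b <- d2[which.min(d2[, 1L]), ]
    tfrac <- seq_len(linker_length) / (linker_length + 1L)
    axis <- (b - a) / sqrt(sum((b - a)^2))
    perp1 <- crossv(axis, c(0, 0, 1))
    if (sum(perp1^2) < 1e-6) perp1 <- crossv(axis, c(0, 1, 0))
    perp1 <- perp1 / sqrt(sum(perp1^2))
    perp2 <- crossv(axis, perp1)
    link <- t(vapply(seq_along(tfrac), function(i) {
      wob <- if (i %% 2L == 1L) perp1 else perp2
      a + tfrac[i] * (b - a) + 1.8 * (-1)^(i %/% 2L) * wob
    }, numeric(3L)))
    coords <- rbind(d1, link, d2)
    n <- nrow(coords)
    st <- structure3d(.ca_atoms(n), coords)
    attr(st, "domains") <- c(rep(1L, n_per_domain), rep(0L, linker_length),
                             rep(2L, n_per_domain))
    st
  })
}

#' Displace a structure along known modes, with optional noise
#'
#' Produces a conformer `x' = x + sum(c_i u_i) + eps` with `eps` iid Gaussian
#' per coordinate, and the ground truth needed for parameter-recovery tests.
#' The mode set must have been computed on the structure's atoms.
#'
#' @param x a [structure3d()] (frame 1 used).
#' @param modes a `mode_set` over the same atoms.
#' @param coefficients numeric vector of mode coefficients, indexed by mode,
#'   or a named sparse specification like `c("3" = 1.0)`.
#' @param noise_sigma standard deviation of the added Gaussian noise per
#'   coordinate (Angstrom; default 0).
#' @param seed RNG seed for the noise.
#' @return list with `structure` (the displaced conformer) and `truth`
#'   (mode indices, coefficients, sigma, seed, and the closed-form unfitted
#'   C-alpha RMSD implied by the coefficients at sigma = 0).
#' @export
perturb_along_modes <- function(x, modes, coefficients, noise_sigma = 0,
                                seed = 1L) {
  stopifnot(inherits(x, "structure3d"), inherits(modes, "mode_set"))
  if (nrow(modes$coords) != n_atoms(x))
    stop("mode set and structure have different atom counts")
  m <- length(modes$values)
  cf <- numeric(m)
  if (!is.null(names(coefficients))) {
    idx <- as.integer(names(coefficients))
    stopifnot(all(idx >= 1L), all(idx <= m))
    cf[idx] <- as.numeric(coefficients)
  } else {
    stopifnot(length(coefficients) <= m)
    cf[seq_along(coefficients)] <- coefficients
  }
  D <- as.vector(modes$vectors %*% cf)
  Dm <- matrix(D, ncol = 3L, byrow = TRUE)
  noise <- if (noise_sigma > 0)
    with_seed(seed, matrix(stats::rnorm(3L * n_atoms(x), sd = noise_sigma),
                           ncol = 3L))
  else matrix(0, n_atoms(x), 3L)
  newxyz <- frame_coords(x) + Dm + noise
  is_ca <- x$atoms$elety == "CA"
  rms_ca <- if (any(is_ca))
    sqrt(sum(Dm[is_ca, ]^2) / sum(is_ca)) else NA_real_
  list(
    structure = structure3d(x$atoms, newxyz),
    truth = list(modes = which(cf != 0), coefficients = cf[cf != 0],
                 all_coefficients = cf, sigma = noise_sigma, seed = seed,
                 expected_ca_rmsd = rms_ca)
  )
}

#' Trajectory with a prescribed interface contact schedule
#'
#' Starting from a reference frame, generates `n_frames` frames in which
#' scheduled residue pairs are broken (the B-side residue translated along
#' the pair axis to beyond the cutoff) or re-formed at stated frames; all
#' other atoms receive sub-cutoff Gaussian jitter. An optional register-shift
#' template moves two designated atom pairs in opposite directions so their
#' distance series cross at a stated frame.
#'
#' @param x a [structure3d()]; frame 1 is the reference.
#' @param selection_a,selection_b interface side selections.
#' @param schedule data frame with columns `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `event` (`"break"` or `"form"`), `frame`; may be empty.
#'   Conflicting events for one pair at one frame are an error.
#' @param n_frames number of frames to generate.
#' @param cutoff contact cutoff the schedule is defined against (default 4.5).
#' @param jitter standard deviation of the per-coordinate jitter (default 0).
#' @param register_shift optional list with `pair1`, `pair2` (atom specs as
#'   in [atom_pair_distance()]: the moving atom is the *first* of each pair),
#'   `frame` (crossing frame), `d_near` (default 3.0) and `d_far`
#'   (default 9.0): pair1 runs near -> far, pair2 far -> near, crossing at
#'   the stated frame.
#' @param seed RNG seed for the jitter.
#' @return list with `structure` (multi-frame) and `truth` (the schedule,
#'   jitter, seed and register-shift parameters).
#' @export
make_contact_trajectory <- function(x, selection_a, selection_b,
                                    schedule = NULL, n_frames = 20L,
                                    cutoff = 4.5, jitter = 0,
                                    register_shift = NULL, seed = 1L) {
  stopifnot(inherits(x, "structure3d"), n_frames >= 2L)
  ref <- frame_coords(x, 1L)
  a <- x$atoms
  if (is.null(schedule))
    schedule <- data.frame(chain_a = character(0), resno_a = integer(0),
                           chain_b = character(0), resno_b = integer(0),
                           event = character(0), frame = integer(0))
  if (nrow(schedule) > 0L) {
    key <- paste(schedule$chain_a, schedule$resno_a, schedule$chain_b,
                 schedule$resno_b, schedule$frame)
    conflict <- tapply(schedule$event, key, function(e) length(unique(e)) > 1L)
    if (any(conflict))
      stop("conflicting schedule events for pair(s) at one frame: ",
           names(conflict)[conflict][1])
  }
  res_atoms <- function(chain, resno)
    which(a$chain == chain & a$resno == resno)
  # displacement needed to break/form one pair: move the B residue along the
  # axis between the two residues' closest atoms
  pair_shift <- function(chain_a, resno_a, chain_b, resno_b, want_broken) {
    ia <- res_atoms(chain_a, resno_a); ib <- res_atoms(chain_b, resno_b)
    if (length(ia) == 0L || length(ib) == 0L)
      stop("schedule pair ", chain_a, ":", resno_a, "-", chain_b, ":",
           resno_b, " not resolvable")
    dmat <- as.matrix(stats::dist(rbind(ref[ia, , drop = FALSE],
                                        ref[ib, , drop = FALSE])))
    sub <- dmat[seq_along(ia), length(ia) + seq_along(ib), drop = FALSE]
    w <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    pa <- ref[ia[w[1L]], ]; pb <- ref[ib[w[2L]], ]
    axis <- pb - pa
    axis <- axis / sqrt(sum(axis^2))
    d0 <- min(sub)
    target <- if (want_broken) cutoff + 4 else max(cutoff - 1.5, 1.5)
    list(idx = ib, delta = (target - d0) * axis)
  }
  jit <- if (jitter > 0)
    with_seed(seed, array(stats::rnorm(3L * nrow(ref) * n_frames,
                                       sd = jitter),
                          dim = c(nrow(ref), 3L, n_frames)))
  else array(0, dim = c(nrow(ref), 3L, n_frames))

  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    co <- ref + jit[, , t]
    if (nrow(schedule) > 0L) {
      # the most recent event at or before t decides each pair's state
      pk <- paste(schedule$chain_a, schedule$resno_a,
                  schedule$chain_b, schedule$resno_b)
      for (p in unique(pk)) {
        ev <- schedule[pk == p & schedule$frame <= t, , drop = FALSE]
        if (nrow(ev) == 0L) next
        ev <- ev[which.max(ev$frame), ]
        sh <- pair_shift(ev$chain_a, ev$resno_a, ev$chain_b, ev$resno_b,
                         want_broken = ev$event == "break")
        co[sh$idx, ] <- sweep(co[sh$idx, , drop = FALSE], 2L, sh$delta, `+`)
      }
    }
    if (!is.null(register_shift)) {
      rs <- register_shift
      d_near <- if (is.null(rs$d_near)) 3.0 else rs$d_near
      d_far <- if (is.null(rs$d_far)) 9.0 else rs$d_far
      # linear ramp crossing at rs$frame: s = 0.5 there
      s <- 0.5 * (t - 1L) / max(rs$frame - 1L, 1L)
      s <- min(s, 1)
      move_to <- function(pair, target_d) {
        spec1 <- as.list(pair[[1L]]); spec2 <- as.list(pair[[2L]])
        i1 <- which(a$chain == spec1$chain & a$resno == spec1$resno &
                    a$elety == spec1$elety)
        i2 <- which(a$chain == spec2$chain & a$resno == spec2$resno &
                    a$elety == spec2$elety)
        stopifnot(length(i1) == 1L, length(i2) == 1L)
        axis <- ref[i1, ] - ref[i2, ]
        axis <- axis / sqrt(sum(axis^2))
        co[i1, ] <<- co[i2, ] + target_d * axis
      }
      move_to(rs$pair1, d_near + s * (d_far - d_near))
      move_to(rs$pair2, d_far - s * (d_far - d_near))
    }
    frames[[t]] <- co
  }
  list(
    structure = structure3d(a, frames),
    truth = list(schedule = schedule, n_frames = n_frames, cutoff = cutoff,
                 jitter = jitter, seed = seed,
                 register_shift = register_shift)
  )
}
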