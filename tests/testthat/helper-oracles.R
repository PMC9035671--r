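# Independent oracles and fixture builders shared across the test files.
# Each oracle is deliberately a different algorithm from the implementation
# it checks.

# Quaternion (Horn) superposition: optimal RMSD from the largest eigenvalue
# of the 4x4 Davenport matrix. Independent of the SVD-based Kabsch code.
quaternion_rmsd <- function(mobile, target) {
  P <- scale(mobile, scale = FALSE)
  Q <- scale(target, scale = FALSE)
  S <- crossprod(P, Q)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],       S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],       S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],       S[3,1]+S[1,3],        S[2,3]+S[3,2],      -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(sum(P^2) + sum(Q^2) - 2 * lam, 0) / nrow(P))
}

# All-pairs distance scan (the O(N^2) definition the cell list must match).
brute_force_pairs <- function(coords, cutoff) {
  d <- as.matrix(dist(coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2], d = d[idx])
  out[order(out$i, out$j), ]
}

# Element-by-element dense ANM Hessian assembly (loops, no sparsity).
dense_hessian_oracle <- function(coords, springs, mass = NULL) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]
    r <- coords[j, ] - coords[i, ]
    blk <- -(springs$k[s] / springs$r0[s]^2) * (r %o% r)
    ri <- 3 * (i - 1) + 1:3; rj <- 3 * (j - 1) + 1:3
    H[ri, rj] <- H[ri, rj] + blk
    H[rj, ri] <- H[rj, ri] + t(blk)
    H[ri, ri] <- H[ri, ri] - blk
    H[rj, rj] <- H[rj, rj] - blk
  }
  if (!is.null(mass)) {
    s <- rep(1 / sqrt(mass), each = 3)
    H <- H * (s %o% s)
  }
  H
}

# Brute-force residue contact oracle.
brute_force_contacts <- function(st, sel_a, sel_b, cutoff, frame = 1) {
  ia <- resolve_selection(st, sel_a)
  ib <- resolve_selection(st, sel_b)
  co <- frame_coords(st, frame)
  res <- list()
  ra <- paste(st$atoms$chain[ia], st$atoms$resno[ia])
  rb <- paste(st$atoms$chain[ib], st$atoms$resno[ib])
  for (u in unique(ra)) for (v in unique(rb)) {
    du <- co[ia[ra == u], , drop = FALSE]
    dv <- co[ib[rb == v], , drop = FALSE]
    dmin <- min(sqrt(outer(rowSums(du^2), rowSums(dv^2), `+`) -
                       2 * du %*% t(dv)))
    if (dmin <= cutoff) res[[paste(u, v)]] <- dmin
  }
  res
}

# Random-walk chain: consecutive atoms step apart, self-avoiding, confined
# to a compact globule (every atom ends up with several spatial neighbours,
# like a folded protein, so the elastic network is generically rigid);
# connected by construction for any cutoff >= step.
random_walk_structure <- function(n, step = 3.8, confine = 2.8 * n^(1 / 3),
                                  min_sep = 2.0, chain = "A") {
  pts <- matrix(0, n, 3)
  for (i in seq(2, n)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries %% 500 == 0) confine <- confine * 1.05
      dir <- rnorm(3)
      cand <- pts[i - 1, ] + step * dir / sqrt(sum(dir^2))
      far <- sqrt(sum(cand^2)) <= confine
      clear <- i == 2 ||
        min(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2, cand)^2)) >=
        min_sep^2
      if (far && clear) { pts[i, ] <- cand; break }
    }
  }
  atoms <- data.frame(serial = seq_len(n), elety = "CA", elesy = "C",
                      resid = "ALA", chain = chain, resno = seq_len(n),
                      insert = "", o = 1, b = 0, stringsAsFactors = FALSE)
  structure3d(atoms, pts)
}

# Two parallel strands with residue i of chain A directly across from
# residue i of chain B: at cutoff 4.5 the contact map is exactly the rungs
# i-i, so scheduled break events change the conserved fraction by exactly
# 1/n each.
ladder_structure <- function(n = 10, spacing = 3.8, gap = 4.0) {
  a <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  b <- cbind((seq_len(n) - 1) * spacing, gap, 0)
  atoms <- data.frame(serial = seq_len(2 * n), elety = "CA", elesy = "C",
                      resid = "GLY",
                      chain = rep(c("A", "B"), each = n),
                      resno = rep(seq_len(n), 2), insert = "", o = 1, b = 0,
                      stringsAsFactors = FALSE)
  structure3d(atoms, rbind(a, b))
}

# A small two-chain structure with a real interface (two parallel helices).
two_chain_structure <- function(n = 10, gap = 7) {
  a <- make_helix(n, chain = "A")
  b <- make_helix(n, chain = "B")
  xb <- frame_coords(b)
  xb[, 1] <- xb[, 1] + gap
  bt <- b$atoms; bt$serial <- bt$serial + n_atoms(a)
  structure3d(rbind(a$atoms, bt), rbind(frame_coords(a), xb))
}

# Apply a proper rigid motion to every frame of a structure.
rigid_transform <- function(st, axis = c(1, 2, 2), angle = 0.7,
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  structure3d(st$atoms, lapply(st$xyz, function(m)
    sweep(m %*% t(R), 2, shift, `+`)))
}
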