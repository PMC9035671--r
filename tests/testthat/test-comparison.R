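# State comparison: RMSD matrices, subspace overlap, transition decomposition.

hinge_modes <- function(seed = 1, n_modes = 12L, n = 15L) {
  hinge <- make_two_domain_hinge(n, seed = seed)
  net <- build_network(hinge, cutoff = 10)
  list(structure = hinge, net = net,
       modes = compute_modes(net, n_modes = n_modes))
}

test_that("rmsd_matrix is zero for identical or translated copies and matches per-pair superposition", {
  a <- make_helix(20)
  shifted <- structure3d(a$atoms, frame_coords(a) + 1)  # +1 A on every axis
  M <- rmsd_matrix(list(a = a, b = shifted))
  expect_equal(M, matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))),
               tolerance = 1e-9)

  set.seed(3)
  conf <- lapply(1:3, function(k)
    structure3d(a$atoms, frame_coords(a) + matrix(rnorm(60, sd = 0.8), ncol = 3)))
  M3 <- rmsd_matrix(conf)
  expect_equal(M3, t(M3))
  expect_equal(diag(M3), rep(0, 3), ignore_attr = TRUE)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(M3[i, j],
                 superpose(frame_coords(conf[[j]]), frame_coords(conf[[i]]))$rmsd,
                 tolerance = 1e-12)
})

test_that("subspace overlap is 1 on itself, 0 across disjoint eigenvector blocks, and span-invariant", {
  fx <- hinge_modes(seed = 4, n_modes = 25L)
  m <- fx$modes
  self <- subspace_overlap(m, m)
  expect_equal(self$a_onto_b, rep(1, 25), tolerance = 1e-9)
  expect_equal(self$b_onto_a, rep(1, 25), tolerance = 1e-9)

  lowm <- m; lowm$values <- m$values[1:10]; lowm$vectors <- m$vectors[, 1:10]
  high <- m; high$values <- m$values[11:25]; high$vectors <- m$vectors[, 11:25]
  dis <- subspace_overlap(lowm, high)
  expect_lt(max(dis$a_onto_b), 1e-10)
  expect_lt(max(dis$b_onto_a), 1e-10)

  # invariance of the a->b profile to an orthonormal re-basing of set b
  set.seed(8)
  Qr <- qr.Q(qr(matrix(rnorm(625), 25, 25)))
  reb <- m; reb$vectors <- m$vectors %*% Qr
  ov1 <- subspace_overlap(m, m)
  ov2 <- subspace_overlap(m, reb)
  expect_equal(ov2$a_onto_b, ov1$a_onto_b, tolerance = 1e-10)
  expect_true(all(ov2$a_onto_b >= -1e-9 & ov2$a_onto_b <= 1 + 1e-9))
})

test_that("mean overlap is symmetric for equal-dimension spans on the same atom support", {
  fx <- hinge_modes(seed = 6, n_modes = 10L)
  pert <- perturb_along_modes(fx$structure, fx$modes,
                              c("1" = 1.5, "4" = -1.0), seed = 2)
  net2 <- build_network(pert$structure, cutoff = 10)
  m2 <- compute_modes(net2, n_modes = 10L)
  ov <- subspace_overlap(fx$modes, m2, k_average = 10L)
  expect_equal(mean(ov$a_onto_b), mean(ov$b_onto_a), tolerance = 1e-10)
})

test_that("a displacement along one mode is attributed entirely to that mode", {
  fx <- hinge_modes(seed = 1)
  pert <- perturb_along_modes(fx$structure, fx$modes, c("7" = 0.8), seed = 1)
  fit <- transition_fit(fx$modes, pert$structure)
  expect_equal(fit$coefficients[7], 0.8, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[-7])), 1e-8)
  expect_lt(fit$rmsd_final, 1e-9)
  expect_equal(fit$fraction_reduced, 1, tolerance = 1e-8)
  # the identical pair decomposes to nothing
  null <- transition_fit(fx$modes, fx$structure)
  expect_equal(null$rmsd0, 0)
  expect_lt(max(abs(null$coefficients)), 1e-10)
})

test_that("the cumulative curve matches independent per-k least squares and is monotone", {
  set.seed(19)
  st <- random_walk_structure(40)
  net <- build_network(st, cutoff = 10)
  m <- compute_modes(net, n_modes = 20L)
  target <- structure3d(st$atoms,
                        frame_coords(st) + matrix(rnorm(120, sd = 0.4), ncol = 3))
  fit <- transition_fit(m, target)
  np <- fit$n_paired
  # independent: generic dense least squares per k on the restricted modes
  xa <- m$coords[fit$pairing$idx_a, ]
  d <- as.vector(t(fit$target_fitted - xa))
  rows <- as.vector(outer(1:3, 3 * (fit$pairing$idx_a - 1), `+`))
  U <- m$vectors[rows, ]
  for (k in c(1, 3, 7, 20)) {
    beta <- qr.solve(U[, 1:k, drop = FALSE], d)
    res <- sqrt(sum((d - U[, 1:k, drop = FALSE] %*% beta)^2) / np)
    expect_equal(fit$rmsd_k[k + 1], res, tolerance = 1e-10)
  }
  expect_true(all(diff(fit$rmsd_k) <= 1e-12))
  expect_equal(fit$rmsd0, superpose(frame_coords(target), frame_coords(st))$rmsd,
               tolerance = 1e-12)
})

test_that("the complete mode basis reproduces any conformation of the same atoms", {
  set.seed(23)
  st <- random_walk_structure(20)
  net <- build_network(st, cutoff = 10)
  m <- compute_modes(net, blocks = make_blocks(net, "atom"), n_modes = 54L)
  target <- structure3d(st$atoms,
                        frame_coords(st) + matrix(rnorm(60, sd = 0.5), ncol = 3))
  fit <- transition_fit(m, target)
  expect_lt(fit$rmsd_final, 1e-8)
})

test_that("transition paths start at the input, end at the fitted displacement, and approach the target monotonically", {
  fx <- hinge_modes(seed = 9)
  pert <- perturb_along_modes(fx$structure, fx$modes,
                              c("2" = 1.2, "5" = 0.7), seed = 3)
  fit <- transition_fit(fx$modes, pert$structure)
  path <- transition_path(fit, n_frames = 11)
  expect_identical(frame_coords(path, 1), fx$modes$coords)
  xa_rows <- fit$pairing$idx_a
  end_rmsd <- sqrt(sum((frame_coords(path, 11)[xa_rows, ] -
                          fit$target_fitted)^2) / fit$n_paired)
  expect_equal(end_rmsd, fit$rmsd_final, tolerance = 1e-9)
  per_frame <- vapply(1:11, function(k)
    sqrt(sum((frame_coords(path, k)[xa_rows, ] - fit$target_fitted)^2) /
           fit$n_paired), 0)
  expect_true(all(diff(per_frame) <= 1e-12))
  # screw variant exists and also starts exactly at the input
  scr <- transition_path(fit, n_frames = 5, extrapolation = "screw")
  expect_identical(frame_coords(scr, 1), fx$modes$coords)
})

test_that("noise-free conformers generated along known modes are recovered exactly", {
  fx <- hinge_modes(seed = 12)
  cf <- c("1" = 0.9, "3" = -0.6, "8" = 0.4)
  pert <- perturb_along_modes(fx$structure, fx$modes, cf, seed = 1)
  fit <- transition_fit(fx$modes, pert$structure)
  expect_equal(fit$coefficients[c(1, 3, 8)], unname(cf), tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[-c(1, 3, 8)])), 1e-8)
  # >99.9% of the decrease on the true modes
  solo_true <- sum(fit$solo[c(1, 3, 8)])
  expect_gt(solo_true / sum(fit$solo), 0.999)
})
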