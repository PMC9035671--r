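# PDB reading/writing, selections, pairing and superposition.

test_that("single- and multi-model PDB files parse with atoms in file order", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  st <- read_pdb(f)
  expect_equal(n_frames(st), 1L)
  expect_equal(n_atoms(st), 3L)
  expect_equal(st$atoms$elety, c("N", "CA", "C"))
  expect_equal(frame_coords(st)[2, ], c(1.458, 0, 0))
  # masses from element
  expect_equal(st$atoms$mass, c(14.007, 12.011, 12.011))

  two <- c("MODEL        1", pdb[1:3], "ENDMDL",
           "MODEL        2",
           sub("0.000   0.000   0.000", "0.000   0.000   1.000", pdb[1]),
           pdb[2:3], "ENDMDL", "END")
  writeLines(two, f)
  st2 <- read_pdb(f)
  expect_equal(n_frames(st2), 2L)
  expect_equal(frame_coords(st2, 2)[1, 3], 1)
})

test_that("write/read round trip preserves identities exactly and coordinates to PDB precision", {
  set.seed(101)
  for (frames in c(1L, 10L)) {
    st <- random_walk_structure(15)
    xyz <- lapply(seq_len(frames), function(k)
      frame_coords(st) + matrix(rnorm(45, sd = 0.5), ncol = 3))
    st <- structure3d(st$atoms, xyz)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(st, f)
    lines <- readLines(f)
    expect_equal(sum(grepl("^MODEL", lines)), if (frames > 1) frames else 0L)
    back <- read_pdb(f)
    expect_equal(n_frames(back), frames)
    expect_identical(back$atoms$elety, st$atoms$elety)
    expect_identical(back$atoms$resno, st$atoms$resno)
    expect_identical(back$atoms$chain, st$atoms$chain)
    for (k in seq_len(frames))
      expect_lt(max(abs(frame_coords(back, k) - frame_coords(st, k))), 1e-3)
  }
})

test_that("altloc policy keeps the highest-occupancy location", {
  pdb <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  st <- read_pdb(f)
  expect_equal(n_atoms(st), 2L)
  expect_equal(frame_coords(st)[1, 1], 9)   # occupancy 0.60 wins
})

test_that("coordinates exceeding the PDB field width are rejected on write", {
  st <- make_helix(3)
  st$xyz[[1]][1, 1] <- 12345.0
  expect_error(write_pdb(st, withr::local_tempfile(fileext = ".pdb")),
               "field width")
})

test_that("selections resolve to increasing indices and match a linear scan", {
  st <- make_helix(5, atoms_per_residue = 2)
  idx <- resolve_selection(st, atom_selection(elety = "CA"))
  expect_equal(length(idx), 5L)
  expect_true(all(diff(idx) > 0))
  idx2 <- resolve_selection(st, atom_selection(resno = 2:3))
  expect_equal(sort(unique(st$atoms$resno[idx2])), 2:3)
  expect_equal(length(idx2), 4L)
  expect_error(resolve_selection(st, atom_selection(chain = "Z")),
               "matched no atoms")

  # combined chain+range+name filter on a 4-chain fixture vs brute force
  set.seed(7)
  chains <- lapply(c("A", "B", "C", "D"), function(ch) {
    s <- random_walk_structure(12, chain = ch)
    s$atoms$elety <- rep(c("CA", "CB", "N"), each = 4)
    s
  })
  atoms <- do.call(rbind, lapply(chains, `[[`, "atoms"))
  atoms$serial <- seq_len(nrow(atoms))
  st4 <- structure3d(atoms, do.call(rbind, lapply(chains, frame_coords)))
  sel <- atom_selection(chain = c("B", "D"), resno = 3:9, elety = c("CA", "N"))
  got <- resolve_selection(st4, sel)
  want <- which(st4$atoms$chain %in% c("B", "D") &
                st4$atoms$resno %in% 3:9 &
                st4$atoms$elety %in% c("CA", "N"))
  expect_identical(got, want)
})

test_that("atom pairing matches the set intersection of identities", {
  a <- make_helix(20)
  pr <- pair_common_atoms(a, a)
  expect_identical(pr$idx_a, pr$idx_b)
  expect_equal(length(pr$idx_a), 20L)

  # drop residue 7 from one side
  b <- subset_atoms(a, setdiff(seq_len(20), 7))
  pr2 <- pair_common_atoms(a, b)
  expect_false(7 %in% a$atoms$resno[pr2$idx_a])
  expect_equal(length(pr2$idx_a), 19L)

  # random 20% deletions on each side vs hash-join oracle
  set.seed(11)
  keep_a <- sort(sample(20, 16)); keep_b <- sort(sample(20, 16))
  pa <- subset_atoms(a, keep_a); pb <- subset_atoms(a, keep_b)
  pr3 <- pair_common_atoms(pa, pb)
  want <- intersect(paste(pa$atoms$chain, pa$atoms$resno, pa$atoms$elety),
                    paste(pb$atoms$chain, pb$atoms$resno, pb$atoms$elety))
  expect_setequal(paste(pa$atoms$chain[pr3$idx_a], pa$atoms$resno[pr3$idx_a],
                        pa$atoms$elety[pr3$idx_a]), want)
  expect_error(pair_common_atoms(a, make_helix(5, chain = "Q")),
               "no atoms common")
})

test_that("Kabsch superposition recovers rigid motions and matches a quaternion oracle", {
  set.seed(5)
  A <- matrix(rnorm(150), ncol = 3)
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  # 90 degrees about z plus translation: exact recovery
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  B <- sweep(A %*% t(Rz), 2, c(3, -1, 2), `+`)
  fit <- superpose(B, A)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation %*% Rz, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # random clouds vs the quaternion oracle, plus symmetry
  for (rep in 1:5) {
    P <- matrix(rnorm(150), ncol = 3)
    Q <- matrix(rnorm(150), ncol = 3)
    expect_equal(superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-10)
    expect_equal(superpose(P, Q)$rmsd, superpose(Q, P)$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(superpose(A[1:4, ], A[1:5, ]), "equal size")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition onto any proper rigid image of a set gives zero RMSD", {
  set.seed(21)
  for (rep in 1:5) {
    A <- matrix(rnorm(90), ncol = 3)
    st <- structure3d(data.frame(elety = "CA", resno = 1:30), A)
    B <- frame_coords(rigid_transform(st, axis = rnorm(3), angle = runif(1, 0, pi),
                                      shift = rnorm(3, sd = 10)))
    expect_lt(superpose(B, A)$rmsd, 1e-9)
  }
})
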