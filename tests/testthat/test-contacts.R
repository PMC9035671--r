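# Interface contacts, conservation series, interface tables, distance series.

test_that("residue pairs are in contact iff their minimum heavy-atom distance is within the cutoff", {
  atoms <- data.frame(elety = c("CA", "CB", "CA", "CB"),
                      chain = c("A", "A", "B", "B"),
                      resno = c(1, 1, 1, 1), serial = 1:4)
  st <- structure3d(atoms, rbind(c(0, 0, 0), c(1.5, 0, 0),
                                 c(4.5, 0, 0), c(6.0, 0, 0)))
  cm <- compute_contacts(st, atom_selection(chain = "A"),
                         atom_selection(chain = "B"), cutoff = 4.5)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$dist, 3.0)           # CB(A1) to CA(B1)

  far <- structure3d(atoms, rbind(c(0, 0, 0), c(1.5, 0, 0),
                                  c(7.5, 0, 0), c(9.0, 0, 0)))
  cm2 <- compute_contacts(far, atom_selection(chain = "A"),
                          atom_selection(chain = "B"), cutoff = 4.5)
  expect_equal(nrow(cm2), 0L)

  expect_error(compute_contacts(st, atom_selection(chain = "A"),
                                atom_selection(resno = 1), cutoff = 4.5),
               "overlap")
})

test_that("contact maps equal the brute-force all-pairs oracle on random two-chain fixtures", {
  set.seed(44)
  for (rep in 1:3) {
    a <- random_walk_structure(15, chain = "A")
    b <- random_walk_structure(15, chain = "B")
    xb <- frame_coords(b); xb[, 1] <- xb[, 1] + runif(1, 6, 10)
    bt <- b$atoms; bt$serial <- bt$serial + 15
    st <- structure3d(rbind(a$atoms, bt), rbind(frame_coords(a), xb))
    cm <- compute_contacts(st, atom_selection(chain = "A"),
                           atom_selection(chain = "B"), cutoff = 6)
    oracle <- brute_force_contacts(st, atom_selection(chain = "A"),
                                   atom_selection(chain = "B"), 6)
    got <- if (nrow(cm) > 0) paste("A", cm$resno_a, "B", cm$resno_b)
           else character(0)
    expect_setequal(got, as.character(names(oracle)))
    if (nrow(cm) > 0)
      expect_equal(cm$dist[order(got)],
                   unlist(oracle)[sort(got)], tolerance = 1e-12,
                   ignore_attr = TRUE)
  }
})

test_that("conservation is 1 at the reference and steps exactly with a constructed break schedule", {
  st <- ladder_structure(10)
  selA <- atom_selection(chain = "A"); selB <- atom_selection(chain = "B")
  ref <- compute_contacts(st, selA, selB, cutoff = 4.5)
  expect_equal(nrow(ref), 10L)                # exactly the rungs
  expect_equal(ref$resno_a, ref$resno_b)
  # break half of the reference pairs at frame 10
  sched <- data.frame(chain_a = "A", resno_a = 1:5, chain_b = "B",
                      resno_b = 1:5, event = "break", frame = 10)
  traj <- make_contact_trajectory(st, selA, selB, schedule = sched,
                                  n_frames = 15, cutoff = 4.5, jitter = 0,
                                  seed = 1)
  cs <- contact_conservation(traj$structure, selA, selB, cutoff = 4.5)
  expect_identical(cs$fraction, c(rep(1, 9), rep(0.5, 6)))
  # empty schedule, zero jitter: fraction 1 at every frame
  quiet <- make_contact_trajectory(st, selA, selB, n_frames = 8,
                                   cutoff = 4.5, jitter = 0, seed = 1)
  csq <- contact_conservation(quiet$structure, selA, selB, cutoff = 4.5)
  expect_identical(csq$fraction, rep(1, 8))
})

test_that("per-frame conservation equals brute-force recomputation on a jittered trajectory", {
  st <- two_chain_structure(8)
  selA <- atom_selection(chain = "A"); selB <- atom_selection(chain = "B")
  traj <- make_contact_trajectory(st, selA, selB, n_frames = 6, cutoff = 6,
                                  jitter = 0.4, seed = 9)
  cs <- contact_conservation(traj$structure, selA, selB, cutoff = 6)
  ref <- brute_force_contacts(traj$structure, selA, selB, 6, frame = 1)
  for (t in 1:6) {
    now <- brute_force_contacts(traj$structure, selA, selB, 6, frame = t)
    expect_equal(cs$fraction[t],
                 sum(names(ref) %in% names(now)) / length(ref))
    expect_equal(cs$n_contacts[t], length(now))
  }
})

test_that("interface tables group partners by residue and tally motifs against a manual count", {
  st <- two_chain_structure(12)
  cm <- compute_contacts(st, atom_selection(chain = "A"),
                         atom_selection(chain = "B"), cutoff = 6.5)
  motifs <- data.frame(motif = c("m1", "m2", "m3"),
                       chain = c("A", "A", "B"),
                       start = c(1, 7, 1), end = c(6, 12, 12))
  it <- interface_table(cm, motifs)
  expect_true(all(table(paste(it$residues$chain, it$residues$resno)) == 1))
  # every A residue 1..6 involved is labelled m1, 7..12 m2, all B m3
  ra <- it$residues[it$residues$chain == "A", ]
  expect_true(all(ra$motif[ra$resno <= 6] == "m1"))
  expect_true(all(ra$motif[ra$resno >= 7] == "m2"))
  manual_m1 <- sum(cm$resno_a <= 6)
  counts <- it$motif_counts
  expect_equal(counts$Freq[counts$motif == "m1"], manual_m1)
  expect_equal(sum(it$residues$n_partners[it$residues$chain == "A"]),
               nrow(cm))
  bad <- data.frame(motif = c("x", "y"), chain = "A",
                    start = c(1, 4), end = c(5, 9))
  expect_error(interface_table(cm, bad), "overlap")
})

test_that("atom-pair distance series follow motion and centred smoothing matches a loop oracle", {
  base <- two_chain_structure(5)
  frames <- lapply(0:9, function(t) {
    co <- frame_coords(base)
    co[1, 1] <- co[1, 1] - t       # atom 1 walks away 1 A per frame
    co
  })
  tr <- structure3d(base$atoms, frames)
  a1 <- list(chain = "A", resno = 1, elety = "CA")
  a2 <- list(chain = "B", resno = 1, elety = "CA")
  ds <- atom_pair_distance(tr, a1, a2)
  expect_equal(diff(ds$dist), rep(1, 9), tolerance = 1e-12)

  static <- structure3d(base$atoms, rep(list(frame_coords(base)), 4))
  expect_equal(diff(atom_pair_distance(static, a1, a2)$dist), rep(0, 3))

  set.seed(2)
  noisy_frames <- lapply(1:12, function(t)
    frame_coords(base) + matrix(rnorm(30, sd = 0.3), ncol = 3))
  noisy <- structure3d(base$atoms, noisy_frames)
  sm <- atom_pair_distance(noisy, a1, a2, smoothing_window = 5)
  d <- atom_pair_distance(noisy, a1, a2)$dist
  oracle <- vapply(1:12, function(t) mean(d[max(1, t - 2):min(12, t + 2)]), 0)
  expect_equal(sm$dist_smooth, oracle, tolerance = 1e-12)

  expect_error(atom_pair_distance(tr, list(chain = "Q", resno = 1, elety = "CA"), a2),
               "not found")
})

test_that("conservation fractions are invariant under rigid motion of whole frames", {
  st <- two_chain_structure(9)
  selA <- atom_selection(chain = "A"); selB <- atom_selection(chain = "B")
  traj <- make_contact_trajectory(st, selA, selB, n_frames = 5, cutoff = 6,
                                  jitter = 0.3, seed = 4)
  cs <- contact_conservation(traj$structure, selA, selB, cutoff = 6)
  moved <- rigid_transform(traj$structure)
  cs2 <- contact_conservation(moved, selA, selB, cutoff = 6)
  expect_equal(cs2$fraction, cs$fraction, tolerance = 1e-12)
  expect_equal(cs2$n_contacts, cs$n_contacts)
})
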