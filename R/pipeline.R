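# Pipeline entry points: one function per analysis stage, each writing
# tab-separated tables (single '#' header line) plus a run log, and a thin
# command-line dispatcher.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Serialise a mode set to a plain-text container
#'
#' Sections: a provenance header, eigenvalues, the atom table, equilibrium
#' coordinates, block assignment, and the mode matrix (one row of m values
#' per Cartesian degree of freedom). Numbers are written with 17 significant
#' digits, so rereading reproduces the mode set to full double precision and
#' rewriting is byte-identical.
#'
#' @param modes a `mode_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modeset <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- modes$provenance
  writeLines(c(
    "# modecomp mode_set v1",
    paste("# cutoff", fmt_num(p$cutoff)),
    paste("# mass_weighted", p$mass_weighted),
    paste("# n_blocks", p$n_blocks),
    paste("# reduced_dim", p$reduced_dim),
    paste("# n_zero", modes$n_zero),
    paste("# n_atoms", nrow(modes$coords)),
    paste("# n_modes", length(modes$values)),
    "EIGENVALUES", fmt_num(modes$values),
    "ZERO_EIGENVALUES", fmt_num(modes$zero_values),
    "ATOMS"), con)
  a <- modes$atoms
  writeLines(paste(a$serial, a$elety, a$elesy, a$resid, a$chain, a$resno,
                   ifelse(nzchar(a$insert), a$insert, "."),
                   fmt_num(a$mass), sep = "\t"), con)
  writeLines("COORDS", con)
  writeLines(apply(modes$coords, 1L, function(r)
    paste(fmt_num(r), collapse = "\t")), con)
  writeLines("BLOCKS", con)
  writeLines(as.character(modes$blocks), con)
  writeLines("VECTORS", con)
  writeLines(apply(modes$vectors, 1L, function(r)
    paste(fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' Read a serialised mode set
#' @param path a file written by [write_modeset()].
#' @return a `mode_set`.
#' @export
read_modeset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]
    sub(paste0("^# ", key, " "), "", ln)
  }
  sec <- function(name) which(lines == name)[1]
  n_atoms <- as.integer(getv("n_atoms"))
  n_modes <- as.integer(getv("n_modes"))
  n_zero <- as.integer(getv("n_zero"))
  ev <- as.numeric(lines[(sec("EIGENVALUES") + 1L):(sec("ZERO_EIGENVALUES") - 1L)])
  zv <- as.numeric(lines[(sec("ZERO_EIGENVALUES") + 1L):(sec("ATOMS") - 1L)])
  at_lines <- lines[(sec("ATOMS") + 1L):(sec("COORDS") - 1L)]
  at <- utils::read.table(text = at_lines, sep = "\t",
                          col.names = c("serial", "elety", "elesy", "resid",
                                        "chain", "resno", "insert", "mass"),
                          colClasses = c("integer", "character", "character",
                                         "character", "character", "integer",
                                         "character", "numeric"))
  at$insert[at$insert == "."] <- ""
  co <- do.call(rbind, lapply(lines[(sec("COORDS") + 1L):(sec("BLOCKS") - 1L)],
                              function(l) as.numeric(strsplit(l, "\t")[[1]])))
  blocks <- as.integer(lines[(sec("BLOCKS") + 1L):(sec("VECTORS") - 1L)])
  vec <- do.call(rbind, lapply(lines[(sec("VECTORS") + 1L):length(lines)],
                               function(l) as.numeric(strsplit(l, "\t")[[1]])))
  stopifnot(nrow(co) == n_atoms, length(ev) == n_modes,
            nrow(vec) == 3L * n_atoms)
  structure(list(
    values = ev, frequencies = sqrt(pmax(ev, 0)), vectors = vec,
    n_zero = n_zero, zero_values = zv, coords = co, mass = at$mass,
    atoms = at, blocks = blocks,
    provenance = list(cutoff = as.numeric(getv("cutoff")),
                      mass_weighted = as.logical(getv("mass_weighted")),
                      n_blocks = as.integer(getv("n_blocks")),
                      reduced_dim = as.integer(getv("reduced_dim")))
  ), class = "mode_set")
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

run_log <- function(out_dir, command, params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c(
    paste("command:", command),
    paste("modecomp version:",
          as.character(utils::packageVersion("modecomp"))),
    paste("R version:", R.version.string),
    vapply(names(params), function(k)
      paste0(k, ": ", paste(format(params[[k]]), collapse = " ")), "")
  )
  writeLines(lines, file.path(out_dir, paste0(command, ".log")))
}

.sel_from_args <- function(chain = NULL, resno = NULL, elety = NULL) {
  atom_selection(chain = chain, resno = resno, elety = elety)
}

#' Compute and serialise normal modes for a structure
#'
#' @param input path to a PDB file.
#' @param out_dir output directory.
#' @param cutoff interaction cutoff in Angstrom.
#' @param n_modes number of modes requested (clamped to the available
#'   non-rigid degrees of freedom).
#' @param ca_only use a C-alpha network instead of all heavy atoms.
#' @param mass_weighted use atomic masses.
#' @param animate_modes indices of modes to animate (linear and screw
#'   multi-model PDBs); empty for none.
#' @param amplitude_rmsd peak RMSD of the animations.
#' @return the `mode_set`, invisibly; writes `modes.txt` (+ animations).
#' @export
run_modes <- function(input, out_dir, cutoff = 10, n_modes = 100L,
                      ca_only = FALSE, mass_weighted = TRUE,
                      animate_modes = integer(0), amplitude_rmsd = 2) {
  st <- read_pdb(input)
  sel <- if (ca_only) atom_selection(elety = "CA") else NULL
  net <- build_network(st, sel, cutoff = cutoff)
  avail <- with(compute_modes_avail(net), n_avail)
  nm <- min(n_modes, avail)
  modes <- compute_modes(net, n_modes = nm, mass_weighted = mass_weighted)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_modeset(modes, file.path(out_dir, "modes.txt"))
  for (k in animate_modes) {
    lin <- extrapolate_mode_linear(modes, k, amplitude_rmsd)
    scr <- extrapolate_mode_nonlinear(modes, k, amplitude_rmsd)
    write_pdb(lin, file.path(out_dir, sprintf("mode%03d_linear.pdb", k)))
    write_pdb(scr, file.path(out_dir, sprintf("mode%03d_screw.pdb", k)))
  }
  run_log(out_dir, "modes",
          list(input = input, cutoff = cutoff, n_modes = nm,
               ca_only = ca_only, mass_weighted = mass_weighted))
  invisible(modes)
}

# number of non-rigid RTB degrees of freedom available for a network
compute_modes_avail <- function(network, blocks = NULL) {
  if (is.null(blocks)) blocks <- make_blocks(network)
  dof <- 0L
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    dof <- dof + ncol(.block_basis(network$coords[idx, , drop = FALSE],
                                   network$mass[idx]))
  }
  nr <- ncol(.block_basis(network$coords, network$mass))
  list(n_avail = dof - nr, reduced_dim = dof, n_rigid = nr)
}

#' Subspace-overlap comparison of two serialised mode sets
#'
#' @param modes_a,modes_b paths to files written by [write_modeset()].
#' @param out_dir output directory.
#' @param k_average leading-mode count for the average overlap.
#' @return the `overlap_profile`, invisibly; writes `overlap.tsv`.
#' @export
run_compare <- function(modes_a, modes_b, out_dir, k_average = 10L) {
  ma <- read_modeset(modes_a); mb <- read_modeset(modes_b)
  ov <- subspace_overlap(ma, mb, k_average = k_average)
  df <- data.frame(mode = seq_along(ov$a_onto_b),
                   lambda_a = ov$values_a[seq_along(ov$a_onto_b)],
                   a_onto_b = ov$a_onto_b,
                   lambda_b = ov$values_b[seq_along(ov$b_onto_a)],
                   b_onto_a = ov$b_onto_a)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(df, file.path(out_dir, "overlap.tsv"))
  run_log(out_dir, "compare",
          list(modes_a = modes_a, modes_b = modes_b,
               k_average = k_average,
               mean_a_onto_b = ov$mean_a_onto_b,
               mean_b_onto_a = ov$mean_b_onto_a))
  invisible(ov)
}

#' Transition decomposition between two structures
#'
#' @param modes_file serialised mode set of the starting state.
#' @param target_pdb PDB of the end state.
#' @param out_dir output directory.
#' @param n_modes modes to use (default all).
#' @param n_frames frames in the path animation.
#' @param extrapolation `"linear"` or `"screw"`.
#' @return the `transition_fit`, invisibly; writes `transition.tsv` and
#'   `path.pdb`.
#' @export
run_transition <- function(modes_file, target_pdb, out_dir, n_modes = NULL,
                           n_frames = 20L,
                           extrapolation = c("linear", "screw")) {
  modes <- read_modeset(modes_file)
  target <- read_pdb(target_pdb)
  fit <- transition_fit(modes, target, n_modes = n_modes)
  m <- fit$n_modes
  df <- data.frame(
    k = 0:m,
    rmsd_k = fit$rmsd_k,
    marginal = c(NA, fit$marginal),
    solo = c(NA, fit$solo),
    coefficient = c(NA, fit$coefficients),
    cumulative_fraction = c(0, (fit$rmsd0 - fit$rmsd_k[-1]) /
                              max(fit$rmsd0, 1e-300))
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(df, file.path(out_dir, "transition.tsv"))
  path <- transition_path(fit, n_frames = n_frames,
                          extrapolation = match.arg(extrapolation))
  write_pdb(path, file.path(out_dir, "path.pdb"))
  run_log(out_dir, "transition",
          list(modes = modes_file, target = target_pdb, n_modes = m,
               rmsd0 = fit$rmsd0, rmsd_final = fit$rmsd_final,
               fraction_reduced = fit$fraction_reduced))
  invisible(fit)
}

#' Pairwise RMSD matrix over several structures
#'
#' @param inputs character vector of PDB paths (>= 2).
#' @param out_dir output directory.
#' @param chain,resno,elety selection criteria (default C-alpha atoms).
#' @return the matrix, invisibly; writes `rmsd_matrix.tsv`.
#' @export
run_rmsd_matrix <- function(inputs, out_dir, chain = NULL, resno = NULL,
                            elety = "CA") {
  states <- lapply(inputs, read_pdb)
  names(states) <- basename(inputs)
  M <- rmsd_matrix(states, .sel_from_args(chain, resno, elety))
  df <- data.frame(state = rownames(M), as.data.frame(M, optional = TRUE),
                   check.names = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(df, file.path(out_dir, "rmsd_matrix.tsv"))
  run_log(out_dir, "rmsd-matrix", list(inputs = inputs))
  invisible(M)
}

#' Interface contact conservation along a trajectory
#'
#' @param input multi-model PDB path.
#' @param out_dir output directory.
#' @param chain_a,chain_b chains defining the two interface sides.
#' @param cutoff contact cutoff in Angstrom.
#' @param reference_frame reference frame index.
#' @param time_per_frame frame-to-time scale.
#' @param motif_file optional TSV (columns motif, chain, start, end) for the
#'   interface table.
#' @return the `contact_series`, invisibly; writes `conservation.tsv`,
#'   `contacts.tsv` and (given motifs) `interface.tsv`.
#' @export
run_contacts <- function(input, out_dir, chain_a, chain_b, cutoff = 4.5,
                         reference_frame = 1L, time_per_frame = 1,
                         motif_file = NULL) {
  st <- read_pdb(input)
  sa <- atom_selection(chain = chain_a)
  sb <- atom_selection(chain = chain_b)
  series <- contact_conservation(st, sa, sb, cutoff = cutoff,
                                 reference_frame = reference_frame,
                                 time_per_frame = time_per_frame)
  ref <- attr(series, "reference")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(series), file.path(out_dir, "conservation.tsv"))
  write_tsv(as.data.frame(ref), file.path(out_dir, "contacts.tsv"))
  if (!is.null(motif_file)) {
    motifs <- utils::read.table(motif_file, header = TRUE, sep = "\t",
                                comment.char = "", stringsAsFactors = FALSE)
    names(motifs) <- sub("^X?\\.?", "", names(motifs))
    it <- interface_table(ref, motifs)
    write_tsv(it$residues, file.path(out_dir, "interface.tsv"))
  }
  run_log(out_dir, "contacts",
          list(input = input, chain_a = chain_a, chain_b = chain_b,
               cutoff = cutoff, reference_frame = reference_frame))
  invisible(series)
}

#' Atom-pair distance series along a trajectory
#'
#' @param input multi-model PDB path.
#' @param out_dir output directory.
#' @param atom1,atom2 `"chain:resno:name"` strings.
#' @param smoothing_window centred running-mean width (odd).
#' @return the `distance_series`, invisibly; writes `distance.tsv`.
#' @export
run_distance <- function(input, out_dir, atom1, atom2,
                         smoothing_window = 1L) {
  parse_atom <- function(s) {
    p <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(p) != 3L) stop("atom spec must be chain:resno:name, got ", s)
    list(chain = p[1], resno = as.integer(p[2]), elety = p[3])
  }
  st <- read_pdb(input)
  ds <- atom_pair_distance(st, parse_atom(atom1), parse_atom(atom2),
                           smoothing_window = smoothing_window)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(ds), file.path(out_dir, "distance.tsv"))
  run_log(out_dir, "distance", list(input = input, atom1 = atom1,
                                    atom2 = atom2))
  invisible(ds)
}

#' Generate the synthetic demonstration fixtures
#'
#' Writes a helix PDB, a two-domain hinge PDB, a mode-displaced conformer
#' pair, and a contact-schedule trajectory with a register-shift event,
#' together with a ground-truth sidecar.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @return invisibly, the list of generated objects.
#' @export
run_simulate <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  helix <- make_helix(40)
  write_pdb(helix, file.path(out_dir, "helix.pdb"))
  hinge <- make_two_domain_hinge(20, seed = seed)
  write_pdb(hinge, file.path(out_dir, "hinge.pdb"))
  net <- build_network(hinge, cutoff = 10)
  modes <- compute_modes(net, n_modes = 20L)
  pert <- perturb_along_modes(hinge, modes, c("1" = 2.0), seed = seed)
  write_pdb(pert$structure, file.path(out_dir, "hinge_displaced.pdb"))
  traj <- make_contact_trajectory(
    two_chain_fixture(seed), atom_selection(chain = "A"),
    atom_selection(chain = "B"),
    schedule = NULL, n_frames = 20L, seed = seed)
  write_pdb(traj$structure, file.path(out_dir, "trajectory.pdb"))
  truth <- c(
    "# ground truth for the simulated fixtures",
    paste("seed:", seed),
    paste("hinge_displaced modes:", paste(pert$truth$modes, collapse = ",")),
    paste("hinge_displaced coefficients:",
          paste(fmt_num(pert$truth$coefficients), collapse = ",")),
    paste("hinge_displaced expected_ca_rmsd:",
          fmt_num(pert$truth$expected_ca_rmsd))
  )
  writeLines(truth, file.path(out_dir, "ground_truth.txt"))
  run_log(out_dir, "simulate", list(seed = seed))
  invisible(list(helix = helix, hinge = hinge, perturbed = pert,
                 trajectory = traj))
}

# small two-chain structure used by run_simulate: two parallel helices
two_chain_fixture <- function(seed = 1L) {
  a <- make_helix(12, chain = "A")
  b <- make_helix(12, chain = "B")
  xb <- frame_coords(b)
  xb[, 1] <- xb[, 1] + 8
  structure3d(rbind(a$atoms, transform(b$atoms, serial = serial + n_atoms(a))),
              rbind(frame_coords(a), xb))
}

#' Command-line dispatcher
#'
#' Subcommands: `modes`, `compare`, `transition`, `rmsd-matrix`, `contacts`,
#' `distance`, `simulate`. Options are `--key value` flags; `--config
#' file.yaml` supplies defaults that flags override. Intended for
#' `Rscript -e 'modecomp::modecomp_cli()'` or the installed `exec/modecomp`
#' wrapper.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
modecomp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: modecomp <modes|compare|transition|rmsd-matrix|",
            "contacts|distance|simulate> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    k <- sub("^--", "", rest[i])
    opts[[k]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (!is.null(opts$config)) {
    cfg <- yaml::read_yaml(opts$config)
    for (k in names(cfg)) if (is.null(opts[[k]])) opts[[k]] <- cfg[[k]]
  }
  num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  chr <- function(k, d = NULL) if (is.null(opts[[k]])) d else opts[[k]]
  out <- chr("out", "modecomp_out")
  status <- tryCatch({
    switch(cmd,
      "modes" = run_modes(chr("input"), out, cutoff = num("cutoff", 10),
                          n_modes = num("n-modes", 100),
                          ca_only = isTRUE(as.logical(chr("ca-only", "FALSE")))),
      "compare" = run_compare(chr("modes-a"), chr("modes-b"), out,
                              k_average = num("k-average", 10)),
      "transition" = run_transition(chr("modes"), chr("target"), out,
                                    n_modes = if (is.null(opts[["n-modes"]]))
                                      NULL else num("n-modes", NULL)),
      "rmsd-matrix" = run_rmsd_matrix(strsplit(chr("inputs"), ",")[[1]], out),
      "contacts" = run_contacts(chr("input"), out, chr("chain-a"),
                                chr("chain-b"), cutoff = num("cutoff", 4.5),
                                reference_frame = num("reference-frame", 1),
                                motif_file = chr("motifs")),
      "distance" = run_distance(chr("input"), out, chr("atom1"),
                                chr("atom2"),
                                smoothing_window = num("smooth", 1)),
      "simulate" = run_simulate(out, seed = num("seed", 1)),
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
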