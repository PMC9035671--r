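# Interface contact analysis over multi-frame structures: residue-residue
# contact maps, conservation relative to a reference frame, per-motif
# interface composition, and atom-pair distance series.

#' Residue-residue contacts between two atom groups in one frame
#'
#' A residue pair is in contact when the minimum heavy-atom distance between
#' the two residues is at or below `cutoff`. The two selections must be
#' disjoint at the atom level.
#'
#' @param x a [structure3d()].
#' @param selection_a,selection_b [atom_selection()]s defining the two sides
#'   of the interface.
#' @param cutoff contact cutoff in Angstrom (default 4.5, the standard
#'   heavy-atom contact convention; use e.g. 6 or 8 to match alternative
#'   definitions).
#' @param frame which frame to analyse (default 1).
#' @return a `contact_map`: data frame with the residue identities of both
#'   sides and the per-pair minimum distance `dist`, plus the cutoff and
#'   frame as attributes.
#' @export
compute_contacts <- function(x, selection_a, selection_b, cutoff = 4.5,
                             frame = 1L) {
  stopifnot(inherits(x, "structure3d"), cutoff > 0)
  ia <- resolve_selection(x, selection_a)
  ib <- resolve_selection(x, selection_b)
  if (length(intersect(ia, ib)) > 0L)
    stop("selections overlap at the atom level; interface sides must be disjoint")
  co <- frame_coords(x, frame)
  prs <- cross_neighbor_pairs(co[ia, , drop = FALSE], co[ib, , drop = FALSE],
                              cutoff)
  ra <- residue_key(x$atoms)[ia[prs$i]]
  rb <- residue_key(x$atoms)[ib[prs$j]]
  pair_key <- paste(ra, rb, sep = "::")
  if (nrow(prs) > 0L) {
    mind <- tapply(prs$d, pair_key, min)
    keys <- names(mind)
    sides <- strsplit(keys, "::", fixed = TRUE)
    pa <- strsplit(vapply(sides, `[`, "", 1L), "|", fixed = TRUE)
    pb <- strsplit(vapply(sides, `[`, "", 2L), "|", fixed = TRUE)
    df <- data.frame(
      chain_a = vapply(pa, `[`, "", 1L),
      resno_a = as.integer(vapply(pa, `[`, "", 2L)),
      insert_a = vapply(pa, function(p) if (length(p) >= 3L) p[3L] else "", ""),
      chain_b = vapply(pb, `[`, "", 1L),
      resno_b = as.integer(vapply(pb, `[`, "", 2L)),
      insert_b = vapply(pb, function(p) if (length(p) >= 3L) p[3L] else "", ""),
      dist = as.vector(mind),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$chain_a, df$resno_a, df$chain_b, df$resno_b), ]
    rownames(df) <- NULL
  } else {
    df <- data.frame(chain_a = character(0), resno_a = integer(0),
                     insert_a = character(0), chain_b = character(0),
                     resno_b = integer(0), insert_b = character(0),
                     dist = numeric(0), stringsAsFactors = FALSE)
  }
  attr(df, "cutoff") <- cutoff
  attr(df, "frame") <- frame
  class(df) <- c("contact_map", "data.frame")
  df
}

contact_pair_keys <- function(cmap) {
  paste(cmap$chain_a, cmap$resno_a, cmap$insert_a,
        cmap$chain_b, cmap$resno_b, cmap$insert_b, sep = "|")
}

#' Conservation of reference contacts along a trajectory
#'
#' The contact map of the reference frame defines the reference pair set; for
#' every frame, the conserved fraction is the share of reference pairs still
#' in contact, and the total cross-group contact count is reported alongside
#' (newly formed contacts enter the count but not the fraction).
#'
#' @inheritParams compute_contacts
#' @param reference_frame frame defining the reference contact set (default 1).
#' @param time_per_frame optional scale mapping frame index to time (frame 1
#'   is time 0).
#' @param window optional integer vector of frames over which to report the
#'   window-mean conserved fraction.
#' @return a `contact_series`: data frame with `frame`, `time`, `fraction`,
#'   `n_contacts`; attributes `reference` (the reference `contact_map`) and
#'   `window_mean`.
#' @export
contact_conservation <- function(x, selection_a, selection_b, cutoff = 4.5,
                                 reference_frame = 1L, time_per_frame = 1,
                                 window = NULL) {
  stopifnot(inherits(x, "structure3d"))
  if (reference_frame < 1L || reference_frame > n_frames(x))
    stop("reference_frame out of range")
  ref <- compute_contacts(x, selection_a, selection_b, cutoff, reference_frame)
  if (nrow(ref) == 0L)
    stop("reference frame has no contacts between the two selections")
  ref_keys <- contact_pair_keys(ref)
  nf <- n_frames(x)
  fraction <- numeric(nf); count <- integer(nf)
  for (t in seq_len(nf)) {
    cm <- compute_contacts(x, selection_a, selection_b, cutoff, t)
    keys <- contact_pair_keys(cm)
    fraction[t] <- sum(ref_keys %in% keys) / length(ref_keys)
    count[t] <- nrow(cm)
  }
  out <- data.frame(frame = seq_len(nf),
                    time = (seq_len(nf) - 1L) * time_per_frame,
                    fraction = fraction, n_contacts = count)
  attr(out, "reference") <- ref
  attr(out, "reference_frame") <- reference_frame
  if (!is.null(window))
    attr(out, "window_mean") <- mean(fraction[window])
  class(out) <- c("contact_series", "data.frame")
  out
}

#' Per-residue interface composition with motif annotation
#'
#' @param cmap a `contact_map`.
#' @param motifs data frame with columns `motif`, `chain`, `start`, `end`
#'   mapping residue ranges to motif names; ranges on the same chain must not
#'   overlap. Residues outside every range are labelled `NA`.
#' @return list with `residues` (one row per interface residue: chain, resno,
#'   motif, number of partners, partner list) and `motif_counts` (contacts
#'   per motif).
#' @export
interface_table <- function(cmap, motifs = NULL) {
  stopifnot(inherits(cmap, "contact_map"))
  if (!is.null(motifs)) {
    stopifnot(all(c("motif", "chain", "start", "end") %in% names(motifs)))
    for (ch in unique(motifs$chain)) {
      m <- motifs[motifs$chain == ch, , drop = FALSE]
      if (nrow(m) > 1L) {
        o <- order(m$start)
        if (any(m$end[o][-nrow(m)] >= m$start[o][-1L]))
          stop("motif annotation ranges overlap on chain ", ch)
      }
    }
  }
  label <- function(chain, resno) {
    if (is.null(motifs)) return(rep(NA_character_, length(chain)))
    vapply(seq_along(chain), function(i) {
      hit <- motifs$chain == chain[i] & motifs$start <= resno[i] &
        motifs$end >= resno[i]
      if (any(hit)) motifs$motif[which(hit)[1L]] else NA_character_
    }, "")
  }
  side <- function(chain, resno, pchain, presno) {
    key <- paste(chain, resno)
    rows <- !duplicated(key)
    partners <- vapply(key[rows], function(k) {
      sel <- key == k
      paste(paste0(pchain[sel], ":", presno[sel]), collapse = ",")
    }, "")
    data.frame(chain = chain[rows], resno = resno[rows],
               motif = label(chain[rows], resno[rows]),
               n_partners = as.vector(table(key)[key[rows]]),
               partners = partners, stringsAsFactors = FALSE)
  }
  res <- rbind(side(cmap$chain_a, cmap$resno_a, cmap$chain_b, cmap$resno_b),
               side(cmap$chain_b, cmap$resno_b, cmap$chain_a, cmap$resno_a))
  res <- res[order(res$chain, res$resno), ]
  rownames(res) <- NULL
  ml <- label(cmap$chain_a, cmap$resno_a)
  ml_b <- label(cmap$chain_b, cmap$resno_b)
  counts <- table(motif = c(ml, ml_b), useNA = "ifany")
  list(residues = res,
       motif_counts = as.data.frame(counts, stringsAsFactors = FALSE))
}

#' Distance between two atoms along a trajectory
#'
#' @param x a [structure3d()].
#' @param atom1,atom2 atom specifications: lists (or named vectors) with
#'   `chain`, `resno` and `elety`.
#' @param smoothing_window odd integer; width of a centred running mean
#'   (edges use the available partial window). Default 1 (no smoothing).
#' @return a `distance_series` data frame with `frame` and `dist` (and
#'   `dist_smooth` when smoothing is requested).
#' @export
atom_pair_distance <- function(x, atom1, atom2, smoothing_window = 1L) {
  stopifnot(inherits(x, "structure3d"))
  find <- function(spec) {
    spec <- as.list(spec)
    hit <- which(x$atoms$chain == as.character(spec$chain) &
                 x$atoms$resno == as.integer(spec$resno) &
                 x$atoms$elety == as.character(spec$elety))
    if (length(hit) != 1L)
      stop("atom ", spec$chain, ":", spec$resno, ":", spec$elety,
           if (length(hit) == 0L) " not found" else " is ambiguous")
    hit
  }
  i <- find(atom1); j <- find(atom2)
  d <- vapply(x$xyz, function(m) sqrt(sum((m[i, ] - m[j, ])^2)), 0)
  out <- data.frame(frame = seq_along(d), dist = d)
  w <- as.integer(smoothing_window)
  if (w > 1L) {
    if (w %% 2L == 0L) stop("smoothing_window must be odd")
    h <- (w - 1L) %/% 2L
    n <- length(d)
    out$dist_smooth <- vapply(seq_len(n), function(t)
      mean(d[max(1L, t - h):min(n, t + h)]), 0)
  }
  class(out) <- c("distance_series", "data.frame")
  out
}
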