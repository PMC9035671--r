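# Fixed-radius neighbour search by cell-list binning. Linear-time in
# expectation for roughly uniform densities; results identical to the
# all-pairs definition (asserted against a brute-force oracle in the tests).

# integer cell coordinates for each point, cells of edge `cutoff`
.cells <- function(coords, origin, cutoff) {
  g <- floor(sweep(coords, 2L, origin) / cutoff)
  storage.mode(g) <- "integer"
  g
}

.cell_id <- function(g, dims) {
  g[, 1L] + dims[1L] * (g[, 2L] + dims[2L] * g[, 3L])
}

# the half-space of neighbour offsets (13 of 26) plus the self cell,
# enumerating each unordered cell pair once
.half_offsets <- local({
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- off[, 3L] > 0 | (off[, 3L] == 0 & (off[, 2L] > 0 |
          (off[, 2L] == 0 & off[, 1L] > 0)))
  off[keep, , drop = FALSE]
})

#' Pairs of points within a cutoff distance (single set)
#'
#' @param coords N x 3 matrix.
#' @param cutoff distance cutoff in the same units as `coords`.
#' @return data frame with columns `i`, `j` (`i < j`) and `d` (distance),
#'   ordered by (`i`, `j`).
#' @keywords internal
neighbor_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  origin <- apply(coords, 2L, min)
  g <- .cells(coords, origin, cutoff)
  dims <- apply(g, 2L, max) + 2L      # +2: room for +1 offsets, avoids wrap
  id <- .cell_id(g, dims)
  by_cell <- split(seq_len(n), id)
  occupied <- g[!duplicated(id), , drop = FALSE]
  occ_id <- id[!duplicated(id)]
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L

  add_pairs <- function(ii, jj) {
    if (length(ii) == 0L) return()
    d2 <- rowSums((coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE])^2)
    keep <- d2 <= cutoff^2
    if (any(keep)) {
      k <<- k + 1L
      out_i[[k]] <<- ii[keep]; out_j[[k]] <<- jj[keep]
      out_d[[k]] <<- sqrt(d2[keep])
    }
  }

  for (c_idx in seq_along(occ_id)) {
    a <- by_cell[[as.character(occ_id[c_idx])]]
    # within-cell pairs
    if (length(a) > 1L) {
      cmb <- utils::combn(a, 2L)
      add_pairs(cmb[1L, ], cmb[2L, ])
    }
    # half-space neighbour cells
    for (r in seq_len(nrow(.half_offsets))) {
      ng <- occupied[c_idx, ] + .half_offsets[r, ]
      nid <- ng[1L] + dims[1L] * (ng[2L] + dims[2L] * ng[3L])
      b <- by_cell[[as.character(nid)]]
      if (!is.null(b)) {
        grid <- expand.grid(a = a, b = b)
        add_pairs(grid$a, grid$b)
      }
    }
  }
  if (k == 0L) return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  i <- unlist(out_i); j <- unlist(out_j); d <- unlist(out_d)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  o <- order(i, j)
  data.frame(i = i[o], j = j[o], d = d[o])
}

#' Pairs of points within a cutoff distance across two sets
#'
#' @param a,b coordinate matrices.
#' @param cutoff distance cutoff.
#' @return data frame with columns `i` (index into `a`), `j` (index into `b`)
#'   and `d`, ordered by (`i`, `j`).
#' @keywords internal
cross_neighbor_pairs <- function(a, b, cutoff) {
  na <- nrow(a); nb <- nrow(b)
  empty <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  if (na == 0L || nb == 0L) return(empty)
  origin <- pmin(apply(a, 2L, min), apply(b, 2L, min))
  ga <- .cells(a, origin, cutoff)
  gb <- .cells(b, origin, cutoff)
  dims <- pmax(apply(ga, 2L, max), apply(gb, 2L, max)) + 2L
  idb <- .cell_id(gb, dims)
  by_cell_b <- split(seq_len(nb), idb)
  res_i <- list(); res_j <- list(); res_d <- list(); k <- 0L
  all_off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(na)) {
    cand <- integer(0)
    for (r in seq_len(nrow(all_off))) {
      ng <- ga[i, ] + all_off[r, ]
      if (any(ng < 0L)) next
      nid <- ng[1L] + dims[1L] * (ng[2L] + dims[2L] * ng[3L])
      bb <- by_cell_b[[as.character(nid)]]
      if (!is.null(bb)) cand <- c(cand, bb)
    }
    if (length(cand) == 0L) next
    d2 <- rowSums(sweep(b[cand, , drop = FALSE], 2L, a[i, ])^2)
    keep <- d2 <= cutoff^2
    if (any(keep)) {
      k <- k + 1L
      res_i[[k]] <- rep.int(i, sum(keep))
      res_j[[k]] <- cand[keep]
      res_d[[k]] <- sqrt(d2[keep])
    }
  }
  if (k == 0L) return(empty)
  i <- unlist(res_i); j <- unlist(res_j); d <- unlist(res_d)
  o <- order(i, j)
  data.frame(i = i[o], j = j[o], d = d[o])
}
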