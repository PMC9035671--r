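# Least-squares rigid-body superposition (Kabsch algorithm).

#' Superpose one coordinate set onto another
#'
#' Finds the proper rotation `R` and translation `t` minimising the sum of
#' squared distances between `mobile %*% t(R) + t` and `target` (Kabsch
#' algorithm via SVD of the cross-covariance). Reflections are excluded.
#'
#' @param mobile,target N x 3 coordinate matrices of paired points, N >= 3,
#'   not all collinear.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd` (Angstrom) and `coords` (the transformed mobile set).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("mobile and target must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(target, 2L, ct)
  for (M in list(P, Q)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] <= 1e-9 * max(sv[1], 1e-300))
      stop("degenerate (collinear or coincident) point set: ",
           "superposition is not unique")
  }
  C <- crossprod(P, Q)                    # sum_i p_i q_i^T
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  fitted <- sweep(fitted, 2L, ct, `+`)
  rmsd <- sqrt(sum((fitted - target)^2) / n)
  list(rotation = R, translation = as.vector(ct - R %*% cm),
       rmsd = rmsd, coords = fitted)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b N x 3 matrices.
#' @param fit superpose first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = TRUE) {
  if (fit) return(superpose(a, b)$rmsd)
  sqrt(sum((as.matrix(a) - as.matrix(b))^2) / nrow(a))
}
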