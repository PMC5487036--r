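# Rigid-body superposition and internal-coordinate atom placement.

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)

#' Place an atom from internal coordinates (NERF construction)
#'
#' Positions atom D such that `|D - c| = bond`, the angle b-c-D equals
#' `angle` and the dihedral a-b-c-D equals `dihedral` (degrees).
#'
#' @param a,b,c Reference positions (numeric length-3).
#' @param bond Bond length c-D (Angstrom).
#' @param angle Bond angle b-c-D (degrees).
#' @param dihedral Torsion a-b-c-D (degrees).
#' @return Numeric length-3 position of D.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Least-squares superposition of `mob` onto `ref` via singular value
#' decomposition of the covariance matrix, constrained to a proper
#' rotation (determinant +1).
#'
#' @param ref,mob Numeric matrices, `n x 3`, in corresponding order.
#' @return List with `rotation` (3x3, applied to centred mobile
#'   coordinates), `translation` (length 3), `rmsd` (Angstrom) and
#'   `fitted` (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(ref, mob) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  stopifnot(ncol(ref) == 3, ncol(mob) == 3)
  if (nrow(ref) != nrow(mob)) stop("point sets differ in size")
  if (nrow(ref) < 3) stop("superposition needs at least 3 points")
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(mob, 2, cm)  # centred mobile
  Q <- sweep(ref, 2, cr)  # centred reference
  if (max(abs(P)) < 1e-9 || max(abs(Q)) < 1e-9) {
    stop("degenerate (collapsed) point set")
  }
  H <- crossprod(P, Q)    # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop("degenerate geometry: singular covariance")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # rotation applied to centred mobile rows
  fitted <- P %*% t(R)
  fitted <- sweep(fitted, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  list(rotation = R, translation = cr - as.vector(R %*% cm), rmsd = rmsd,
       fitted = fitted)
}

#' Pairwise-minimum distance between two coordinate sets
#' @param a,b Numeric `n x 3` matrices.
#' @return Smallest Euclidean distance between a row of `a` and of `b`.
#' @export
min_cross_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

cross_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
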