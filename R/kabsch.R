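#' Optimal rigid-body superposition of two point sets
#'
#' Computes the minimum root-mean-square deviation (RMSD) between two
#' conformations of the same ordered point set over all proper rigid
#' transformations (rotation + translation), using the Kabsch singular value
#' decomposition algorithm. Used throughout the package to assign structural
#' alphabet letters to 4-Calpha fragments.
#'
#' @param mobile Numeric n x 3 matrix of coordinates to superpose (nm).
#' @param reference Numeric n x 3 matrix of target coordinates (nm); must be
#'   non-degenerate (not all points identical).
#' @return A list with elements
#'   \describe{
#'     \item{rmsd}{minimum RMSD (nm)}
#'     \item{rotation}{3 x 3 proper rotation matrix `R` (det = +1) such that
#'       `sweep(mobile, 2, cm) %*% t(R)` best matches the centred reference,
#'       where `cm` is the mobile centroid}
#'     \item{translation}{reference centroid minus rotated mobile centroid}
#'   }
#' @examples
#' frag <- matrix(c(0, 0, 0, 0.38, 0, 0, 0.76, 0, 0, 1.14, 0.1, 0), 4, 3,
#'                byrow = TRUE)
#' kabsch_superpose(frag, frag)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    abort("`mobile` and `reference` must be n x 3 matrices of equal size.")
  }
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    abort("Coordinates must be finite.")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)     # centred mobile
  Q <- sweep(reference, 2, cr)  # centred reference
  if (sum(Q^2) < 1e-20) {
    abort("Degenerate reference fragment: all points identical.")
  }
  H <- crossprod(P, Q)          # 3 x 3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- P %*% t(R)
  rmsd <- sqrt(sum((rot - Q)^2) / nrow(P))
  list(rmsd = rmsd, rotation = R, translation = cr)
}

## RMSD only, skipping checks: hot loop of the encoder.
.kabsch_rmsd <- function(P, Q) {
  # P, Q already centred 4x3
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  # E = sum(P^2) + sum(Q^2) - 2 * (s1 + s2 + d*s3)
  e <- sum(P^2) + sum(Q^2) - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])
  sqrt(max(e, 0) / nrow(P))
}
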