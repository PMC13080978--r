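# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Least-squares rigid superposition (Kabsch)
#'
#' Rotation and translation minimizing the RMSD of `mobile` onto `fixed`.
#' Proper rotation enforced (determinant +1).
#'
#' @param mobile,fixed n x 3 coordinate matrices, row-matched.
#' @return list with `R` (3x3 rotation), `t` (translation), and `coords`
#'   (superposed mobile coordinates).
#' @keywords internal
#' @noRd
kabsch <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3L)
  if (nrow(mobile) < 3L) stop("need at least 3 atoms for superposition")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  coords <- A %*% t(R)
  coords <- sweep(coords, 2, cf, `+`)
  list(R = R, t = cf - as.vector(R %*% cm), coords = coords)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniformly distributed random rotation matrix (from random quaternion).
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# All-pairs Euclidean distances between rows of two coordinate matrices.
cross_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# data.frame constructor without validation overhead (columns must be
# equal-length atomic vectors).
quickdf <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = c(NA_integer_, -length(lst[[1]])))
}

vec_angle <- function(u, v) {
  cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
  if (cu == 0 || cv == 0) return(NA_real_)
  acos(pmin(1, pmax(-1, sum(u * v) / (cu * cv)))) * 180 / pi
}
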