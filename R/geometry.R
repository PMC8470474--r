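# Rigid-body superposition and rotation-axis extraction.
#
# The optimal rotation is the orthogonal-Procrustes solution computed from the
# SVD of the covariance matrix, with reflections excluded by sign-correcting
# the smallest singular direction.

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)

# Least-squares rigid fit mapping x onto y (both n x 3).
# Returns rotation R and translation t with  y ~ x %*% t(R) + t.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) < 3) stop("need at least 3 point pairs")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))          # H = Xc' Yc
  d <- sign(det(s$v %*% t(s$u)))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("singular configuration: points are (nearly) collinear")
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  rmsd <- sqrt(mean(rowSums((xc %*% t(R) - yc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

new_superposition <- function(R, t, rmsd, n_pairs, centroids = NULL,
                              pairs = NULL, refined = FALSE) {
  structure(list(rotation = R, translation = t, rmsd = rmsd,
                 n_pairs = n_pairs, centroids = centroids, pairs = pairs,
                 refined = refined),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd %.3f A over %d Ca pairs%s\n",
              x$rmsd, x$n_pairs, if (isTRUE(x$refined)) " (refined)" else ""))
  invisible(x)
}

#' Rigid superposition of two paired point sets
#'
#' Least-squares rigid fit (rotation + translation, reflection excluded)
#' mapping `x` onto `y`. This is the primitive behind [superpose()]; exposed
#' for direct use on raw coordinates.
#'
#' @param x,y n x 3 matrices of paired coordinates (Angstrom).
#' @return a `SuperpositionResult`: rotation (3 x 3, det +1), translation
#'   (length 3), `rmsd` over the pairs after fitting, `n_pairs`, and
#'   `centroids` (list of the two input centroids).
#' @export
superpose_xyz <- function(x, y) {
  k <- kabsch(x, y)
  new_superposition(k$rotation, k$translation, k$rmsd, nrow(x),
                    centroids = list(colMeans(x), colMeans(y)))
}

rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  cosang <- max(-1, min(1, (tr - 1) / 2))
  a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  if (vnorm(a) > 1e-8) {
    v <- unit(a)
    ang <- atan2(vnorm(a), cosang) * 180 / pi   # in (0, 180]
  } else if (cosang > 0) {                      # identity
    return(list(angle = 0, axis = c(0, 0, 1)))
  } else {                                      # 180 degrees: R + I = 2 vv'
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    v <- unit(M[, j])
    ang <- 180
  }
  list(angle = ang, axis = v)
}

#' Extract the symmetry axis of a superposition
#'
#' Converts the rigid transform of a protodomain-onto-protodomain (or
#' chain-onto-chain) superposition into an axis report: rotation angle,
#' unit axis direction, screw translation along the axis, and a point on the
#' axis (the one nearest the midpoint of the two input centroids). The axis is
#' labelled `"C2"` when the angle falls within `config$c2_angle_tol` of 180
#' degrees; a near-identity transform (angle below `config$no_axis_angle`)
#' yields a typed no-axis result rather than an error.
#'
#' @param sp a `SuperpositionResult`.
#' @param paired_centroids optional list of two 3-vectors; defaults to the
#'   centroids stored in `sp`.
#' @param config see [igproto_config()].
#' @return an object of class `SymmetryAxis`: list with `found`, `direction`
#'   (unit 3-vector), `point` (3-vector, Angstrom), `angle` (degrees, in
#'   (-180, 180]), `screw` (Angstrom), `order_label`.
#' @export
symmetry_axis <- function(sp, paired_centroids = NULL, config = igproto_config()) {
  stopifnot(inherits(sp, "SuperpositionResult"))
  if (is.null(paired_centroids)) paired_centroids <- sp$centroids
  aa <- rotation_angle_axis(sp$rotation)
  if (abs(aa$angle) < config$no_axis_angle) {
    return(structure(list(found = FALSE, direction = NULL, point = NULL,
                          angle = aa$angle, screw = NA_real_,
                          order_label = "none"),
                     class = "SymmetryAxis"))
  }
  v <- aa$axis
  t <- sp$translation
  screw <- sum(t * v)
  # point on axis: (I - R) p = t - screw v; (I - R) is singular along v, so
  # add vv' (p is chosen with zero component along v, then slid to the
  # centroid midpoint).
  M <- diag(3) - sp$rotation + tcrossprod(v)
  p0 <- as.numeric(solve(M, t - screw * v))
  mid <- (paired_centroids[[1]] + paired_centroids[[2]]) / 2
  point <- p0 + sum((mid - p0) * v) * v
  order_label <- if (abs(aa$angle) >= 180 - config$c2_angle_tol) "C2" else
    sprintf("rotation(%.0f)", aa$angle)
  structure(list(found = TRUE, direction = v, point = point,
                 angle = aa$angle, screw = screw, order_label = order_label),
            class = "SymmetryAxis")
}

#' @export
print.SymmetryAxis <- function(x, ...) {
  if (!isTRUE(x$found)) { cat("SymmetryAxis: none (near-identity)\n"); return(invisible(x)) }
  cat(sprintf("SymmetryAxis %s: angle %.2f deg, screw %.3f A, direction (%.3f, %.3f, %.3f)\n",
              x$order_label, x$angle, x$screw,
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

# acute angle (deg) between two directions, ignoring sign
line_angle <- function(u, v) {
  ca <- abs(sum(unit(u) * unit(v)))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# signed angle (deg) between two vectors
vec_angle <- function(u, v) {
  ca <- sum(unit(u) * unit(v))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# distance from point p to the line (point q, direction v)
point_line_dist <- function(p, q, v) {
  v <- unit(v); w <- p - q
  vnorm(w - sum(w * v) * v)
}

# minimal distance between two lines (point p, direction u) and (q, v)
line_line_dist <- function(p, u, q, v) {
  n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  if (vnorm(n) < 1e-8) return(point_line_dist(p, q, v))
  abs(sum((p - q) * n)) / vnorm(n)
}
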