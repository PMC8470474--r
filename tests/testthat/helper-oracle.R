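# Independent superposition oracle: numeric minimization of the RMSD over
# rotations parameterized by unit quaternions (multi-start BFGS). Used to
# cross-check the closed-form fit; never calls the package's own solver.
quaternion_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; a <- q[2]; b <- q[3]; cc <- q[4]
    matrix(c(1 - 2 * (b^2 + cc^2), 2 * (a * b - cc * w), 2 * (a * cc + b * w),
             2 * (a * b + cc * w), 1 - 2 * (a^2 + cc^2), 2 * (b * cc - a * w),
             2 * (a * cc - b * w), 2 * (b * cc + a * w), 1 - 2 * (a^2 + b^2)),
           3, 3, byrow = TRUE)
  }
  f <- function(q) { R <- rot(q); sqrt(mean(rowSums((xc %*% t(R) - yc)^2))) }
  best <- Inf
  for (init in list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
                    c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1), c(.5, .5, .5, .5)))
    best <- min(best, stats::optim(init, f, method = "BFGS",
                                   control = list(maxit = 500, reltol = 1e-14))$value)
  best
}

random_rotation <- function() {
  th <- stats::runif(1, 0, 2 * pi)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# apply a rigid motion to a whole StructureModel
move_structure <- function(st, R, t) {
  m <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  m <- sweep(m, 2, t, FUN = "+")
  st$atoms$x <- m[, 1]; st$atoms$y <- m[, 2]; st$atoms$z <- m[, 3]
  st
}
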