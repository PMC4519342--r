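## Independent oracles kept deliberately separate from the package's own
## code paths.

## Brute-force minimal RMSD over rotations: quaternion grid search with
## local refinement via optim. Slow but independent of the SVD route.
brute_force_rmsd <- function(a, b, n_coarse = 8) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rot_from_angles <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    rx %*% ry %*% rz
  }
  msd <- function(p) {
    r <- rot_from_angles(p)
    mean(rowSums((a %*% r - b)^2))
  }
  grid <- seq(0, 2 * pi, length.out = n_coarse + 1)[-(n_coarse + 1)]
  best <- Inf; best_p <- c(0, 0, 0)
  for (p1 in grid) for (p2 in grid) for (p3 in grid) {
    v <- msd(c(p1, p2, p3))
    if (v < best) { best <- v; best_p <- c(p1, p2, p3) }
  }
  opt <- stats::optim(best_p, msd, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  sqrt(opt$value)
}

## Direct (ungridded) sum of corrected kernels at probe points.
direct_bias_sum <- function(points, centers, sigma, height,
                            domain_lo = 0, domain_hi = 32,
                            weights = NULL, corrected = TRUE) {
  weights <- weights %||% rep(1, length(centers))
  vapply(points, function(p) {
    g <- height * exp(-((p - centers) / sigma)^2 / 2)
    if (corrected) {
      pc <- min(max(p, domain_lo), domain_hi)
      g <- g / (pnorm((domain_hi - pc) / sigma) - pnorm((domain_lo - pc) / sigma))
    }
    sum(weights * g)
  }, 0)
}

## A random rigid motion (rotation + translation), seeded.
random_rigid_motion <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]),
                 cos(th[3]), 0, 0, 0, 1), 3, 3)
  list(R = rx %*% ry %*% rz, t = runif(3, -2, 2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

kT310 <- 2.5775

## Basin free-energy difference (left vs right of `divide`) of a 1D fes
## object or analytic values on the same axis.
basin_delta_f <- function(values, axis, divide = 16, kT = kT310) {
  w <- exp(-ifelse(is.na(values), Inf, values) / kT)
  -kT * log(sum(w[axis < divide]) / sum(w[axis >= divide]))
}
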