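#' Analytic toy potentials on CV space
#'
#' Toy free-energy landscapes standing in for the molecular landscape in
#' desk-scale runs: a sum of Gaussian wells on the CV domain, or minus
#' kT log of a Gaussian-mixture density matched to a synthetic ensemble.
#' Both carry an analytic evaluator, so estimated free energies can be
#' compared against quadrature-exact references.
#'
#' @param centers Well centres: vector (1D) or matrix with one row per
#'   well (2D).
#' @param depths Well depths in kJ/mol (> 0; wells are attractive).
#' @param widths Gaussian width per well (CV units).
#' @param dims Dimensionality (1 or 2), inferred from `centers`.
#' @param domain_lo,domain_hi Sampling domain per dimension (default
#'   \[0, 32\]).
#' @return A `toy_potential` object; call it on points via
#'   [potential_energy()].
#' @examples
#' pot <- toy_potential_wells(centers = c(8, 24), depths = c(20, 17), widths = 3)
#' potential_energy(pot, c(8, 16, 24))
#' @export
toy_potential_wells <- function(centers, depths, widths,
                                dims = NULL, domain_lo = 0, domain_hi = 32) {
  if (is.matrix(centers)) {
    dims <- dims %||% ncol(centers)
  } else {
    dims <- dims %||% 1L
    centers <- matrix(centers, ncol = dims)
  }
  k <- nrow(centers)
  depths <- rep_len(depths, k)
  widths <- rep_len(widths, k)
  stopifnot(all(depths > 0), all(widths > 0))
  structure(list(kind = "wells", dims = as.integer(dims), centers = centers,
                 depths = depths, widths = widths,
                 domain_lo = rep_len(domain_lo, dims),
                 domain_hi = rep_len(domain_hi, dims)),
            class = "toy_potential")
}

#' @rdname toy_potential_wells
#' @param states List of synthetic-ensemble states (see
#'   [synthetic_ensemble_spec()]): the potential is
#'   `-kT log(sum_k pop_k N(s; cv_mean_k, cv_spread_k))`, so a sampler at
#'   temperature `kT` reproduces the ensemble's state populations.
#' @param kT Thermal energy in kJ/mol.
#' @export
toy_potential_mixture <- function(states, kT = KT_310,
                                  domain_lo = 0, domain_hi = 32) {
  dims <- length(states[[1]]$cv_mean)
  structure(list(kind = "mixture", dims = as.integer(dims), states = states,
                 kT = kT,
                 domain_lo = rep_len(domain_lo, dims),
                 domain_hi = rep_len(domain_hi, dims)),
            class = "toy_potential")
}

#' @rdname toy_potential_wells
#' @param potential A `toy_potential`.
#' @param point One point (vector) or many (matrix rows, or plain vector
#'   in 1D).
#' @return `potential_energy()`: energy in kJ/mol per point.
#' @export
potential_energy <- function(potential, point) {
  d <- potential$dims
  pts <- if (is.matrix(point)) point else
    matrix(point, ncol = d, byrow = d > 1)
  if (potential$kind == "wells") {
    u <- rep(0, nrow(pts))
    for (k in seq_len(nrow(potential$centers))) {
      z2 <- rep(0, nrow(pts))
      for (j in seq_len(d)) {
        z2 <- z2 + ((pts[, j] - potential$centers[k, j]) /
                      potential$widths[k])^2
      }
      u <- u - potential$depths[k] * exp(-z2 / 2)
    }
    u
  } else {
    dens <- rep(0, nrow(pts))
    for (st in potential$states) {
      z2 <- rep(0, nrow(pts))
      spread <- rep_len(st$cv_spread, d)
      for (j in seq_len(d)) {
        z2 <- z2 + ((pts[, j] - st$cv_mean[j]) / spread[j])^2
      }
      dens <- dens + st$population * exp(-z2 / 2) / prod(spread)
    }
    -potential$kT * log(pmax(dens, 1e-300))
  }
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential> ", x$kind, ", ", x$dims, "D on [",
      paste(x$domain_lo, collapse = ","), "] .. [",
      paste(x$domain_hi, collapse = ","), "]\n", sep = "")
  invisible(x)
}

## ---- FES grid spec ------------------------------------------------------

#' Free-energy-surface grid specification
#'
#' The FES and all binned observables live on a regular grid of points over
#' the CV domain: by default 160 points per dimension from 0 to 32, the
#' grid on which the reference analysis tabulates its surfaces. Frames are
#' assigned to the nearest grid point.
#'
#' @param dims 1 or 2.
#' @param n Points per dimension.
#' @param lo,hi Domain per dimension.
#' @return A `fes_grid` spec.
#' @export
fes_grid <- function(dims = 2L, n = 160L, lo = 0, hi = 32) {
  dims <- as.integer(dims)
  stopifnot(dims %in% c(1L, 2L), n >= 2, hi > lo)
  axes <- lapply(seq_len(dims), function(d) seq(lo, hi, length.out = n))
  structure(list(dims = dims, n = as.integer(n), lo = lo, hi = hi,
                 dx = (hi - lo) / (n - 1), axes = axes),
            class = "fes_grid")
}

## nearest-node bin index per dimension, clipped to [1, n]
fes_bin_index <- function(grid, x) {
  pmin(pmax(as.integer(round((x - grid$lo) / grid$dx)) + 1L, 1L), grid$n)
}

#' Exact free-energy surface of a toy potential
#'
#' Tabulates the analytic potential on an FES grid (free energy equals the
#' potential up to a constant for a sampler in CV space), or its 1D
#' marginal `-kT log integral exp(-U/kT)` by trapezoidal quadrature over
#' the other coordinate. The minimum is shifted to zero.
#'
#' @param potential A [toy_potential_wells()] / [toy_potential_mixture()].
#' @param grid A [fes_grid()] matching the requested output dimension.
#' @param kT Thermal energy (kJ/mol), used only for marginalisation.
#' @param marginal_of For a 2D potential and 1D grid: which coordinate to
#'   keep (1 = alpha, 2 = beta).
#' @param n_quad Quadrature points for marginalisation.
#' @return A `fes` object (see [fes_from_bias_history()]).
#' @export
exact_fes <- function(potential, grid = fes_grid(dims = potential$dims),
                      kT = KT_310, marginal_of = 1L, n_quad = 2001L) {
  if (grid$dims == potential$dims) {
    pts <- if (grid$dims == 1L) matrix(grid$axes[[1]], ncol = 1) else
      as.matrix(expand.grid(a = grid$axes[[1]], b = grid$axes[[2]]))
    vals <- potential_energy(potential, pts)
    values <- if (grid$dims == 1L) vals else matrix(vals, grid$n, grid$n)
  } else if (potential$dims == 2L && grid$dims == 1L) {
    other <- if (marginal_of == 1L) 2L else 1L
    yq <- seq(potential$domain_lo[other], potential$domain_hi[other],
              length.out = n_quad)
    dy <- yq[2] - yq[1]
    values <- vapply(grid$axes[[1]], function(x) {
      pts <- matrix(0, n_quad, 2)
      pts[, marginal_of] <- x
      pts[, other] <- yq
      u <- potential_energy(potential, pts)
      w <- exp(-(u - min(u)) / kT)
      -kT * (log(sum(w) - (w[1] + w[n_quad]) / 2) + log(dy)) + min(u)
    }, 0)
  } else {
    abort("cannot expand a 1D potential onto a 2D grid")
  }
  new_fes(grid, values - min(values),
          visited = array(TRUE, dim = c(grid$n, if (grid$dims == 2L) grid$n)),
          kT = kT)
}
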