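#' Free-energy surfaces from the time-averaged bias
#'
#' In metadynamics the accumulated bias tends to the negative of the free
#' energy; averaging the bias over the whole run, rather than taking its
#' final value, suppresses the hill-by-hill fluctuations. Because hills
#' are deposited instantaneously at times `t_k`, the time average of the
#' cumulative bias over `[t_start, t_end]` collapses to a weighted hill
#' sum: hill `k` contributes with weight
#' `(t_end - max(t_k, t_start)) / (t_end - t_start)`. The estimator is
#' `F(s) = -<V(s, t)>_t`, shifted so the minimum over visited nodes is 0.
#' Nodes outside every hill's truncation support are flagged unvisited
#' and carry `NA` free energy rather than a fabricated value.
#'
#' @param hills A hills tibble ([hills_tibble()]) from the replica biased
#'   along the CV(s) of interest (for a 2D surface, the doubly-biased one).
#' @param grid An [fes_grid()] (defaults to 160 points over \[0, 32\] per
#'   hill dimension).
#' @param t_start,t_end Averaging window in ps; defaults to the full hill
#'   record starting at 0.
#' @param kT Thermal energy (kJ/mol) stored for later probability
#'   conversion; 2.5775 kJ/mol at 310 K.
#' @param corrected Evaluate hills with the boundary correction
#'   (default TRUE).
#' @param trunc_sigma Hill truncation radius in sigmas.
#' @return A `fes` object: grid axes, free-energy values in kJ/mol
#'   (`NA` where unvisited), a visited mask, and `kT`.
#' @export
fes_from_bias_history <- function(hills, grid = NULL, t_start = 0,
                                  t_end = NULL, kT = KT_310,
                                  corrected = TRUE, trunc_sigma = 6) {
  if (!is.data.frame(hills) || nrow(hills) == 0) {
    abort("need at least one hill to estimate a free-energy surface")
  }
  dims <- if ("center_alpha" %in% names(hills)) 2L else 1L
  grid <- grid %||% fes_grid(dims = dims)
  stopifnot(grid$dims == dims)
  t_end <- t_end %||% max(hills$time)
  if (t_start >= t_end) abort("t_start must precede t_end")
  keep <- hills$time <= t_end
  if (!any(keep)) abort("no hills inside the averaging window")
  hills <- hills[keep, ]
  w <- (t_end - pmax(hills$time, t_start)) / (t_end - t_start)

  ## accumulate the weighted bias on a bias_grid congruent with the FES grid
  acc <- bias_grid(dims = dims, lower = grid$lo, upper = grid$hi,
                   n_nodes = grid$n, domain_lo = grid$lo, domain_hi = grid$hi)
  acc <- deposit_hills(acc, hills, weights = w, corrected = corrected,
                       trunc_sigma = trunc_sigma)
  visited <- visited_mask(grid, hills, trunc_sigma)
  values <- -acc$values
  values[!visited] <- NA_real_
  values <- values - min(values, na.rm = TRUE)
  new_fes(grid, values, visited, kT)
}

## nodes within trunc_sigma of any hill centre
visited_mask <- function(grid, hills, trunc_sigma = 6) {
  h <- as_hill_matrix(hills, grid$dims)
  if (grid$dims == 1L) {
    vis <- rep(FALSE, grid$n)
    for (k in seq_len(nrow(h$centers))) {
      vis <- vis | abs(grid$axes[[1]] - h$centers[k, 1]) <=
        trunc_sigma * h$sigmas[k, 1]
    }
    vis
  } else {
    vis <- matrix(FALSE, grid$n, grid$n)
    for (k in seq_len(nrow(h$centers))) {
      ia <- abs(grid$axes[[1]] - h$centers[k, 1]) <= trunc_sigma * h$sigmas[k, 1]
      ib <- abs(grid$axes[[2]] - h$centers[k, 2]) <= trunc_sigma * h$sigmas[k, 2]
      vis[ia, ib] <- TRUE
    }
    vis
  }
}

new_fes <- function(grid, values, visited, kT) {
  structure(list(grid = grid, values = values, visited = visited, kT = kT),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat("<fes> ", x$grid$dims, "D, ", x$grid$n, " points/dim over [",
      x$grid$lo, ", ", x$grid$hi, "], F in [",
      format(rng[1], digits = 3), ", ", format(rng[2], digits = 3),
      "] kJ/mol (", format(rng[2] / x$kT, digits = 3), " kT), ",
      sum(!x$visited), " unvisited nodes\n", sep = "")
  invisible(x)
}

#' @rdname fes_from_bias_history
#' @param x A `fes` object.
#' @param ... Unused.
#' @method tidy fes
#' @export
tidy.fes <- function(x, ...) {
  g <- x$grid
  if (g$dims == 1L) {
    tibble(bin_alpha = seq_len(g$n), alpha = g$axes[[1]],
           free_energy = as.numeric(x$values),
           free_energy_kT = as.numeric(x$values) / x$kT,
           visited = as.logical(x$visited))
  } else {
    idx <- expand.grid(bin_alpha = seq_len(g$n), bin_beta = seq_len(g$n))
    tibble(bin_alpha = idx$bin_alpha, bin_beta = idx$bin_beta,
           alpha = g$axes[[1]][idx$bin_alpha],
           beta = g$axes[[2]][idx$bin_beta],
           free_energy = as.numeric(x$values),
           free_energy_kT = as.numeric(x$values) / x$kT,
           visited = as.logical(x$visited))
  }
}

#' @rdname fes_from_bias_history
#' @method glance fes
#' @export
glance.fes <- function(x, ...) {
  tibble(dims = x$grid$dims, n_points = length(x$values),
         n_visited = sum(x$visited),
         f_max_kT = max(x$values, na.rm = TRUE) / x$kT,
         kT = x$kT)
}

#' Boltzmann probabilities of the FES bins
#'
#' Converts a free-energy surface to per-bin probabilities
#' `p_b = exp(-F_b/kT) / sum exp(-F_b/kT)` over visited bins only;
#' unvisited bins carry no weight rather than a fabricated one. Invariant
#' to any additive offset of the surface.
#'
#' @param fes A `fes` object.
#' @param kT Thermal energy (defaults to the surface's own).
#' @return A tibble of visited bins: indices, coordinates and `prob`
#'   (summing to 1).
#' @export
probability_from_fes <- function(fes, kT = NULL) {
  kT <- kT %||% fes$kT
  td <- tidy(fes) |> dplyr::filter(.data$visited)
  if (nrow(td) == 0) abort("all bins unvisited: no probabilities defined")
  w <- exp(-(td$free_energy - min(td$free_energy)) / kT)
  td |>
    dplyr::mutate(prob = w / sum(w)) |>
    dplyr::select(dplyr::starts_with("bin_"), dplyr::any_of(c("alpha", "beta")),
                  "prob")
}

#' Convergence of class free energies with simulation time
#'
#' Recomputes the free-energy surface from the hill record truncated at a
#' series of checkpoint times, reweights the secondary-structure class
#' fractions at each, and reports the class free energies relative to coil
#' (`-ln f_class/f_coil`, in kT) as a function of time — the standard
#' convergence diagnostic for bias-exchange runs.
#'
#' @param hills Hills tibble of the biased replica.
#' @param frames Frames tibble with `ss` strings (see [generate_frames()]).
#' @param grid An [fes_grid()].
#' @param checkpoints Times (ps) at which to truncate the hill record;
#'   checkpoints before the first hill are dropped with a warning.
#' @param kT Thermal energy in kJ/mol.
#' @param level `"peptide"` (default) or `"residue"` fractions.
#' @param ... Passed to [fes_from_bias_history()].
#' @return A tibble with `time`, `class`, `delta_f_kT`.
#' @export
convergence_trace <- function(hills, frames, grid = NULL, checkpoints,
                              kT = KT_310, level = "peptide", ...) {
  stopifnot(length(checkpoints) >= 1)
  first_hill <- min(hills$time)
  bad <- checkpoints <= first_hill
  if (any(bad)) {
    warn("dropping checkpoints at or before the first hill")
    checkpoints <- checkpoints[!bad]
  }
  if (length(checkpoints) == 0) abort("no usable checkpoints")
  purrr::map_dfr(sort(checkpoints), function(tc) {
    fes_t <- fes_from_bias_history(hills, grid = grid, t_end = tc, kT = kT, ...)
    prob <- probability_from_fes(fes_t)
    fr <- class_fractions(frames, grid = fes_t$grid, prob = prob)
    pep <- fr$peptide |>
      tidyr::pivot_wider(names_from = "class", values_from = "fraction")
    coil <- pep$coil %||% NA_real_
    ## classes never observed in the ensemble cannot be traced
    fr$peptide |>
      dplyr::filter(.data$class != "coil", .data$fraction > 0) |>
      dplyr::transmute(time = tc, class = .data$class,
                       delta_f_kT = class_free_energy(.data$fraction, coil))
  })
}
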