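#' Plot a free-energy surface
#'
#' 2D surfaces as a filled raster in kT (unvisited bins blank), 1D
#' profiles as a line, matching the conventional presentation of
#' (alpha_RMSD, beta_RMSD) free-energy maps.
#'
#' @param object A `fes` object.
#' @param max_kT Cap for the colour scale (kT).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fes
#' @export
autoplot.fes <- function(object, max_kT = NULL, ...) {
  td <- tidy(object)
  if (object$grid$dims == 1L) {
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = .data$alpha,
                                       y = .data$free_energy_kT)) +
        ggplot2::geom_line(na.rm = TRUE) +
        ggplot2::labs(x = expression(alpha[RMSD]),
                      y = "free energy (kT)") +
        ggplot2::theme_minimal()
    )
  }
  if (!is.null(max_kT)) {
    td$free_energy_kT <- pmin(td$free_energy_kT, max_kT)
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                   fill = .data$free_energy_kT)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1,
                                  name = "F (kT)") +
    ggplot2::labs(x = expression(alpha[RMSD]), y = expression(beta[RMSD])) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot CV trajectories of a bias-exchange run
#'
#' One panel per replica showing the sampled path on the
#' (alpha_RMSD, beta_RMSD) plane (2D runs) or the alpha_RMSD time series
#' (1D runs).
#'
#' @param object A `bemd_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bemd_run
#' @export
autoplot.bemd_run <- function(object, ...) {
  tr <- object$trajectories
  if ("beta" %in% names(tr)) {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                     colour = .data$time)) +
      ggplot2::geom_path(alpha = 0.5, linewidth = 0.2) +
      ggplot2::facet_wrap(~replica) +
      ggplot2::scale_colour_viridis_c(name = "time (ps)") +
      ggplot2::labs(x = expression(alpha[RMSD]), y = expression(beta[RMSD])) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$alpha)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~replica, ncol = 1) +
      ggplot2::labs(x = "time (ps)", y = expression(alpha[RMSD])) +
      ggplot2::theme_minimal()
  }
}

#' Plot class free-energy convergence traces
#'
#' Class free energies relative to coil (kT) versus simulation time, one
#' line per secondary-structure class — the convergence diagnostic for
#' the time-averaged-bias estimator.
#'
#' @param trace Output of [convergence_trace()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$delta_f_kT,
                                      colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (ps)", y = expression(Delta * F ~ "vs coil (kT)"),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot per-residue secondary-structure fractions
#'
#' Reweighted helix/strand/turn/bend fractions by residue, the standard
#' per-residue propensity profile.
#'
#' @param fractions The `residue` tibble from [class_fractions()].
#' @param classes Classes to show.
#' @return A ggplot object.
#' @export
plot_residue_fractions <- function(fractions,
                                   classes = c("helix", "strand")) {
  df <- fractions |> dplyr::filter(.data$class %in% classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resid, y = .data$fraction,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "fraction", colour = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
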