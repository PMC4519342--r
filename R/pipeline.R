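#' Pipeline configuration
#'
#' Nested list of every tunable in the desk-scale pipeline, defaulting to
#' the reference parameter set: 310 K; hills of 0.1 kJ/mol and width 2.0
#' deposited every 1 ps; CV switching r0 = 0.08 nm, n = 8, m = 12;
#' CV-domain boundaries 0 and 32; 1D bias grids of 2351 nodes over
#' \[-5, 42\]; a 160 x 160 free-energy grid over \[0, 32\]^2; a distance
#' wall at 7.0 nm with kappa = 100 kJ/mol. Desk-scale knobs (step counts,
#' synthetic-ensemble size) are sized so the demo completes in minutes.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(sampler = list(n_steps = 5000L))
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    temperature = 310,
    kT = KT_310,
    cv = list(r0 = 0.08, n_exp = 8L, m_exp = 12L),
    hills = list(height = 0.1, sigma = 2.0, pace = 1L),
    domain = list(lo = 0, hi = 32),
    bias_grid = list(lower = -5, upper = 42, n_1d = 2351L, n_2d = 471L),
    fes = list(n = 160L),
    wall = list(position = 7.0, kappa = 100.0),
    sampler = list(n_steps = 20000L, proposal_sigma = 2, exchange_interval = 100L,
                   stride = 10L),
    ensemble = list(n_res = 37L, n_frames = 20000L),
    seed = 1L)
  overrides <- list(...)
  if (length(overrides) > 0) {
    message("pipeline_config overrides: ",
            paste(names(overrides), collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  ## a full config file is not an "override"; no logging on read
  suppressMessages(do.call(pipeline_config, yaml::read_yaml(path)))
}

#' Run the full desk-scale pipeline
#'
#' End-to-end composition of every stage on synthetic ground truth:
#' generate a coil/helix/hairpin frame ensemble and its matching toy
#' potential; run the four-replica bias-exchange sampler; estimate the
#' free-energy surface from the time-averaged bias of the doubly-biased
#' replica; convert it to bin probabilities; reweight per-residue
#' secondary-structure fractions, class free energies vs coil and
#' ensemble-averaged secondary shifts; compare predicted shifts against
#' the (synthetic) experimental table with the mean-absolute-error
#' statistic; and write every report with an embedded provenance block.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent); `NULL` skips all
#'   file output.
#' @param spec Optional [synthetic_ensemble_spec()]; defaults to
#'   [demo_ensemble_spec()] sized per `config`.
#' @return A list with the run, FES, probabilities, fraction tables,
#'   class free-energy table, shift predictions, error table and the
#'   convergence trace; `paths` names the written files.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         spec = NULL) {
  cfg <- config
  if (cfg$ensemble$n_frames < 1) abort("config requests zero frames")
  spec <- spec %||% demo_ensemble_spec(n_res = cfg$ensemble$n_res,
                                       n_frames = cfg$ensemble$n_frames,
                                       seed = cfg$seed)
  synth <- generate_frames(spec)
  pot <- toy_potential_mixture(spec$states, kT = cfg$kT,
                               domain_lo = cfg$domain$lo,
                               domain_hi = cfg$domain$hi)

  run <- run_bias_exchange(
    pot, replicas = c("neutral", "alpha_only", "beta_only", "both"),
    n_steps = cfg$sampler$n_steps, kT = cfg$kT,
    proposal_sigma = cfg$sampler$proposal_sigma,
    exchange_interval = cfg$sampler$exchange_interval,
    hill_pace = cfg$hills$pace, hill_height = cfg$hills$height,
    hill_sigma = cfg$hills$sigma, stride = cfg$sampler$stride,
    seed = cfg$seed, bias_grid_nodes = cfg$bias_grid$n_2d)

  grid <- fes_grid(dims = 2L, n = cfg$fes$n, lo = cfg$domain$lo,
                   hi = cfg$domain$hi)
  fes <- fes_from_bias_history(run$hills$both, grid = grid, kT = cfg$kT)
  prob <- probability_from_fes(fes)

  fractions <- class_fractions(synth$frames, grid = grid, prob = prob)
  coil_pep <- fractions$peptide$fraction[fractions$peptide$class == "coil"]
  class_df <- fractions$peptide |>
    dplyr::filter(.data$class != "coil") |>
    dplyr::mutate(delta_f_kT = class_free_energy(.data$fraction, coil_pep))

  ## reweighted shift predictions and error vs the synthetic experiment
  rc <- synthetic_random_coil_reference(cfg$ensemble$n_res)
  bm <- bin_and_average(synth$frames,
                        synth$shifts |> dplyr::rename(value = "shift_ppm"),
                        grid)
  pred <- ensemble_average(bm, prob) |>
    dplyr::rename(shift_ppm = "estimate") |>
    secondary_shift(rc)
  exp_table <- synthetic_experiment_table(spec, rc)
  pred_vs_exp <- dplyr::inner_join(
    pred, exp_table, by = c("resid", "atom"), suffix = c("_pred", "_exp"))
  errors <- pred_vs_exp |>
    dplyr::group_by(.data$atom) |>
    dplyr::summarise(error_ppm = shift_error(.data$secondary_ppm_pred,
                                             .data$secondary_ppm_exp),
                     n_residues = dplyr::n(), .groups = "drop")

  n_cp <- 5L
  cps <- seq(0, max(run$hills$both$time), length.out = n_cp + 1L)[-1]
  trace <- convergence_trace(run$hills$both, synth$frames, grid = grid,
                             checkpoints = cps, kT = cfg$kT)

  result <- list(config = cfg, spec = spec, frames = synth$frames,
                 shifts = synth$shifts, run = run, fes = fes, prob = prob,
                 fractions = fractions, class_free_energies = class_df,
                 shift_predictions = pred, shift_errors = errors,
                 convergence = trace, paths = NULL)

  if (!is.null(out_dir)) {
    result$paths <- write_pipeline_reports(result, out_dir)
  }
  result
}

## the per-residue secondary shifts implied by the spec's exact state
## populations and shift means: the "experimental" table of the demo
synthetic_experiment_table <- function(spec, rc) {
  purrr::map_dfr(spec$states, function(st) {
    if (is.null(st$shift_mean)) return(NULL)
    st$shift_mean |>
      dplyr::mutate(population = st$population)
  }) |>
    dplyr::group_by(.data$resid, .data$atom) |>
    dplyr::summarise(shift_ppm = sum(.data$population * .data$mean_ppm) /
                       sum(.data$population), .groups = "drop") |>
    secondary_shift(rc)
}

write_pipeline_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prov <- provenance_lines(result$config, result$config$seed)
  paths <- list()

  paths$fes <- file.path(out_dir, "fes.dat")
  write_fes_table(result$fes, paths$fes, provenance = prov)

  paths$hills <- file.path(out_dir, "hills_both.dat")
  write_hills(result$run$hills$both, paths$hills, provenance = prov)

  paths$colvar <- file.path(out_dir, "colvar_neutral.dat")
  neutral <- result$run$trajectories |>
    dplyr::filter(.data$replica == "neutral") |>
    dplyr::select("time", "alpha", "beta")
  write_colvar(neutral, paths$colvar, provenance = prov)

  write_csv_report <- function(df, name) {
    p <- file.path(out_dir, name)
    writeLines(prov, p)
    readr::write_csv(df, p, append = TRUE, col_names = TRUE, progress = FALSE)
    p
  }
  paths$residue_fractions <- write_csv_report(result$fractions$residue,
                                              "residue_fractions.csv")
  paths$peptide_fractions <- write_csv_report(result$fractions$peptide,
                                              "peptide_fractions.csv")
  paths$class_free_energies <- write_csv_report(result$class_free_energies,
                                                "class_free_energies.csv")
  paths$shift_errors <- write_csv_report(result$shift_errors,
                                         "shift_errors.csv")
  paths$convergence <- write_csv_report(result$convergence, "convergence.csv")
  paths
}

#' Project a PDB trajectory onto the CV plane and write a COLVAR file
#'
#' Reads backbone frames from a (multi-MODEL) PDB file, evaluates
#' alpha_RMSD and antiparallel beta_RMSD for each, and writes the
#' COLVAR-style table. Deterministic: re-running produces a
#' byte-identical file.
#'
#' @param pdb_path Input PDB (models = frames).
#' @param out_path Output COLVAR path.
#' @param times Optional frame times (ps).
#' @param params [switching_params()].
#' @return The CV tibble, invisibly.
#' @export
project_cv_file <- function(pdb_path, out_path, times = NULL,
                            params = switching_params()) {
  frames <- read_backbone_pdb_frames(pdb_path)
  cv <- project_cv(frames, times = times, params = params)
  write_colvar(cv, out_path)
  invisible(cv)
}
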