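#' DSSP class grouping
#'
#' Maps DSSP one-letter codes to the four reported secondary-structure
#' classes plus coil: H/G/I (alpha, 3-10 and pi helices) to `helix`, E/B
#' (sheet and bridge) to `strand`, T to `turn`, S to `bend`; every other
#' code (including blank and `~`) to `coil`. Helices are grouped because
#' 3-10 and pi helices are often misclassified as alpha; bridges share
#' the sheet hydrogen-bonding pattern.
#'
#' @return Named character vector mapping DSSP letters to class names.
#' @examples
#' ss_class_map()[c("H", "E", "T")]
#' @export
ss_class_map <- function() {
  c(H = "helix", G = "helix", I = "helix",
    E = "strand", B = "strand",
    T = "turn", S = "bend")
}

SS_CLASSES <- c("helix", "strand", "turn", "bend", "coil")

## expand per-frame ss strings to a long (frame, resid, class) tibble
expand_ss <- function(frames) {
  if (!"ss" %in% names(frames) || all(is.na(frames$ss))) {
    abort("frames carry no secondary-structure strings")
  }
  fr <- frames[!is.na(frames$ss), ]
  letters_by_frame <- strsplit(fr$ss, "")
  n_res <- lengths(letters_by_frame)
  if (length(unique(n_res)) != 1) {
    abort("secondary-structure strings must all have the same length")
  }
  map <- ss_class_map()
  codes <- unlist(letters_by_frame)
  cls <- unname(map[codes])
  cls[is.na(cls)] <- "coil"
  tibble(frame = rep(fr$frame, each = n_res[1]),
         resid = rep(seq_len(n_res[1]), times = nrow(fr)),
         class = factor(cls, levels = SS_CLASSES))
}

#' Assign frames to FES bins
#'
#' Adds nearest-grid-point bin indices (`bin_alpha`, and `bin_beta` in 2D)
#' to a frames tibble.
#'
#' @param frames Tibble with `alpha` (and `beta` for a 2D grid) columns.
#' @param grid An [fes_grid()].
#' @return The frames tibble with bin columns added.
#' @export
assign_bins <- function(frames, grid = fes_grid()) {
  frames$bin_alpha <- fes_bin_index(grid, frames$alpha)
  if (grid$dims == 2L) {
    if (!"beta" %in% names(frames)) abort("2D grid needs a beta column")
    frames$bin_beta <- fes_bin_index(grid, frames$beta)
  }
  frames
}

#' Bin frames and average an observable
#'
#' Assigns each frame to its (alpha_RMSD, beta_RMSD) bin and returns the
#' arithmetic mean of the observable over the frames in each populated
#' bin, together with the frame count (counts sum to the number of
#' observed frames; empty bins are simply absent).
#'
#' @param frames Frames tibble with CV columns (see [generate_frames()]).
#' @param observables Long tibble with a `frame` key, a `value` column and
#'   any grouping columns (e.g. `resid`, `atom`).
#' @param grid An [fes_grid()].
#' @return Tibble keyed by bin indices and grouping columns with `mean`
#'   and `n`.
#' @export
bin_and_average <- function(frames, observables, grid = fes_grid()) {
  if (!"value" %in% names(observables)) abort("observables need a value column")
  if (nrow(observables) == 0 || all(is.na(observables$value))) {
    abort("observable absent from all frames")
  }
  binned <- assign_bins(frames, grid)
  bin_cols <- intersect(c("bin_alpha", "bin_beta"), names(binned))
  keys <- setdiff(names(observables), c("frame", "value"))
  observables |>
    dplyr::inner_join(binned[, c("frame", bin_cols)], by = "frame") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(bin_cols, keys)))) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
}

#' Probability-weighted ensemble average of binned observables
#'
#' Combines per-bin observable means with the Boltzmann probabilities of
#' the free-energy surface: `sum_b p_b * mean_b`, with the probabilities
#' renormalised over the bins that both hold frames and carry probability.
#'
#' @param bin_means Output of [bin_and_average()].
#' @param prob Output of [probability_from_fes()].
#' @return Tibble with one `estimate` per grouping-column combination.
#' @export
ensemble_average <- function(bin_means, prob) {
  bin_cols <- intersect(c("bin_alpha", "bin_beta"), names(bin_means))
  joined <- dplyr::inner_join(bin_means,
                              prob[, c(bin_cols, "prob")], by = bin_cols)
  if (nrow(joined) == 0) {
    abort("no overlap between populated bins and the probability field")
  }
  keys <- setdiff(names(bin_means), c(bin_cols, "mean", "n"))
  if (length(keys) == 0) {
    joined |>
      dplyr::summarise(estimate = sum(.data$prob * .data$mean) / sum(.data$prob))
  } else {
    joined |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(estimate = sum(.data$prob * .data$mean) / sum(.data$prob),
                       .groups = "drop")
  }
}

#' Secondary chemical shifts
#'
#' Subtracts the residue- and atom-specific random-coil reference from a
#' raw shift: positive C-alpha secondary shifts indicate helical
#' propensity, negative ones sheet propensity, zero random coil.
#'
#' @param shifts Tibble with `resid`, `atom`, and a shift column
#'   `shift_ppm` (raw predicted or measured shifts, ppm).
#' @param reference Random-coil reference tibble (`resid`, `atom`,
#'   `rc_ppm`), e.g. [synthetic_random_coil_reference()].
#' @return `shifts` with `secondary_ppm = shift_ppm - rc_ppm` added.
#' @export
secondary_shift <- function(shifts, reference) {
  ref <- reference[, c("resid", "atom", "rc_ppm")]
  names(ref)[3] <- ".rc_ref"
  out <- dplyr::left_join(shifts, ref, by = c("resid", "atom"))
  missing <- is.na(out$.rc_ref) & !is.na(out$shift_ppm)
  if (any(missing)) {
    bad <- out[missing, ]
    abort(paste0("no random-coil reference for residue ", bad$resid[1],
                 " atom ", bad$atom[1]))
  }
  out$secondary_ppm <- out$shift_ppm - out$.rc_ref
  out$.rc_ref <- NULL
  out
}

#' Temperature correction of amide-proton shifts
#'
#' Amide-proton (HN) shifts move linearly with temperature; experimental
#' temperature coefficients (ppb/K) extrapolate a shift measured at
#' `t_ref` to `t_target`: `shift + coeff * (t_target - t_ref) / 1000`.
#'
#' @param shift_ppm Shift(s) at the reference temperature, ppm.
#' @param coeff_ppb_per_k Temperature coefficient(s), ppb/K.
#' @param t_ref,t_target Reference and target temperatures, K.
#' @return Corrected shift(s) in ppm.
#' @examples
#' apply_temperature_correction(8.2, -8, 278, 310) # 8.2 - 0.256
#' @export
apply_temperature_correction <- function(shift_ppm, coeff_ppb_per_k,
                                         t_ref, t_target) {
  stopifnot(all(is.finite(shift_ppm)), all(is.finite(coeff_ppb_per_k)))
  shift_ppm + coeff_ppb_per_k * (t_target - t_ref) / 1000
}

#' Mean absolute shift error
#'
#' The per-atom agreement statistic between predicted and experimental
#' shifts: `(1/n) * sum_i |pred_i - exp_i|` over the n residues with both
#' values present (unassigned residues are dropped pairwise).
#'
#' @param pred,exp Numeric vectors of per-residue shifts (ppm), equal
#'   length; `NA`s excluded pairwise.
#' @return Mean absolute error in ppm per residue.
#' @examples
#' shift_error(c(1, 2), c(0.5, 2.5)) # 0.5
#' @export
shift_error <- function(pred, exp) {
  if (length(pred) != length(exp)) abort("pred and exp must have equal length")
  ok <- !is.na(pred) & !is.na(exp)
  if (!any(ok)) abort("no residues with both predicted and experimental shifts")
  mean(abs(pred[ok] - exp[ok]))
}

#' Reweighted secondary-structure class fractions
#'
#' For each residue, the fraction of frames in each class is averaged
#' within every (alpha_RMSD, beta_RMSD) bin and then weighted by the
#' bin's Boltzmann probability from the free-energy surface; the
#' peptide-level fraction is the mean over residues. Per-residue class
#' fractions sum to 1.
#'
#' @param frames Frames tibble with `ss` strings.
#' @param grid An [fes_grid()].
#' @param prob Probabilities from [probability_from_fes()].
#' @return List with tibbles `residue` (`resid`, `class`, `fraction`) and
#'   `peptide` (`class`, `fraction`).
#' @export
class_fractions <- function(frames, grid = fes_grid(), prob) {
  ss_long <- expand_ss(frames)
  binned <- assign_bins(frames[!is.na(frames$ss), ], grid)
  bin_cols <- intersect(c("bin_alpha", "bin_beta"), names(binned))
  bf <- binned[, c("frame", bin_cols)]
  bin_tot <- bf |>
    dplyr::count(dplyr::across(dplyr::all_of(bin_cols)), name = "n_frames")
  pj <- dplyr::inner_join(bin_tot, prob[, c(bin_cols, "prob")], by = bin_cols)
  if (nrow(pj) == 0) {
    abort("no overlap between populated bins and the probability field")
  }
  pj$w <- pj$prob / sum(pj$prob)
  counts <- ss_long |>
    dplyr::inner_join(bf, by = "frame") |>
    dplyr::count(dplyr::across(dplyr::all_of(c(bin_cols, "resid", "class"))),
                 name = "n_rc")
  res <- counts |>
    dplyr::inner_join(pj[, c(bin_cols, "w", "n_frames")], by = bin_cols) |>
    dplyr::mutate(contrib = .data$w * .data$n_rc / .data$n_frames) |>
    dplyr::group_by(.data$resid, .data$class) |>
    dplyr::summarise(fraction = sum(.data$contrib), .groups = "drop") |>
    tidyr::complete(.data$resid,
                    class = factor(SS_CLASSES, levels = SS_CLASSES),
                    fill = list(fraction = 0)) |>
    dplyr::arrange(.data$resid, .data$class)
  pep <- res |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  list(residue = res, peptide = pep)
}

#' Class free energy relative to coil
#'
#' `-ln(f_class / f_coil)` in units of kT: the free-energy cost of a
#' residue adopting the class instead of coil. A zero class fraction is
#' reported as `Inf` with a warning rather than an error, mirroring how
#' vanishing populations appear as large values in reports.
#'
#' @param fraction_class,fraction_coil Class and coil fractions (> 0 for
#'   finite results).
#' @return Free energy in kT (vectorised over `fraction_class`).
#' @examples
#' class_free_energy(0.10, 0.40) # ln 4 ~ 1.386
#' @export
class_free_energy <- function(fraction_class, fraction_coil) {
  if (any(fraction_coil <= 0)) abort("coil fraction must be positive")
  if (any(fraction_class < 0)) abort("fractions cannot be negative")
  out <- -log(fraction_class / fraction_coil)
  if (any(is.infinite(out))) warn("zero class fraction: free energy is Inf")
  out
}
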