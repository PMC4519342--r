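make_frames <- function(alpha, beta = NULL, ss = NA_character_) {
  out <- tibble::tibble(frame = seq_along(alpha), time = (seq_along(alpha) - 1) * 10,
                        alpha = alpha)
  if (!is.null(beta)) out$beta <- beta
  out$ss <- ss
  out
}

test_that("bin averages match hand arithmetic and ignore frame order", {
  g <- fes_grid(dims = 1, n = 33)  # 1-unit bins
  fr <- make_frames(c(4.1, 3.9, 4.0, 10.1, 9.9))
  obs <- tibble::tibble(frame = 1:5, value = c(1, 2, 3, 10, 20))
  bm <- bin_and_average(fr, obs, g)
  expect_equal(nrow(bm), 2)
  expect_equal(bm$mean[bm$bin_alpha == 5], 2)    # node 4 -> index 5
  expect_equal(bm$mean[bm$bin_alpha == 11], 15)
  expect_equal(sum(bm$n), 5)
  perm <- sample(5)
  bm2 <- bin_and_average(fr[perm, ], obs[perm, ], g)
  expect_equal(as.data.frame(bm2), as.data.frame(bm))
  expect_error(bin_and_average(fr, obs[0, ], g), "absent")
})

test_that("ensemble averages equal closed forms and the brute-force sum", {
  g <- fes_grid(dims = 1, n = 33)
  fr <- make_frames(c(4, 4, 10, 10, 10))
  obs <- tibble::tibble(frame = 1:5, value = c(0, 0, 3, 3, 3))
  bm <- bin_and_average(fr, obs, g)
  prob <- tibble::tibble(bin_alpha = c(5, 11), prob = c(2 / 3, 1 / 3))
  expect_equal(ensemble_average(bm, prob)$estimate, 1.0, tolerance = 1e-12)
  ## uniform probabilities reduce to the mean of bin means
  prob_u <- tibble::tibble(bin_alpha = c(5, 11), prob = c(0.5, 0.5))
  expect_equal(ensemble_average(bm, prob_u)$estimate, 1.5, tolerance = 1e-12)
  ## oracle equivalence on a random ensemble: assigning every frame its
  ## bin's probability share equals the independent frame-weighted sum
  set.seed(31)
  frr <- make_frames(runif(500, 0, 32))
  obsr <- tibble::tibble(frame = 1:500, value = rnorm(500))
  bmr <- bin_and_average(frr, obsr, g)
  pr <- tibble::tibble(bin_alpha = unique(bmr$bin_alpha))
  pr$prob <- runif(nrow(pr))
  pr$prob <- pr$prob / sum(pr$prob)
  est <- ensemble_average(bmr, pr)$estimate
  ## brute force: per-frame weight = p_bin / n_bin
  bins <- bemdtools:::fes_bin_index(g, frr$alpha)
  nb <- table(bins)
  wts <- pr$prob[match(bins, pr$bin_alpha)] / as.numeric(nb[as.character(bins)])
  expect_equal(est, sum(wts * obsr$value) / sum(wts), tolerance = 1e-10)
  expect_error(ensemble_average(bmr, tibble::tibble(bin_alpha = 999,
                                                    prob = 1)), "overlap")
})

test_that("secondary shifts subtract the reference with sign convention", {
  rc <- tibble::tibble(resid = 1:2, atom = "CA", rc_ppm = 56.0)
  sh <- tibble::tibble(resid = 1:2, atom = "CA", shift_ppm = c(58.2, 56.0))
  out <- secondary_shift(sh, rc)
  expect_equal(out$secondary_ppm, c(2.2, 0))
  expect_gt(out$secondary_ppm[1], 0)  # upfield CA = helical propensity
  sh_bad <- tibble::tibble(resid = 3, atom = "CB", shift_ppm = 30)
  expect_error(secondary_shift(sh_bad, rc), "residue 3")
  ## vectorised over many residues equals the elementwise loop
  rc_big <- synthetic_random_coil_reference(20)
  sh_big <- rc_big |> dplyr::mutate(shift_ppm = rc_ppm + seq_len(dplyr::n()) / 10)
  out_big <- secondary_shift(sh_big, rc_big)
  expect_equal(out_big$secondary_ppm, seq_len(nrow(rc_big)) / 10)
})

test_that("temperature correction is linear in the coefficient", {
  expect_equal(apply_temperature_correction(8.5, -8, 278, 310),
               8.5 - 0.256)
  expect_equal(apply_temperature_correction(8.5, 0, 278, 310), 8.5)
  expect_equal(apply_temperature_correction(8.5, -8, 278, 278), 8.5)
})

test_that("shift error reproduces hand-computed fixtures", {
  expect_equal(shift_error(c(1, 2), c(1, 2)), 0)
  expect_equal(shift_error(c(1.0, 2.0), c(0.5, 2.5)), 0.5)
  ## 5-residue fixture with a missing assignment dropped pairwise
  pred <- c(1.0, 2.0, 3.0, 4.0, 5.0)
  ex <- c(1.1, 1.8, NA, 4.4, 4.9)
  expect_equal(shift_error(pred, ex), (0.1 + 0.2 + 0.4 + 0.1) / 4)
  ## shifting all predictions by a constant moves the error by |c| when
  ## the differences share a sign
  expect_equal(shift_error(c(1, 2) + 0.3, c(1, 2)),
               shift_error(c(1, 2), c(1, 2)) + 0.3)
  expect_error(shift_error(c(NA, NA), c(1, 2)), "no residues")
  expect_error(shift_error(1:3, 1:2), "equal length")
})

test_that("class map groups the fixture string as hand-tabulated", {
  s <- "HHHHGGGEEEBSSTC"
  cls <- unname(ss_class_map()[strsplit(s, "")[[1]]])
  cls[is.na(cls)] <- "coil"
  expect_equal(sum(cls == "helix"), 7)   # HHHH + GGG
  expect_equal(sum(cls == "strand"), 4)  # EEE + B
  expect_equal(sum(cls == "bend"), 2)    # SS
  expect_equal(sum(cls == "turn"), 1)    # T
  expect_equal(sum(cls == "coil"), 1)    # C
  ## unknown codes (blank, ~) fall through to coil
  weird <- unname(ss_class_map()[c("~", " ", "X")])
  expect_true(all(is.na(weird)))
})

test_that("class fractions recover hand counts and sum to one", {
  g <- fes_grid(dims = 1, n = 33)
  ## one bin, two frames: all-H and all-C -> helix 0.5 everywhere
  fr <- make_frames(c(4, 4), ss = c(strrep("H", 6), strrep("C", 6)))
  prob <- tibble::tibble(bin_alpha = 5, prob = 1)
  cf <- class_fractions(fr, g, prob)
  expect_equal(cf$residue$fraction[cf$residue$class == "helix"],
               rep(0.5, 6))
  expect_equal(cf$peptide$fraction[cf$peptide$class == "helix"], 0.5)
  ## per-residue fractions sum to 1
  sums <- cf$residue |>
    dplyr::group_by(resid) |>
    dplyr::summarise(s = sum(fraction))
  expect_equal(sums$s, rep(1, 6), tolerance = 1e-10)
  ## all-helix ensemble: fraction 1 everywhere
  fr_h <- make_frames(c(4, 10), ss = rep(strrep("H", 6), 2))
  prob2 <- tibble::tibble(bin_alpha = c(5, 11), prob = c(0.5, 0.5))
  cf_h <- class_fractions(fr_h, g, prob2)
  expect_equal(cf_h$peptide$fraction[cf_h$peptide$class == "helix"], 1)
  ## the fixture string, weighted across two bins with p = (2/3, 1/3)
  s <- "HHHHGGGEEEBSSTC"
  fr_mix <- make_frames(c(4, 10), ss = c(s, strrep("C", 15)))
  prob3 <- tibble::tibble(bin_alpha = c(5, 11), prob = c(2 / 3, 1 / 3))
  cf_m <- class_fractions(fr_mix, g, prob3)
  pep <- cf_m$peptide
  expect_equal(pep$fraction[pep$class == "helix"], (2 / 3) * 7 / 15,
               tolerance = 1e-12)
  expect_equal(pep$fraction[pep$class == "strand"], (2 / 3) * 4 / 15,
               tolerance = 1e-12)
  expect_equal(pep$fraction[pep$class == "coil"],
               (2 / 3) * 1 / 15 + 1 / 3, tolerance = 1e-12)
})

test_that("class free energies follow -ln(f/f_coil)", {
  expect_equal(class_free_energy(0.4, 0.4), 0)
  expect_equal(class_free_energy(0.4 * exp(-1), 0.4), 1, tolerance = 1e-12)
  expect_equal(class_free_energy(0.10, 0.40), log(4), tolerance = 1e-12)
  expect_warning(out <- class_free_energy(0, 0.4), "Inf")
  expect_true(is.infinite(out))
  expect_error(class_free_energy(0.1, 0), "positive")
})

test_that("reweighting outputs are invariant to FES offsets", {
  spec <- synthetic_ensemble_spec(list(
    ensemble_state("coil", 0.8, cv_mean = 4, cv_spread = 1.5,
                   ss = strrep("C", 8)),
    ensemble_state("helix", 0.2, cv_mean = 20, cv_spread = 1.5,
                   ss = strrep("H", 8))),
    n_frames = 2000, seed = 6)
  synth <- generate_frames(spec)
  g <- fes_grid(dims = 1, n = 160)
  pot <- toy_potential_mixture(spec$states, kT = kT310)
  fes <- exact_fes(pot, g, kT = kT310)
  fes_shift <- fes
  fes_shift$values <- fes$values + 11.3
  p1 <- probability_from_fes(fes)
  p2 <- probability_from_fes(fes_shift)
  c1 <- class_fractions(synth$frames, g, p1)
  c2 <- class_fractions(synth$frames, g, p2)
  expect_equal(c1$peptide$fraction, c2$peptide$fraction, tolerance = 1e-12)
})
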