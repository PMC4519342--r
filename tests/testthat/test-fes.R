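test_that("a single hill gives a well of its height at the centre", {
  h <- hills_tibble(time = 0, center = 16)
  fes <- fes_from_bias_history(h, grid = fes_grid(dims = 1), t_end = 100)
  expect_equal(min(fes$values, na.rm = TRUE), 0)
  i_min <- which.min(fes$values)
  expect_equal(fes$grid$axes[[1]][i_min], 16, tolerance = 0.25)
  ## constant-in-time bias: well depth equals the hill height
  expect_equal(max(fes$values[fes$visited], na.rm = TRUE), 0.1,
               tolerance = 0.005)
})

test_that("time-average weights follow the hand piecewise integral", {
  ## two equal hills at t = 0 and t = T/2, averaged over [0, T]:
  ## weights 1 and 1/2
  h <- hills_tibble(time = c(0, 50), center = c(10, 22))
  fes <- fes_from_bias_history(h, grid = fes_grid(dims = 1), t_end = 100)
  ax <- fes$grid$axes[[1]]
  near <- function(x) which.min(abs(ax - x))
  probes <- ax[c(near(10), near(22))]
  direct <- direct_bias_sum(probes, c(10, 22), 2, 0.1,
                            weights = c(1, 0.5))
  got <- -fes$values[c(near(10), near(22))]
  ## compare differences (the surface is shifted to min 0)
  expect_equal(diff(got), diff(direct), tolerance = 1e-4)
  ## hills before t_start keep full weight; those after are discounted
  fes2 <- fes_from_bias_history(h, grid = fes_grid(dims = 1),
                                t_start = 25, t_end = 100)
  direct2 <- direct_bias_sum(probes, c(10, 22), 2, 0.1,
                             weights = c(1, 50 / 75))
  got2 <- -fes2$values[c(near(10), near(22))]
  expect_equal(diff(got2), diff(direct2), tolerance = 1e-4)
  expect_error(fes_from_bias_history(h, t_start = 200, t_end = 100),
               "precede")
  expect_error(fes_from_bias_history(h[0, ]), "at least one hill")
})

test_that("unvisited bins are flagged, not silently zero", {
  h <- hills_tibble(time = 0:10, center = rep(5, 11))
  fes <- fes_from_bias_history(h, grid = fes_grid(dims = 1), t_end = 20)
  ax <- fes$grid$axes[[1]]
  expect_true(all(is.na(fes$values[ax > 5 + 12.5])))
  expect_true(all(!fes$visited[ax > 5 + 12.5]))
  expect_true(all(fes$visited[abs(ax - 5) < 10]))
})

test_that("probabilities follow closed forms and ignore FES offsets", {
  g <- fes_grid(dims = 1, n = 2, lo = 0, hi = 1)
  fes <- bemdtools:::new_fes(g, c(0, kT310 * log(2)), c(TRUE, TRUE), kT310)
  p <- probability_from_fes(fes)
  expect_equal(p$prob, c(2 / 3, 1 / 3), tolerance = 1e-12)
  ## uniform surface: equal probabilities
  g5 <- fes_grid(dims = 1, n = 5, lo = 0, hi = 4)
  fes5 <- bemdtools:::new_fes(g5, rep(1.3, 5), rep(TRUE, 5), kT310)
  expect_equal(probability_from_fes(fes5)$prob, rep(0.2, 5))
  ## offset invariance
  fes_off <- bemdtools:::new_fes(g, c(0, kT310 * log(2)) + 7.7,
                                 c(TRUE, TRUE), kT310)
  expect_equal(probability_from_fes(fes_off)$prob, p$prob, tolerance = 1e-12)
  ## unvisited bins carry no weight
  fes_u <- bemdtools:::new_fes(g5, c(0, 0, NA, 0, NA),
                               c(TRUE, TRUE, FALSE, TRUE, FALSE), kT310)
  pu <- probability_from_fes(fes_u)
  expect_equal(nrow(pu), 3)
  expect_equal(sum(pu$prob), 1)
  fes_none <- bemdtools:::new_fes(g5, rep(NA_real_, 5), rep(FALSE, 5), kT310)
  expect_error(probability_from_fes(fes_none), "unvisited")
})

test_that("double-well FES recovery matches the quadrature oracle", {
  pot <- toy_potential_wells(centers = c(8, 24),
                             depths = c(8 * kT310, 6.5 * kT310), widths = 3)
  run <- run_bias_exchange(pot, replicas = "biased", n_steps = 2e4,
                           hill_pace = 1, exchange_interval = 0,
                           seed = 4, init_state = 8)
  fes <- fes_from_bias_history(run$hills$biased, grid = fes_grid(dims = 1))
  exact <- exact_fes(pot, fes_grid(dims = 1))
  df_est <- basin_delta_f(fes$values, fes$grid$axes[[1]])
  df_exact <- basin_delta_f(exact$values, exact$grid$axes[[1]])
  expect_lt(abs(df_est - df_exact), 0.5 * kT310)
})

test_that("convergence traces are consistent and constant for static bias", {
  spec <- synthetic_ensemble_spec(list(
    ensemble_state("coil", 0.7, cv_mean = 4, cv_spread = 1.5,
                   ss = strrep("C", 8)),
    ensemble_state("helix", 0.3, cv_mean = 20, cv_spread = 1.5,
                   ss = paste0("C", strrep("H", 6), "C"))),
    n_frames = 4000, seed = 2)
  synth <- generate_frames(spec)
  ## a stationary bias: identical hill sets at every checkpoint scale all
  ## weights equally, so the trace is constant
  h <- hills_tibble(time = 0, center = 12)
  tr <- convergence_trace(h, synth$frames, grid = fes_grid(dims = 1),
                          checkpoints = c(50, 100, 200))
  helix_vals <- tr$delta_f_kT[tr$class == "helix"]
  expect_equal(length(unique(round(helix_vals, 9))), 1)
  ## single checkpoint at T equals the full-run estimate
  pot <- toy_potential_wells(centers = c(4, 20), depths = c(10, 8),
                             widths = 2.5)
  run <- run_bias_exchange(pot, replicas = "biased", n_steps = 5000,
                           seed = 9, exchange_interval = 0, init_state = 4)
  tr1 <- convergence_trace(run$hills$biased, synth$frames,
                           grid = fes_grid(dims = 1),
                           checkpoints = max(run$hills$biased$time))
  fes_full <- fes_from_bias_history(run$hills$biased,
                                    grid = fes_grid(dims = 1))
  prob <- probability_from_fes(fes_full)
  fr <- class_fractions(synth$frames, grid = fes_full$grid, prob = prob)
  coil <- fr$peptide$fraction[fr$peptide$class == "coil"]
  helix <- fr$peptide$fraction[fr$peptide$class == "helix"]
  expect_equal(tr1$delta_f_kT[tr1$class == "helix"],
               class_free_energy(helix, coil), tolerance = 1e-10)
  expect_warning(
    convergence_trace(run$hills$biased, synth$frames,
                      grid = fes_grid(dims = 1),
                      checkpoints = c(0.5, max(run$hills$biased$time))),
    "checkpoint")
})

test_that("exact FES marginalisation matches refined quadrature", {
  pot <- toy_potential_wells(centers = rbind(c(8, 4), c(20, 12)),
                             depths = c(12, 9), widths = c(2, 3))
  g1 <- fes_grid(dims = 1, n = 81)
  coarse <- exact_fes(pot, g1, marginal_of = 1, n_quad = 501)
  fine <- exact_fes(pot, g1, marginal_of = 1, n_quad = 4001)
  expect_equal(coarse$values, fine$values, tolerance = 1e-6)
  ## flat potential: F identically 0
  flat <- toy_potential_wells(centers = 16, depths = 1e-12, widths = 3)
  f0 <- exact_fes(flat, fes_grid(dims = 1, n = 33))
  expect_lt(max(abs(f0$values)), 1e-10)
})

test_that("FES grid refinement barely moves basin free energies", {
  pot <- toy_potential_wells(centers = c(8, 24),
                             depths = c(8 * kT310, 6.5 * kT310), widths = 3)
  run <- run_bias_exchange(pot, replicas = "biased", n_steps = 1e4,
                           hill_pace = 1, exchange_interval = 0,
                           seed = 14, init_state = 8)
  f160 <- fes_from_bias_history(run$hills$biased,
                                grid = fes_grid(dims = 1, n = 160))
  f320 <- fes_from_bias_history(run$hills$biased,
                                grid = fes_grid(dims = 1, n = 320))
  d160 <- basin_delta_f(f160$values, f160$grid$axes[[1]])
  d320 <- basin_delta_f(f320$values, f320$grid$axes[[1]])
  expect_lt(abs(d160 - d320), 0.1 * kT310)
})
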