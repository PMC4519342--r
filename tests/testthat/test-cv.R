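test_that("switching function matches closed-form values and is monotone", {
  p <- switching_params()  # r0 = 0.08 nm, n = 8, m = 12
  expect_equal(switching(0, p), 1, tolerance = 1e-14)
  expect_equal(switching(p$r0, p), 2 / 3, tolerance = 1e-14)
  expect_equal(switching(2 * p$r0, p), 255 / 4095, tolerance = 1e-14)
  ## continuity at r0 via the analytic limit
  expect_equal(switching(p$r0 * (1 + 1e-9), p), 2 / 3, tolerance = 1e-6)
  r <- seq(0, 0.5, by = 0.005)
  expect_true(all(diff(switching(r, p)) < 0))
  expect_true(all(switching(r, p) > 0 & switching(r, p) <= 1))
  expect_error(switching(-0.1, p), "non-negative")
  expect_error(switching_params(r0 = -1))
})

test_that("superposition RMSD agrees with a brute-force rotation search", {
  set.seed(42)
  for (k in 1:3) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(superposition_rmsd(a, b), brute_force_rmsd(a, b),
                 tolerance = 1e-6)
    ## symmetry in the arguments
    expect_equal(superposition_rmsd(a, b), superposition_rmsd(b, a),
                 tolerance = 1e-12)
  }
})

test_that("superposition RMSD is zero under rigid motions and handles edge cases", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  ## identity up to the sqrt of double-precision cancellation noise
  expect_lt(superposition_rmsd(a, a), 1e-6)
  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_lt(superposition_rmsd(a, a %*% rot90), 1e-7)
  m <- random_rigid_motion(3)
  moved <- sweep(a %*% t(m$R), 2, -m$t)
  expect_lt(superposition_rmsd(a, moved), 1e-7)
  ## collinear points do not break the SVD route
  line <- cbind(1:5, 0, 0) * 0.1
  expect_equal(superposition_rmsd(line, line), 0, tolerance = 1e-12)
  expect_error(superposition_rmsd(a, a[1:5, ]), "equal atom counts")
  expect_error(superposition_rmsd(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("superposition RMSD matches bio3d's Kabsch fit", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  ## bio3d rounds to 3 decimals
  expect_equal(superposition_rmsd(a, b), ref, tolerance = 2e-3)
})

test_that("alpha_rmsd counts helical windows", {
  helix <- build_ideal_structure("alpha_helix", 37)
  a <- alpha_rmsd(helix)
  expect_gte(a, 31)
  expect_lte(a, 32)
  ## single-window identity: 6-residue helix is the template itself
  expect_equal(alpha_rmsd(build_ideal_structure("alpha_helix", 6)), 1,
               tolerance = 1e-9)
  expect_lt(alpha_rmsd(build_ideal_structure("extended", 6)), 0.5)
  helix6 <- build_ideal_structure("alpha_helix", 6)
  short <- new_backbone(lapply(helix6$coords, function(m) m[1:5, ]))
  expect_error(alpha_rmsd(short), "at least 6")
})

test_that("alpha_rmsd equals an independent per-window evaluation", {
  bb <- build_ideal_structure("random_coil", 12, seed = 9)
  tmpl <- fragment_template("ideal_alpha")
  p <- switching_params()
  manual <- 0
  for (i in seq_len(bb$n_res - 5)) {
    frag <- matrix(NA_real_, 30, 3)
    r <- 0
    for (res in i:(i + 5)) {
      for (at in c("N", "CA", "CB", "C", "O")) {
        r <- r + 1
        xyz <- bb$coords[[at]][res, ]
        if (at == "CB" && anyNA(xyz)) xyz <- bb$coords$CA[res, ]
        frag[r, ] <- xyz
      }
    }
    manual <- manual + switching(superposition_rmsd(frag, tmpl$coords), p)
  }
  expect_equal(alpha_rmsd(bb), manual, tolerance = 1e-10)
})

test_that("beta segment enumeration follows the separation rule", {
  ## 8 residues: only (1, 6) has the second segment starting >= 3
  ## positions after the first ends
  p8 <- bemdtools:::beta_segment_pairs(8)
  expect_equal(nrow(p8), 1)
  expect_equal(c(p8$i, p8$j), c(1, 6))
  ## 10 residues, hand enumeration: i + 5 <= j, j + 2 <= 10
  p10 <- bemdtools:::beta_segment_pairs(10)
  hand <- rbind(c(1, 6), c(1, 7), c(1, 8), c(2, 7), c(2, 8), c(3, 8))
  expect_equal(as.matrix(p10), hand, ignore_attr = TRUE)
})

test_that("beta_rmsd separates hairpins from helices", {
  hairpin <- build_ideal_structure("beta_hairpin", 16)
  helix <- build_ideal_structure("alpha_helix", 37)
  expect_gte(beta_rmsd_antiparallel(hairpin), 1)
  expect_lt(alpha_rmsd(hairpin), 0.5)
  expect_lt(beta_rmsd_antiparallel(helix), 0.5)
  ## count of near-template fragments from exhaustive enumeration bounds
  ## the smooth count from below (each matching fragment contributes ~1,
  ## every other fragment a positive remainder)
  tmpl <- fragment_template("ideal_antiparallel_beta")
  p <- switching_params()
  pairs <- bemdtools:::beta_segment_pairs(16)
  rmsds <- vapply(seq_len(nrow(pairs)), function(k) {
    frag <- bemdtools:::extract_fragment(
      hairpin, c(pairs$i[k]:(pairs$i[k] + 2), pairs$j[k]:(pairs$j[k] + 2)))
    superposition_rmsd(frag, tmpl$coords)
  }, 0)
  n_match <- sum(rmsds < p$r0)
  expect_gte(n_match, 1)
  expect_gte(beta_rmsd_antiparallel(hairpin), n_match * 2 / 3)
  expect_error(beta_rmsd_antiparallel(build_ideal_structure("extended", 7)),
               "at least 8")
})

test_that("CVs are invariant under rigid motions of the whole structure", {
  for (kind in c("alpha_helix", "beta_hairpin", "random_coil")) {
    bb <- build_ideal_structure(kind, 12, seed = 5)
    m <- random_rigid_motion(17)
    moved <- bemdtools:::transform_backbone(bb, m$R, m$t)
    expect_equal(alpha_rmsd(moved), alpha_rmsd(bb), tolerance = 1e-10)
    expect_equal(beta_rmsd_antiparallel(moved), beta_rmsd_antiparallel(bb),
                 tolerance = 1e-10)
  }
})

test_that("alpha_rmsd decreases monotonically along a helix-to-coil morph", {
  helix <- build_ideal_structure("alpha_helix", 12)
  coil <- build_ideal_structure("extended", 12)
  lam <- seq(0, 1, length.out = 12)
  vals <- vapply(lam, function(l) {
    coords <- lapply(c(N = "N", CA = "CA", CB = "CB", C = "C", O = "O"),
                     function(at) {
                       (1 - l) * helix$coords[[at]] + l * coil$coords[[at]]
                     })
    alpha_rmsd(new_backbone(coords))
  }, 0)
  expect_true(all(diff(vals) <= 1e-9))
  ## bounds hold along the whole morph
  expect_true(all(vals >= 0 & vals <= 12 - 5))
})

test_that("project_cv returns one row per frame and is deterministic", {
  frames <- list(build_ideal_structure("alpha_helix", 10),
                 build_ideal_structure("beta_hairpin", 10))
  cv <- project_cv(frames, times = c(0, 10))
  expect_equal(nrow(cv), 2)
  expect_equal(cv$time, c(0, 10))
  expect_gt(cv$alpha[1], cv$alpha[2])
  expect_identical(cv, project_cv(frames, times = c(0, 10)))
  expect_error(project_cv(list()), "empty trajectory")
})
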