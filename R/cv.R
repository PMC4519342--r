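#' Rational switching function
#'
#' The smooth counting kernel used by the secondary-structure collective
#' variables: `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with the analytic
#' limit `n/m` at `r = r0`. It is 1 at `r = 0`, strictly decreasing, and
#' tends to 0 for large `r`, so a sum of `s(RMSD)` over fragments counts,
#' smoothly, the fragments close to an ideal template.
#'
#' @param r Non-negative distance(s) in nm (vectorised).
#' @param params Switching parameters from [switching_params()].
#' @return Dimensionless value(s) in (0, 1].
#' @examples
#' switching(0, switching_params())          # 1
#' switching(0.08, switching_params())       # 2/3, the r = r0 limit
#' @export
switching <- function(r, params = switching_params()) {
  if (any(r < 0)) abort("switching distances must be non-negative")
  x <- r / params$r0
  n <- params$n_exp
  m <- params$m_exp
  out <- numeric(length(x))
  at_limit <- abs(x - 1) < 1e-12
  out[at_limit] <- n / m
  xi <- x[!at_limit]
  out[!at_limit] <- (1 - xi^n) / (1 - xi^m)
  out
}

#' @rdname switching
#' @param r0 Reference distance in nm. The CV parameter set prints 0.8
#'   without units; the package adopts 0.8 angstrom = 0.08 nm, the
#'   convention of the PLUMED-1.x era implementation of these CVs (an
#'   r0 of 0.8 nm would saturate the switch for every near-ideal fragment,
#'   whose RMSDs are ~0.05-0.1 nm).
#' @param n_exp,m_exp Numerator and denominator exponents (8 and 12).
#' @export
switching_params <- function(r0 = 0.08, n_exp = 8L, m_exp = 12L) {
  stopifnot(r0 > 0, n_exp > 0, m_exp > n_exp)
  list(r0 = r0, n_exp = as.integer(n_exp), m_exp = as.integer(m_exp))
}

#' Optimal-superposition RMSD between two ordered point sets
#'
#' Minimal root-mean-square deviation over all rigid rotations and
#' translations (Kabsch algorithm: centre both sets, rotate by the SVD
#' solution with a determinant correction against improper rotations).
#'
#' @param frag_a,frag_b Numeric `k x 3` matrices, `k >= 3`, same `k`.
#' @return RMSD in the coordinate units of the inputs.
#' @export
superposition_rmsd <- function(frag_a, frag_b) {
  if (!is.matrix(frag_a) || !is.matrix(frag_b) ||
      ncol(frag_a) != 3 || ncol(frag_b) != 3) {
    abort("fragments must be k x 3 coordinate matrices")
  }
  if (nrow(frag_a) != nrow(frag_b)) abort("fragments must have equal atom counts")
  if (nrow(frag_a) < 3) abort("need at least 3 atoms for superposition")
  if (!all(is.finite(frag_a)) || !all(is.finite(frag_b))) {
    abort("fragment coordinates must be finite")
  }
  a <- sweep(frag_a, 2, colMeans(frag_a))
  b <- sweep(frag_b, 2, colMeans(frag_b))
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- c(1, 1, d)
  ## min RMSD^2 = (|a|^2 + |b|^2 - 2 * sum(s * singular values)) / k
  msd <- (sum(a * a) + sum(b * b) - 2 * sum(s * sv$d)) / nrow(a)
  sqrt(max(msd, 0))
}

## ---- fragment templates -------------------------------------------------

#' Ideal fragment templates for the secondary-structure CVs
#'
#' Templates are generated from canonical dihedrals with the same builder
#' used for query structures, rather than shipped as opaque coordinate
#' constants. The alpha template is 6 consecutive residues of an ideal
#' helix; the antiparallel beta template is the two 3-residue strands of a
#' minimal ideal hairpin (residues 1-3 and 6-8 of an 8-residue hairpin).
#' Each template is the stacked `30 x 3` matrix of backbone atoms
#' (N, CA, CB, C, O per residue) in nm.
#'
#' @param kind `"ideal_alpha"` or `"ideal_antiparallel_beta"`.
#' @return A list with `kind` and the `30 x 3` coordinate matrix `coords`.
#' @export
fragment_template <- function(kind = c("ideal_alpha", "ideal_antiparallel_beta")) {
  kind <- match.arg(kind)
  coords <- if (kind == "ideal_alpha") {
    helix <- build_ideal_structure("alpha_helix", 6)
    extract_fragment(helix, 1:6)
  } else {
    hairpin <- build_ideal_structure("beta_hairpin", 8)
    extract_fragment(hairpin, c(1:3, 6:8))
  }
  list(kind = kind, coords = coords)
}

## Stack backbone atoms of the given residues into a (5*length(idx)) x 3
## matrix, substituting CA for a missing CB (glycine).
extract_fragment <- function(bb, idx) {
  out <- matrix(NA_real_, 5L * length(idx), 3)
  r <- 0L
  for (i in idx) {
    for (at in BACKBONE_ATOMS) {
      r <- r + 1L
      xyz <- bb$coords[[at]][i, ]
      if (at == "CB" && anyNA(xyz)) xyz <- bb$coords$CA[i, ]
      out[r, ] <- xyz
    }
  }
  out
}

## ---- the CVs ------------------------------------------------------------

#' Secondary-structure collective variables
#'
#' `alpha_rmsd()` sums `switching(RMSD)` over every contiguous 6-residue
#' window against the ideal helical template; it varies from ~0 for a coil
#' to `n_res - 5` (32 for a 37-mer) for an ideal helix, and is roughly the
#' number of residues in a helix. `beta_rmsd_antiparallel()` does the same
#' over composite 6-residue fragments built from two 3-residue segments
#' `i..i+2` and `j..j+2` with the second segment starting at least 3
#' positions after the first ends (`j >= i + 5`), against the ideal
#' antiparallel two-strand template.
#'
#' @param structure A [new_backbone()] object.
#' @param template A [fragment_template()]; defaults to the matching kind.
#' @param params Switching parameters ([switching_params()]).
#' @return A non-negative dimensionless count.
#' @examples
#' helix <- build_ideal_structure("alpha_helix", 12)
#' alpha_rmsd(helix)  # ~7 = 12 - 5 windows, all matching
#' @export
alpha_rmsd <- function(structure, template = fragment_template("ideal_alpha"),
                       params = switching_params()) {
  if (structure$n_res < 6) abort("alpha_rmsd needs at least 6 residues")
  windows <- seq_len(structure$n_res - 5L)
  sum(vapply(windows, function(i) {
    frag <- extract_fragment(structure, i:(i + 5L))
    switching(superposition_rmsd(frag, template$coords), params)
  }, 0))
}

#' @rdname alpha_rmsd
#' @export
beta_rmsd_antiparallel <- function(structure,
                                   template = fragment_template("ideal_antiparallel_beta"),
                                   params = switching_params()) {
  if (structure$n_res < 8) abort("beta_rmsd needs at least 8 residues")
  pairs <- beta_segment_pairs(structure$n_res)
  if (nrow(pairs) == 0) return(0)
  sum(vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    frag <- extract_fragment(structure, c(i:(i + 2L), j:(j + 2L)))
    switching(superposition_rmsd(frag, template$coords), params)
  }, 0))
}

## Enumerate (i, j) segment-start pairs: segments i..i+2 and j..j+2 with
## j >= i + 5 (second segment starts >= 3 positions after the first ends);
## only i < j is kept, so each composite fragment is counted once.
beta_segment_pairs <- function(n_res) {
  grid <- expand.grid(i = seq_len(n_res), j = seq_len(n_res))
  keep <- grid$j >= grid$i + 5L & grid$j + 2L <= n_res & grid$i + 2L <= n_res
  tibble(i = grid$i[keep], j = grid$j[keep]) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Project structures onto the (alpha_RMSD, beta_RMSD) plane
#'
#' Evaluates both CVs for each frame of a trajectory, the projection used
#' to locate coil, helical and hairpin states on the free-energy surface.
#'
#' @param frames A `backbone` object or list of them.
#' @param times Optional frame times in ps (default 0, 1, 2, ...).
#' @inheritParams alpha_rmsd
#' @return A tibble with columns `time`, `alpha`, `beta`.
#' @export
project_cv <- function(frames, times = NULL, params = switching_params()) {
  if (inherits(frames, "backbone")) frames <- list(frames)
  if (length(frames) == 0) abort("empty trajectory: no frames to project")
  times <- times %||% (seq_along(frames) - 1)
  tmpl_a <- fragment_template("ideal_alpha")
  tmpl_b <- fragment_template("ideal_antiparallel_beta")
  purrr::imap_dfr(frames, function(fr, k) {
    tibble(time = times[[k]],
           alpha = alpha_rmsd(fr, tmpl_a, params),
           beta = beta_rmsd_antiparallel(fr, tmpl_b, params))
  })
}
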