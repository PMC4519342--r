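## Internal-coordinate geometry: torsions and NeRF atom placement.
## All positions are 3-vectors in nm; angles in degrees at the interface.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("degenerate zero-length vector in geometry")
  v / n
}
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle defined by four points
#'
#' IUPAC sign convention: looking along b–c, the angle from the a–b–c plane
#' to the b–c–d plane, positive clockwise. Used to verify builder round-trips
#' and to assign secondary structure from phi/psi.
#'
#' @param a,b,c,d Numeric 3-vectors (nm).
#' @return Torsion in degrees in (-180, 180].
#' @keywords internal
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

## NeRF: place atom D given positions A, B, C, bond |C-D|, angle B-C-D and
## torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, tors) {
  th <- deg2rad(angle)
  ph <- deg2rad(tors)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + bond * (-cos(th) * bc + sin(th) * cos(ph) * m - sin(th) * sin(ph) * n)
}

## CB from N, CA, C by tetrahedral construction: equal-angle direction out of
## the N-CA-C plane, angle N-CA-CB per BACKBONE_GEOMETRY, fixed chirality.
place_cb <- function(n, ca, c, geom = BACKBONE_GEOMETRY) {
  u1 <- vunit(n - ca)
  u2 <- vunit(c - ca)
  bis <- -vunit(u1 + u2)
  nrm <- vunit(vcross(u1, u2))
  cos_target <- cos(deg2rad(geom$a_n_ca_cb))
  cos_a <- cos_target / sum(bis * u1)
  cos_a <- max(min(cos_a, 1), -1)
  sin_a <- sqrt(1 - cos_a^2)
  ca + geom$b_ca_cb * (cos_a * bis + sin_a * nrm)
}

## Build backbone coordinates from per-residue (phi, psi) in degrees.
## phi[1] is ignored (no preceding carbonyl); psi[n] orients the final O.
## Returns a list of n_res x 3 matrices for N, CA, CB, C, O.
build_backbone_coords <- function(phi, psi, geom = BACKBONE_GEOMETRY) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 1)
  N <- CA <- CB <- C <- O <- matrix(NA_real_, n_res, 3)

  ## seed residue 1 in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(geom$b_n_ca, 0, 0)
  th <- deg2rad(geom$a_n_ca_c)
  C[1, ] <- CA[1, ] + geom$b_ca_c * c(-cos(th), sin(th), 0)

  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           geom$b_c_n, geom$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            geom$b_n_ca, geom$a_c_n_ca, geom$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           geom$b_ca_c, geom$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         geom$b_c_o, geom$a_ca_c_o, psi[i] + 180)
    CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ], geom)
  }
  list(N = N, CA = CA, CB = CB, C = C, O = O)
}

## phi/psi of an existing backbone; terminal undefined angles are NA.
backbone_dihedrals <- function(coords) {
  n_res <- nrow(coords$N)
  phi <- psi <- rep(NA_real_, n_res)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      phi[i] <- torsion_angle(coords$C[i - 1, ], coords$N[i, ],
                              coords$CA[i, ], coords$C[i, ])
    }
    if (i < n_res) {
      psi[i] <- torsion_angle(coords$N[i, ], coords$CA[i, ],
                              coords$C[i, ], coords$N[i + 1, ])
    }
  }
  tibble(resid = seq_len(n_res), phi = phi, psi = psi)
}
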