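#' Physical and geometric constants
#'
#' Thermal energy and ideal backbone geometry used throughout the package.
#' All energies are kJ/mol, all lengths nm, all angles degrees unless noted.
#'
#' `kT_at()` returns the thermal energy k_B*T in kJ/mol. At the reference
#' temperature of 310 K this is 2.5775 kJ/mol, the unit in which class free
#' energies are conventionally reported for amylin.
#'
#' @param temperature Temperature in kelvin.
#' @return `kT_at()`: thermal energy in kJ/mol.
#' @examples
#' kT_at(310) # 2.577
#' @export
kT_at <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  0.0083145 * temperature
}

## kT at 310 K as printed in class free-energy tables (kT units at 310 K)
KT_310 <- 2.5775

## Ideal backbone geometry, single source of truth for structure builders
## and CV fragment templates. Lengths nm, angles degrees.
BACKBONE_GEOMETRY <- list(
  b_n_ca  = 0.1458,  # N-CA bond
  b_ca_c  = 0.1525,  # CA-C bond
  b_c_n   = 0.1329,  # C-N peptide bond
  b_c_o   = 0.1231,  # C=O carbonyl
  b_ca_cb = 0.1521,  # CA-CB
  a_n_ca_c  = 111.2, # backbone angles
  a_ca_c_n  = 116.2,
  a_c_n_ca  = 121.7,
  a_ca_c_o  = 120.8,
  a_n_ca_cb = 110.4,
  omega     = 180.0  # trans peptide bond
)

## Canonical dihedrals (phi, psi) in degrees per secondary-structure kind
IDEAL_DIHEDRALS <- list(
  alpha_helix       = c(phi = -57,  psi = -47),
  antiparallel_beta = c(phi = -139, psi = 135),
  extended          = c(phi = -180, psi = 180),
  # type I' turn positions used in the hairpin builder
  turn1             = c(phi = 60,   psi = 30),
  turn2             = c(phi = 90,   psi = 0)
)

## Ramachandran boxes for the dihedral-based secondary-structure stand-in
## (fixtures only; not a DSSP replacement)
RAMA_BOXES <- list(
  helix = list(phi = c(-100, -30), psi = c(-80, -5)),
  beta  = list(phi = c(-180, -90), psi = c(90, 180))
)

BACKBONE_ATOMS <- c("N", "CA", "CB", "C", "O")

`%||%` <- rlang::`%||%`
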