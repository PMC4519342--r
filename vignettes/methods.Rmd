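---
title: "Free-energy surfaces and ensemble reweighting for disordered peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy surfaces and ensemble reweighting for disordered peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(bemdtools)
library(dplyr)
```

## The problem

Intrinsically disordered peptides such as amylin (IAPP, 37 residues) do not
fold into a single structure: they interconvert among random-coil,
partially helical and hairpin-like conformations, and the *populations* of
those states decide observable quantities like NMR chemical shifts.
Estimating those populations from simulation requires (i) collective
variables (CVs) that resolve secondary structure, (ii) enhanced sampling to
cross the barriers between states, (iii) a free-energy surface (FES) over
the CVs, and (iv) reweighting of per-frame observables by the Boltzmann
probabilities the FES implies. `bemdtools` implements that chain at desk
scale, replacing the expensive explicit-solvent molecular dynamics with a
Metropolis sampler on analytic toy potentials whose exact answers are
known, so every stage can be validated end to end.

## Secondary-structure collective variables

`alpha_rmsd()` and `beta_rmsd_antiparallel()` smoothly count 6-residue
backbone fragments close to an ideal helical or antiparallel two-strand
template. For every fragment the optimal-superposition RMSD `r` (Kabsch
algorithm, `superposition_rmsd()`) enters the rational switching function

$$ s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}, \qquad
   r_0 = 0.08\ \mathrm{nm},\; n = 8,\; m = 12, $$

which is 1 for a perfect match and decays past `r0`. The sum over
fragments is therefore roughly the number of residues in that secondary
structure: an ideal 37-residue helix scores close to its 32 windows on the
alpha CV. The parameter set prints `r0 = 0.8` without units; the package
adopts 0.08 nm (0.8 ångström), the convention of the original
implementation era of these CVs — near-ideal fragments superpose at
0.05–0.1 nm, so an `r0` of 0.8 nm would saturate the switch for
everything. `r0`, `n` and `m` are exposed in `switching_params()`.

Fragment conventions the reference description leaves open, fixed here and
testable because templates are *generated* (from canonical dihedrals and
one table of bond geometry, `BACKBONE_GEOMETRY`) rather than shipped as
opaque coordinates:

* fragment atoms are N, CA, CB, C, O per residue, with CA substituted for a
  missing CB (glycine);
* the beta CV pairs 3-residue segments `i..i+2` and `j..j+2` with
  `j >= i + 5` — the second segment starts at least three positions after
  the first ends, the tightest spacing a two-residue turn permits — and
  each unordered pair is counted once;
* the antiparallel template is extracted from an ideal 8-residue hairpin
  built with a type I' turn; equivalence with any particular external
  implementation is not claimed.

## Boundary-corrected metadynamics

Biased replicas deposit Gaussian hills (height 0.1 kJ/mol, width 2.0, one
per ps-equivalent step) on grids spanning −5 to 42 with 2351 nodes per
1D CV (0.02 spacing). Both CVs are non-negative, and the relevant domain
is [0, 32]: near such boundaries plain Gaussians leak part of their mass
outside and systematically under-fill the edge, which shows up as spurious
free-energy minima near 0 RMSD. `corrected_kernel()` therefore
renormalises each hill by the in-domain mass fraction *at the evaluation
point*,

$$ k(s, c) = h\, \frac{G(s - c;\,\sigma)}{M(s)}, \qquad
   M(s) = \prod_d \left[ \Phi\!\left(\tfrac{\mathrm{hi}_d - s_d}{\sigma_d}\right)
        - \Phi\!\left(\tfrac{\mathrm{lo}_d - s_d}{\sigma_d}\right) \right], $$

clamped to the domain edge outside it. Because
$\int_D G(s-x)\,dx = M(s)\,\sigma\sqrt{2\pi}$ per dimension, the *expected*
bias growth under uniform visiting is exactly uniform in $s$ — the
property the flat-potential acceptance check verifies, and the reason this
normalisation (by mass at the point, not at the hill centre) was chosen:
centre-based normalisation conserves each hill's in-domain mass but still
under-fills the extreme edge, and with a slowly-diffusing sampler that
residual seeds a runaway boundary artifact. Hills are truncated at
6 sigma (neglected tail < 2e-8 of the height); hill centres marginally
outside the domain are clamped for the normalisation. A half-harmonic
upper wall (`wall_energy()`, position 7.0 nm, kappa 100 kJ/mol/nm²)
mirrors the end-to-end distance restraint of the reference setup.

## The four-replica bias-exchange sampler

`run_bias_exchange()` runs one unbiased replica, one biased along
alpha_RMSD, one along beta_RMSD and one along both, each a Metropolis
random walk on the same toy potential at 310 K (kT = 2.5775 kJ/mol).
Every `exchange_interval` (default 100) steps one neighbouring pair, in
cyclic order, attempts to swap states with the bias-only criterion

$$ p = \min\left(1, \exp\!\big[(V_a(x_a) + V_b(x_b) - V_a(x_b)
     - V_b(x_a))/kT\big]\right), $$

which leaves each replica's stationary distribution invariant for frozen
biases (verified by exact enumeration on a two-state model). One RNG
stream per replica plus one for the exchange schedule makes trajectories
bit-reproducible and independent of how many replicas run.

The proposal width defaults to 2.0 CV units, deliberately equal to the
hill width: hills drop once per picosecond-equivalent step, and a
picosecond of real dynamics decorrelates these CVs by about the
fluctuation scale the hill width is matched to. Much smaller steps make
the walker deposit dozens of overlapping hills per correlation length;
deposition then stops being quasi-adiabatic, and the time-averaged bias
picks up slow spatial modes of several tenths of kT (with a centre-normalised
kernel they even nucleate a boundary runaway). The width is a config knob
(`sampler$proposal_sigma`), but 2.0 is the default for this reason.
Out-of-domain proposals are rejected (the walker stays), which preserves
the target distribution exactly.

## Free-energy estimation and convergence

The FES comes from the *time-averaged* bias of the doubly-biased replica,
averaged from the beginning of the run: with instantaneous hill deposits
at times $t_k$,

$$ F(s) = -\frac{1}{T - t_0} \int_{t_0}^{T} V(s, t)\,dt + C
       = -\sum_k \frac{T - \max(t_k, t_0)}{T - t_0}\, k(s, c_k) + C, $$

tabulated on a 160 × 160 grid over [0, 32]² and shifted so the minimum is
zero. `t_start` is exposed but defaults to 0; rather than imposing a
burn-in rule, `convergence_trace()` reports class free energies versus the
averaging horizon so convergence can be judged directly. Grid nodes
outside every hill's support are flagged unvisited and carry `NA`, and
`probability_from_fes()` normalises Boltzmann weights over visited bins
only — unexplored regions are never assigned fabricated weight. All
downstream quantities are invariant to the additive offset.

## Reweighting observables

Frames (CV pair, optional per-residue shifts, optional DSSP string) are
assigned to the nearest FES grid point. Per-bin observable means
(`bin_and_average()`) are combined with bin probabilities
(`ensemble_average()`), with probabilities renormalised over the bins that
both hold frames and carry probability. Secondary shifts subtract a
random-coil reference (positive C-alpha values = helical propensity);
amide-proton shifts can be moved between temperatures with experimental
coefficients (`apply_temperature_correction()`, ppb/K). DSSP codes group
as H/G/I = helix, E/B = strand, T = turn, S = bend, everything else coil;
per-residue class fractions are probability-weighted bin fractions, the
peptide-level fraction is their mean over residues, and
`class_free_energy()` reports $-\ln(f_\mathrm{class}/f_\mathrm{coil})$ in
kT. The agreement statistic between predicted and measured shifts is the
mean absolute error per residue, with unassigned residues dropped
pairwise. Both the amide proton (H or HN) and carbonyl (C or CO) naming
dialects are accepted and normalised; both N and CO are supported as
reported atoms.

## Synthetic ground truth

The synthetic module generates every input the pipeline consumes, so the
whole chain runs with known answers and no downloads:

* `toy_potential_wells()` — sums of Gaussian wells with analytic values
  (the quadrature oracle for FES tests);
* `toy_potential_mixture()` — $-kT\log$ of a state-mixture density, so a
  sampler at kT reproduces prescribed state populations exactly;
* `generate_frames()` — i.i.d. frames from coil/helix/hairpin states with
  truncated-Gaussian CVs, state shift means plus Gaussian noise, and fixed
  DSSP strings; pure function of (spec, seed);
* `build_ideal_structure()` — helices, hairpins, extended chains and
  Ramachandran-box random coils from internal coordinates;
* `assign_ss_dihedral()` — a deterministic phi/psi-box labeller used only
  on synthetic structures (it knows nothing of hydrogen bonds and is not a
  DSSP substitute).

The demo ensemble (`demo_ensemble_spec()`) is a 60/25/15
coil/helix/hairpin mixture of a 37-mer with helix C-alpha shifts
+2.5 ppm, hairpin −1.5 ppm and 0.4 ppm frame noise — a mostly disordered
peptide with a significant helical subpopulation, the regime most force
fields predict for rat amylin. What the generator does **not** emulate:
conformational kinetics within states, correlated shift errors, sequence
specificity, or any solvent effect; passing tests therefore validate the
estimators and bookkeeping, not force-field accuracy on real peptides.

## Numerical choices and problem sizes

* Energies are kJ/mol internally; kT conversions (2.5775 kJ/mol at 310 K)
  happen only at report boundaries.
* 2D bias grids default to 471 nodes per dimension (0.1 spacing) — the
  2351-node spacing of the 1D grids is needless for hills of width 2, and
  the dense product grid would cost memory for no accuracy.
* Bilinear interpolation evaluates grids between nodes; exact at nodes.
* Frames bin to the *nearest* grid point; ties cannot occur off the exact
  midpoints of a 0.2-unit grid.
* The packaged demonstrations and checks use 3–100 thousand sampler steps
  and 3–100 thousand frames — sizes at which the statistical errors of
  every estimator are comfortably below the documented tolerances on a
  single CPU in minutes. The same machinery scales linearly for longer
  runs.

## Known limitations

* The sampler moves in CV space; there are no Cartesian forces, no CV
  gradients, and no parallel-beta variant.
* Only the time-averaged-bias estimator is provided (no well-tempered
  variant, no WHAM, no transition-based reweighting), and the FES carries
  no error bars — convergence traces are the diagnostic.
* The ideal-fragment templates are this package's own convention;
  absolute CV values may differ from other implementations by small
  amounts, though the qualitative geometry (helix ~ window count, coil
  near zero) is robust.
* Real chemical-shift prediction and DSSP assignment are consumed as
  inputs, never reimplemented.

## A worked example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(sampler = list(n_steps = 20000L),
                       ensemble = list(n_frames = 20000L), seed = 1L)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$fractions$peptide
res$class_free_energies
autoplot(res$fes, max_kT = 10)
plot_convergence(res$convergence)
```

The peptide-level helix fraction converges to the generator's ground
truth (0.25 × 35/37 ≈ 0.237 for the demo spec), the strand fraction to
0.15 × 22/37 ≈ 0.089, and the class free energies to
$-\ln(f/f_\mathrm{coil})$ of those numbers; the reports under `demo_out/`
carry a provenance block (package version, config hash, seed) and are
byte-identical across reruns with the same seed.
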