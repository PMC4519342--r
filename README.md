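# bemdtools

Free-energy surfaces and NMR ensemble reweighting for intrinsically
disordered peptides, at desk scale.

Disordered peptides like amylin (IAPP, the 37-residue islet amyloid
polypeptide) interconvert among coil, helical and hairpin conformations;
what an NMR experiment sees is the population-weighted average over that
ensemble. `bemdtools` implements the full analysis chain used to compare
simulated ensembles against such data:

* **Secondary-structure collective variables** — α<sub>RMSD</sub> and
  antiparallel β<sub>RMSD</sub>: smooth counts of 6-residue backbone
  fragments close to ideal helix / two-strand templates, via Kabsch
  superposition and the rational switching function
  *s(r) = (1−(r/r₀)⁸)/(1−(r/r₀)¹²)* with r₀ = 0.08 nm.
* **Boundary-corrected metadynamics** — Gaussian hills (0.1 kJ/mol,
  σ = 2.0, one per ps-equivalent step) accumulated on grids (2351 nodes
  over −5..42 per 1D CV), with kernels renormalised by the in-domain mass
  fraction so the bias stays flat up to the CV boundaries at 0 and 32,
  plus a half-harmonic distance wall (7.0 nm, κ = 100 kJ/mol/nm²).
* **Four-replica bias exchange** — unbiased / α-biased / β-biased /
  both-biased Metropolis walkers on analytic toy potentials at 310 K,
  swapping states through the bias-only Metropolis criterion.
* **FES estimation** — F(s) = −⟨V(s,t)⟩ from the time-averaged bias of
  the doubly-biased replica on a 160×160 grid over [0,32]², minimum at
  zero, unvisited bins flagged; convergence traces of class free
  energies versus time.
* **Ensemble reweighting** — per-bin averages of per-residue chemical
  shifts and DSSP secondary-structure fractions, weighted by Boltzmann
  probabilities of the FES; secondary shifts against a random-coil
  reference; amide-proton temperature-coefficient correction; class free
  energies −ln(f/f_coil) in kT; mean-absolute-error shift statistic.
* **Synthetic ground truth** — generators for every input (ideal/coil
  backbone structures, toy potentials with quadrature-exact free
  energies, mixed coil/helix/hairpin frame ensembles with prescribed
  populations, PDB/COLVAR/HILLS/shift-table/DSSP writers), so the whole
  pipeline runs and validates itself with zero downloads.

Everything is tidyverse-shaped: frames, hills, shifts and reports are
tibbles; fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## A worked example

```r
library(bemdtools)

cfg <- pipeline_config(sampler = list(n_steps = 20000L),
                       ensemble = list(n_frames = 20000L), seed = 1L)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$fractions$peptide
#> # A tibble: 5 × 2
#>   class  fraction
#>   <fct>     <dbl>
#> 1 helix   0.266
#> 2 strand  0.0915
#> 3 turn    0.00831
#> 4 bend    0.00831
#> 5 coil    0.626
res$class_free_energies[, c("class", "delta_f_kT")]
#> # A tibble: 4 × 2
#>   class  delta_f_kT
#>   <fct>       <dbl>
#> 1 helix       0.854
#> 2 strand      1.92
#> 3 turn        4.32
#> 4 bend        4.32
```

The synthetic demo ensemble is a 60/25/15 coil/helix/hairpin mixture of a
37-mer, so the ground-truth helix fraction is 0.25·35/37 ≈ 0.236 and the
strand fraction 0.15·22/37 ≈ 0.089: the pipeline — bias-exchange
sampling on the matching mixture potential, FES from the time-averaged
bias, probability-weighted class fractions — recovers both, and
`delta_f_kT` is −ln(f_class/f_coil) in units of kT at 310 K.
`autoplot(res$fes)` draws the free-energy map on the
(α<sub>RMSD</sub>, β<sub>RMSD</sub>) plane;
`plot_convergence(res$convergence)` shows the class free energies
stabilising with averaging time. Reports written to `demo_out/` embed a
provenance block (package version, config hash, seed) and are
byte-identical when re-run with the same seed.

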