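# qmregion

Electronically informed QM/MM region selection from fragment molecular
orbital (FMO) descriptors.

## The problem

Hybrid QM/MM calculations treat a chemically critical region quantum
mechanically and the rest of the system as classical point charges. Their
predictive power hinges on where that boundary is drawn, and common practice
— distance cutoffs around the ligand, or hand-picked residue lists — ignores
the long-range electronic response that guest binding actually induces in
the host. `qmregion` implements a protocol that derives the QM region from
the electronic response itself, measured fragment by fragment in an
FMO-style calculation:

- **MO-shift analysis.** For every host fragment the HOMO–LUMO gap is
  computed in the guest-free (*apo*) and guest-bound (*holo*) states. The
  shift Δε(R) decays with the fragment's minimum distance R_min to the
  guest; the smallest radius R_conv beyond which |Δε| ≤ δ for every fragment
  defines the *MO-based* QM region {fragment : R_min ≤ R_conv}.
- **Charge-redistribution analysis.** Dimer-level (FMO2) Mulliken charge
  shifts δq give a directed charge-flow network between fragments; *hub*
  fragments that mediate coupling between fragments with no direct edge
  (mediation triplets i–k–j with no i–j edge) are ranked by triplet count
  and betweenness.
- **Region benchmarking.** Empirical, short-range (5 Å ∪ |E_int| > 2
  kcal/mol) and MO-based regions are evaluated against the all-QM reference:
  binding energies E_bind = E(complex) − E(host) − E(guest), guest IP/EA
  (Koopmans: IP = −ε_HOMO, EA = −ε_LUMO), and PIEDA-style pair interaction
  components (electrostatic, exchange-repulsion, charge-transfer,
  dispersion), with signed deviation tables and rank agreement against
  experimental activities (Spearman/Kendall).

So that the whole pipeline runs at desk scale, the package ships its own
electronic-structure engine: a one-orbital self-consistent-charge (SCC)
tight-binding model (distance-decaying hopping, Klopman–Ohno charge kernel,
Born–Mayer repulsion, damped dispersion) with an FMO1 monomer loop in
point-charge embedding and FMO2 dimer corrections. Seeded generators produce
host–guest complexes, planted-decay shift profiles and planted-hub networks
with known ground truth, so every detection step is testable.

## Worked example

```r
library(qmregion)

sys <- gen_host_guest(seed = 1)          # 44-atom host cage + C3O2(+) guest
cfg <- pipeline_config(sys$complex, fragmap = sys$fragmap, delta = 0.05,
                       region_modes = c("mo_based", "short_range", "whole"),
                       out_dir = "run1")
res <- run_protocol(cfg)

res$rconv
#> <convergence_radius> R_conv = 12.272 A (strict mode, delta = 0.05 eV)
#>   tail max |delta_eps| beyond R_conv: 0.02022 eV; 11 fragments

head(res$profile[, c("fragment_id", "name", "rmin", "delta_eps", "delta_q")], 5)
#> # A tibble: 5 × 5
#>   fragment_id name       rmin delta_eps   delta_q
#>         <int> <chr>     <dbl>     <dbl>     <dbl>
#> 1           1 shell1_01  3.49   -0.269   8.89e- 2
#> 2           3 shell2_03  7.50   -0.0865 -1.89e-15
#> 3           4 shell2_04  7.89   -0.109  -5.55e-16
#> 4           2 shell2_02  7.93   -0.0994  1.99e- 2
#> 5           7 shell3_07 11.7    -0.0534 -5.55e-16

res$observables[, c("model", "n_fragments", "n_atoms", "e_bind", "ip", "ea")]
#> # A tibble: 3 × 6
#>   model       n_fragments n_atoms e_bind    ip    ea
#> 1 mo_based              8      33  -2.14  11.6  10.0
#> 2 short_range           2       9  -2.59  11.6  10.0
#> 3 whole                12      49  -2.18  11.6  10.0
```

Reading the output: the fragment closest to the guest (R_min 3.5 Å) shows a
gap shift of −0.27 eV, an order of magnitude above the 0.05 eV tolerance,
and the shift decays with distance; the strict criterion is first satisfied
at R_conv ≈ 12.3 Å. The MO-based region (33 of 49 atoms) reproduces the
all-QM binding energy to 0.04 kcal/mol, while the much smaller short-range
region misses it by 0.4 kcal/mol — the fidelity ordering the protocol is
designed to expose. `autoplot(res$profile, delta = 0.05)` draws the decay
profile, `autoplot(res$network)` the radial charge-flow graph, and
`res$comparison` is the signed deviation table against the whole-system
reference.

Published benchmark tables for the two validation systems (a CHA zeolite
with a templating organic cation, and the cathepsin L inhibitor series) ship
with the package: `benchmark_tables()` returns the per-model QM-atom counts,
guest IP/EA values, binding energies and experimental pIC50 series that the
benchmark helpers reproduce arithmetically.

A thin command-line front end wrapping the same functions is installed at
`system.file("cli", "qmregion.R", package = "qmregion")` (subcommands:
`fragments`, `rmin`, `shift`, `radius`, `select`, `simulate`, `run`).

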