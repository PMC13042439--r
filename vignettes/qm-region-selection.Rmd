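---
title: "Electronically informed QM-region selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronically informed QM-region selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmregion)
```

`qmregion` turns ligand-induced electronic responses into QM/MM region
definitions. This vignette is the package's account of the underlying
models: what is computed, which knobs matter, what the synthetic generators
do and do not emulate, and where the design was genuinely open.

## The descriptor protocol

Two per-fragment descriptors are extracted from a pair of fragment-based
electronic-structure runs, one on the host alone (*apo*) and one on the
host-guest complex (*holo*):

* **Gap shift** `delta_eps = gap(holo) - gap(apo)`, the change of a
  fragment's HOMO-LUMO gap induced by guest binding. Following the
  convention used for this analysis in the field, the shift is defined on
  the gap, not on the individual orbital energies; per-orbital shifts are
  available from the stored states. Plotted against the fragment's minimum
  interatomic distance to the guest, `R_min`, these shifts decay; the
  smallest radius beyond which every `|delta_eps|` falls under a tolerance
  `delta` is the convergence radius `R_conv`, and `{R_min <= R_conv}` is the
  *MO-based* QM region.
* **Charge shift** `delta_q`, the binding-induced change of the fragment's
  Mulliken charge. Monomer net charges are constrained to the fragment's
  formal charge by construction, so meaningful charge redistribution only
  appears at the dimer level: `fmo2_fragment_charges()` adds the
  dimer-minus-monomer shifts onto the monomer charges (these corrections
  conserve total charge pairwise and exactly). The same dimer shifts supply
  the directed edges of the charge-flow network, and fragments that mediate
  a triplet i-k-j whose ends share no direct edge are *hub* candidates,
  ranked lexicographically by (triplet count, betweenness centrality on the
  undirected thresholded graph), ties broken by fragment id. "Hub" has no
  standard operational definition; the mediation-triplet reading was chosen
  because it is directly testable against planted network topologies.

## The tight-binding engine

The engine is a deliberately minimal stand-in for semiempirical DFTB: one
s-like orbital per atom in an orthogonal basis.

* Hopping `H_ab = beta0 * exp(-kappa (r_ab - r0))` for `r_ab <=
  hop_cutoff`, zero beyond. Defaults: `beta0 = -2.5` eV, `kappa = 1.2` 1/A,
  `r0 = 1.4` A, cutoff 6 A — strong enough at bonded distances (1.2-2.5 A)
  that covalent splittings dominate onsite differences, which keeps cluster
  spectra gapped.
* Onsite `H_aa = alpha_a - sum_b gamma_ab q_b - V_ext(a)`, with the
  Klopman-Ohno kernel `gamma_ab = k_e / sqrt(r^2 + (k_e/U_avg)^2)`
  (`gamma_aa = U_a`, `k_e = 14.399` eV A). Charges are Mulliken-style,
  positive = electron-deficient; a positive external charge lowers nearby
  onsite levels, and a remote unit charge shifts all levels by `-k_e/R`
  (bare point charges use the unsoftened Coulomb kernel; embedding charges
  carry the Hubbard parameter of their source atom so monomer-embedding
  electrostatics match the pair kernel exactly).
* Total energy is the variationally consistent functional
  `E = tr(P H0) + 1/2 q' Gamma q + E_rep - E_disp + sum_a q_a V_ext(a)`;
  evaluating the band term against the charge-independent `H0` avoids double
  counting the Coulomb shift already contained in the occupied eigenvalues,
  and is what makes the size-consistency and non-interacting-limit
  identities hold to floating-point accuracy.
* Occupations are integers: lowest orbitals filled pairwise, one singly
  occupied orbital for odd electron counts, no spin polarization. Degenerate
  frontier levels are resolved by orbital index after a stable ascending
  sort, so results are deterministic.
* SCC loop: linear mixing (default 0.2) to a tolerance of 1e-6 e on the
  atomic charges, at most 200 iterations, then one deterministic damped
  restart at a quarter of the mixing with a fourfold iteration budget. After
  convergence the state is re-evaluated once at the output charges so all
  reported quantities refer to a single consistent charge vector.

The Hubbard parameters ship at 3.8-7 eV, roughly half of typical DFTB
values. This is an engine design choice, not a fit: with integer
occupations, the self-consistency loop develops period-two charge sloshing
whenever `U`-driven level shifts exceed frontier gaps (the discrete filling
makes the charge map discontinuous at level crossings, and no damping can
cross a discontinuity that sits between the iterate and the fixed point).
Softer `U` keeps the self-consistent shifts below the gaps of bonded
clusters while preserving the charge physics the descriptors need. The same
mechanism defines the engine's *robust domain*: gapped, closed-shell
subsystems. Whole-system solves of a charged complex can leave that domain
— a +1 guest shifts inner-shell levels by more than a fragment gap relative
to outer shells, so the integer-filling ground state is a charge-transferred
configuration that differs from the FMO ansatz. The FMO layer is unaffected
(each monomer keeps its formal charge), which is precisely why the
fragment-based route remains well-posed where the global solve is not; the
package's exactness tests therefore use neutral bonded-chain fixtures for
whole-system references.

## The FMO layer

`fmo1()` sweeps all QM fragments in ascending id order, each solved in the
point charges of every other fragment (QM charges updated Gauss-Seidel
style with damping 0.5, MM charges fixed), until the global charge vector
changes by less than `outer_tol` (default 1e-6 e; monomers are converged two
orders tighter so inner noise cannot stall the outer test). A final frozen
sweep makes all stored monomer states consistent with one embedding.

`fmo2()` computes explicit dimers for QM pairs within `dimer_cutoff`
(default 6 A, equal to the hopping cutoff) and decomposes
`E_int = E'_IJ - E'_I - E'_J` into frozen-charge electrostatics (ES),
pairwise Born-Mayer exchange repulsion (EX), damped `-C6/r^6` dispersion
(DI), and a charge-transfer remainder (CT). Because CT is defined by
remainder it also absorbs mutual polarization; the published PIEDA
formalism separates these, and this simplification is intentional. Beyond
the cutoff no hopping — hence no charge transfer — is possible, so the
frozen-charge `ES + EX + DI` correction is exact there and no dimer is
solved; this also avoids a numerical pathology of far dimers whose embedded
levels cross (two disjoint subsystems exchanging integer electrons cannot
converge under integer filling). Monomer and dimer energies entering the
assembly are *internal* energies (embedding-interaction term stripped), so
one fragment, and two fragments with their dimer, reproduce the
whole-system energy identically.

`system_energy()` adds frozen-charge electrostatics for MM fragments
(QM-MM and MM-MM). MM fragments carry per-atom Mulliken charges from an
all-QM reference run of the host alone ("frozen_reference", the default;
formal charges spread uniformly are the fallback) — the source of MM
charges is not standardized in practice, and this choice makes the MM
description exact in the apo limit. Binding energies are purely electronic
differences at fixed geometry; MM-region van der Waals terms, solvation and
geometry relaxation are out of scope. Energies are eV internally and
kcal/mol at the interface (1 eV = 23.0609 kcal/mol).

## Region definitions

* *Empirical*: an explicit fragment list (the literature lists behind such
  models are system-specific, so this mode requires the user's list).
* *Short-range*: guest plus fragments with `R_min <= 5` A **union**
  fragments with `|E_int| > 2` kcal/mol against the guest. The conjunction
  is ambiguous in common usage; the union is implemented as the
  conservative (larger-region) reading, with `intersect = TRUE` available.
  The energy test uses the absolute value since attractive energies are
  negative.
* *MO-based*: guest plus `R_min <= r_conv`, boundary inclusive.

All regions always include the guest; `region_partition()` turns a region
into a QM/MM partition. MO-based regions are nested in `r_conv` by
construction.

`convergence_radius()` implements the strict criterion literally: the
smallest sampled radius such that every fragment strictly beyond it
satisfies `|delta_eps| <= delta` (0 if all rows do). The largest sampled
radius is excluded from the candidate list — declaring convergence there
would be vacuous, and a profile whose outermost fragment still violates the
bound is returned with `converged = FALSE`. A quantile mode replaces
"every" by a tail quantile for noisy profiles. The default `delta = 0.01`
eV is a package choice (no standard value exists); on the toy engine's own
fixtures the natural gap-shift scale is larger (about 0.05-0.3 eV near the
guest), so the worked examples use `delta = 0.05` eV. The strict detector
is by construction an extreme-value statistic: its location is set by the
single largest offender, so under noise comparable to `delta` its variance
is governed by the noise tail, and on randomly sampled radii its resolution
is the local sample spacing at the crossover (an exponential, not constant,
quantity). The planted-decay tests measure exactly this behaviour.

## What the generators emulate — and what they do not

`gen_host_guest()` builds the study system for all statistical tests: a
small guest cluster at the centre of three concentric shells of host
fragments (fragment centres at 5, 9.5 and 14 A by default; 11 host
fragments of 4 atoms; jitter 0.1 A). Design choices, made once:

* Host fragments are compact *dimerized rings* (alternating short/long
  bonds), the Peierls mechanism that gaps a half-filled cluster regardless
  of composition. Elements are assigned per short pair (Si-Si and C-C
  pairs), which localizes HOMO and LUMO on chemically distinct pairs at
  different radii and makes the fragment's gap response to the guest field
  first-order and sign-definite.
* Ring planes contain the radial direction (random azimuth). A tangentially
  oriented ring sees a single distance and would show no gap response *by
  symmetry*; constraining the orientation ensures the response vanishes
  with distance, not with orientation — which is the decay the descriptors
  are designed to detect.
* The guest is a C3 triangle capped by two O atoms carrying formal charge
  +1 (a templating cation): a closed shell whose monopole field supplies a
  strong, monotonically decaying perturbation.

What passing tests on these fixtures do *not* show: real hosts screen
electrostatics (the toy's vacuum monopole/dipole tails decay as power laws,
so toy `R_conv` values sit closer to the system boundary than screened
DFTB profiles would suggest); real fragments have many orbitals, covalent
boundary caps and conformational disorder; and the C-C bond-detachment
convention used for covalent fragment boundaries is not modelled — severed
bonds simply lose their hopping terms. Waters and ions, when present in
PDB inputs, default to host-like "solvent" fragments. Hydrogens absent
from PDB inputs are not added.

`gen_decay_profile()` plants `delta_eps = +/- A exp(-R/lam) + eta` with
`R ~ U(0, r_max]` and Gaussian noise, storing the analytic crossover
`lam * log(A/delta)`; `gen_hub_network()` plants hub-spoke stars (spokes
never interconnected) plus noise edges restricted to filler nodes of degree
at most two, so no unplanted node can reach the triplet count of a planted
hub and recovery is exactly testable.

## Numerical conventions and problem sizes

Internal atom indices are 1-based (the natural R convention); every
serialized artifact — fragment-map JSON, emitted atom lists — uses 0-based
indices, stated in the schema and file headers. Fragment sweep order,
eigenvalue sorting, tie-breaking and hub ranking are all deterministic, so
identical inputs give byte-identical outputs; the pipeline writes a
manifest with an input hash and per-file checksums and reproduces itself
exactly under `force = TRUE`.

The statistical suites run at desk scale by choice: 200 randomized chains
(8-40 atoms) for exactness and charge conservation, 100 planted profiles of
500 fragments for crossover recovery, 50 planted networks of 40 nodes for
hub recovery, 50 generated complexes for the nearest-fragment census, and
20 complexes for the nested-radii binding-energy comparison (regions at
cavity+1 and cavity+3 A against the all-QM reference). These sizes give
stable statistics for every claim the tests assert while keeping a full
run in minutes on one core.

## Known limitations

* One orbital per atom: no hybridization, no link-atom treatment, Koopmans
  IP/EA only (whether published IP/EA tables of this kind are Koopmans or
  delta-SCF values is usually unstated; here they are defined as Koopmans).
* Integer occupations: open-shell and level-crossing situations outside the
  gapped domain do not converge; the engine reports `converged = FALSE`
  honestly rather than smearing occupations.
* CT-by-remainder PIEDA; electrostatic-only MM coupling; no three-body
  (FMO3) terms, BSSE, PCM/implicit solvation, or geometry optimization.
* The charge-flow edge definition (dimer Mulliken shifts) is one consistent
  reading of how such arrows can be derived; alternatives (CT energies,
  global charge bookkeeping) would give different edge weights.
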