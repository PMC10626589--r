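---
title: "The density-based many-body expansion: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The density-based many-body expansion: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmbe)
```

## The problem

High-accuracy quantum-chemical methods scale steeply with system size —
CCSD(T), the usual "gold standard", as the seventh power of the basis-set
count — which puts even medium-sized molecular clusters out of reach as a
single calculation. Fragmentation methods sidestep this: a cluster of
molecules (water clusters being the canonical case) partitions naturally
into fragments, and the many-body expansion (MBE) writes the total energy as

$$
E \;=\; \sum_I E_I^{(1)} \;+\; \sum_{I<J}\Delta E_{IJ}^{(2)}
  \;+\; \sum_{I<J<K}\Delta E_{IJK}^{(3)} \;+\;\dots
$$

where $E_I^{(1)}$ are monomer energies and the $k$-mer interaction energies
$\Delta E_S$ are defined by inclusion–exclusion over the subsets of $S$.
Truncating at order $n$ (the *eb-MBE(n)*, energy-based) needs only
calculations on subsystems of up to $n$ fragments — $\sum_{k\le n}\binom{N}{k}$
of them — all independent and embarrassingly parallel. The catch is slow
convergence: for hydrogen-bonded clusters, cooperative polarization puts tens
of kJ/mol into the three-body terms, so eb-MBE(2) is often far from the
4 kJ/mol threshold of chemical accuracy.

## The density-based correction

The same expansion can be applied to the electron density,
$\rho^{(n)} = \sum_S c_S\, \rho_S$, and that expansion converges faster than
the energy's. The density-based MBE (db-MBE) exploits this with an
ONIOM-style two-level construction: the eb-MBE is the high level, and
orbital-free density-functional theory — the total-energy functional
evaluated directly on densities, without orbitals — is the low level:

$$
E_\text{db-MBE}^{(n)} \;=\; E_\text{eb-MBE}^{(n)}
 \;+\; \underbrace{E_\text{tot}[\rho^{(n)}] - E_\text{tot}^{(n)}}_{E^{(n)}_\text{db-corr}}
$$

with $E_\text{tot}[\rho] = T_s[\rho] + V_\text{nuc}[\rho] + J[\rho] +
E_{xc}[\rho] + E_{NN}$ and $E_\text{tot}^{(n)}$ its own term-wise MBE over
the subsystem densities. The correction decomposes into five terms
(`db_correction()` reports each):

* $V_\text{nuc}[\rho^{(n)}] - V^{(n)}_\text{nuc}$ — electron–nuclei
  attraction, where the full-cluster nuclei act on the expanded density but
  each subsystem term uses only its own nuclei;
* $J[\rho^{(n)}] - J^{(n)}$ — Coulomb repulsion;
* $E_{NN} - E^{(n)}_{NN}$ — nuclear repulsion, which is pairwise additive
  and therefore vanishes identically for every $n \ge 2$ (the package
  returns an exact zero there rather than a rounded one);
* the nonadditive kinetic term $\tilde T_s[\rho^{(n)}] - \tilde T_s^{(n)}$;
* the nonadditive exchange–correlation term
  $\tilde E_{xc}[\rho^{(n)}] - \tilde E_{xc}^{(n)}$.

The tilde marks semilocal (GGA) approximations: because the *same*
approximate functional appears on both sides of each difference, only the
nonadditive part — the inter-fragment kinetic and exchange–correlation
physics that the truncated eb-MBE misses — carries functional error. At
$n = N$ every difference cancels exactly and db-MBE reduces to the
supermolecular energy; this is not approximate but an algebraic identity on
a shared integration grid, and the test suite asserts it to 10⁻⁸ Hartree.

The energies entering the eb-MBE and the densities entering the correction
are independent choices (`run_dbmbe(..., density_backend = )`): a high-level
method can supply the energy ledger while a cheaper single-determinant
density (e.g. Hartree–Fock) feeds the correction, which is the configuration
of practical interest since correlated densities are expensive to obtain.

## Expansion algebra

Interaction energies are evaluated bottom-up with memoization,
$\Delta E_S = E_S - \sum_{T\subsetneq S}\Delta E_T$, which is algebraically
identical to the Möbius form
$\Delta E_S = \sum_{T\subseteq S} (-1)^{|S|-|T|} E_T$; the tests compare the
two routes on random ledgers to 10⁻¹² Hartree. For the density (and any
other quantity linear in per-subsystem contributions) the truncated
expansion collapses to a single weighted sum with closed-form signed
coefficients

$$
c_k \;=\; (-1)^{\,n-k}\binom{N-k-1}{\,n-k\,},\qquad k \le n,
$$

applied uniformly to every order-$k$ subsystem (`expansion_coefficients()`).
These weights satisfy $\sum_k c_k \binom{N-1}{k-1} = 1$, so the expanded
density integrates to the exact electron count at every truncation order —
an identity the suite checks in exact integer arithmetic for all
$N \le 8$ and by quadrature on the fixtures.

For $V_\text{nuc}$ and $J$, both evaluation routes are implemented: the
recursive order-by-order accumulation (the default reporting path) and the
"accumulate the field, then evaluate" path. They are mathematically
identical; keeping both turns each into a cross-check of the other, and the
Coulomb term gets a third route (the pairwise double sum
`coulomb_energy_pairwise()`) used as a test oracle.

## Numerics

**Shared supermolecular grid.** All densities are sampled on one
atom-centered Becke grid spanning the whole cluster
(`build_supermolecular_grid()`): Gauss–Chebyshev radial points under Becke's
rational map $r = R_m(1+x)/(1-x)$ with $R_m$ from Bragg–Slater radii (halved
except for H and He, floored at 0.4 Bohr so diffuse toy densities stay
resolved), a Gauss–Legendre × uniform-azimuth angular product rule, and
Becke's smooth cell weights (three smoothing iterations). Using *one* grid
for every subsystem is essential: the signed combinations of the expanded
density then cancel exactly in quadrature, which is what makes the
full-order correction vanish to round-off rather than to grid accuracy.
Levels 1–4 range from roughly 3 800 to 56 000 points per atom. The default
(level 3) integrates a water monomer's Hartree–Fock density to its electron
count within about 2×10⁻⁶ and reproduces erf-form Gaussian electrostatics to
about 10⁻⁶ a.u. on single-electron toys; quadrature error grows roughly
linearly with the electron count of the fragments, so the heavier
multi-electron toy fixtures sit nearer 10⁻⁵. Desk-scale water runs in the
tests and the acceptance script use level 2 (tetramer) and level 1 (trimer
full-order identity, which is grid-level-independent), chosen as the
smallest levels whose quadrature error is negligible against the
kJ/mol-scale quantities being measured.

**Functionals.** The nonadditive kinetic term uses the PW91k (LC94) GGA —
Thomas–Fermi times an enhancement factor in the reduced gradient $s$ — and
the exchange–correlation term uses PBE (PW92 parameterization of the
uniform-gas correlation), both implemented from their published
parameterizations for closed-shell densities. No functional library binding
exists in this R stack, so correctness rests on a double-entry check: an
independent NumPy implementation written from the same publications
(`inst/oracles/gga_reference.py`) must agree at 1000 log-uniform random
$(\rho, \sigma)$ points to 10⁻¹⁰ relative, alongside the analytic limits
($F(s)\to 1$ as $s\to 0$; PBE at zero gradient equals its uniform-gas
limit) and the $\lambda^2$ homogeneity of the kinetic functional under
density scaling.

**Negative densities.** A signed combination $\rho^{(n)}$ can dip below
zero where fragment tails cancel; semilocal functionals are undefined
there. Values below the clamp threshold (default 10⁻¹⁰ a.u., exposed in
`functional_spec()`) are set to zero along with their gradients before
functional evaluation. Only $\tilde T_s$ and $\tilde E_{xc}$ see clamped
densities; the linear terms ($V_\text{nuc}$, $J$, electron counts) always
use the raw signed field, preserving their exact accumulation identities.

**Nuclear cusps.** Becke grids place no points on nuclei, but degenerate
inputs must not produce NaN: grid points within 10⁻¹⁰ Bohr of a nucleus
skip that nucleus's $-Z/r$ term in the quadrature potential.

## Backends

The backend contract is two operations: a subsystem total energy and a
field (density, gradient, analytic Coulomb potential) sampled on the shared
grid. Three implementations ship:

* **Built-in restricted Hartree–Fock** (`hf_backend()`): a compact RHF
  engine over McMurchie–Davidson Gaussian integrals (C++), with STO-3G
  (H, C, N, O) and 6-31G (H, O) bases, DIIS, and tight convergence
  (10⁻¹⁰ Hartree / 10⁻⁸ orbital gradient — the analogue of "very tight" SCF
  settings). It exists so that the whole pipeline — energies, densities,
  analytic Coulomb potentials — runs end-to-end with a real self-consistent
  method at desk scale. It is deliberately minimal: closed-shell only (plus
  the trivial one-electron case), s/p bases, no correlated methods.
* **Analytic Gaussian mock** (`mock_backend()`): each fragment is one
  normalized s-Gaussian at its heaviest atom with a declared closed-form
  pair potential (optional three-body term). Every MBE and db-MBE quantity
  then has a closed-form oracle value, making all downstream modules
  testable with no self-consistent engine at all.
* **Molden import** (`molden_backend()`): wavefunctions from external
  programs enter as Molden files (s/p/sp/d shells, spherical or Cartesian
  d). The Orca dialect applies the documented $\sqrt{(2l-1)!!}$ rescaling
  of $l\ge 2$ contraction coefficients; the reader verifies shell
  normalization through tr(DS) against the occupation sum, which catches a
  wrong-dialect read. Orbital-optimized coupled-cluster densities are
  supported only through this route — by design, since a single optimized
  determinant is exactly what the Molden format carries.

Fields are backend-agnostic: the correction from direct engine fields and
from a Molden round trip of the same wavefunctions agrees to 10⁻¹⁰ Hartree
in the tests.

## Fixtures: what they emulate, and what they do not

`make_water_cluster()` generates rigid gas-phase monomers
(r(OH) = 0.9572 Å, 104.52°). The default `"ring"` mode builds the classic
cyclic hydrogen-bonded motif — each water donating one O–H to the next
oxygen, free hydrogens alternating above and below the ring, neighbor O–O
distances centered in the 2.7–3.2 Å window, with small seeded rigid-body
jitter. This reproduces the feature that makes the method interesting:
cooperative three-body polarization, which puts several kJ/mol into the
terms an order-2 truncation misses. The `"box"` mode places randomly
oriented monomers instead (weakly interacting; useful as a contrast case).

What the fixtures do *not* emulate: optimized cluster geometries (the
ring/book/cage/prism isomer families), large basis sets, or correlated
reference energies. Tests passing here show the expansion algebra, the
quadrature, and the correction assembly are right, and that the db
correction captures cooperative effects in a minimal-basis Hartree–Fock
world; they do not certify kJ/mol agreement with large-basis CCSD(T)
benchmarks, which require external engines and cluster-scale resources.

With the built-in engine on a hydrogen-bonded tetramer (STO-3G, level-2
grid — the configuration `scripts/acceptance.R` runs), the two-body db-MBE
error versus the supermolecular calculation is roughly a third of the
two-body eb-MBE error and sits within chemical accuracy, and the three-body
db-MBE error is an order of magnitude below the three-body eb-MBE error —
the qualitative pattern that motivates the method, at desk scale.

## Workflow, caching, units

`run_dbmbe()` computes or loads every subsystem energy and field through
order $n$ (monomers first, then dimers, and so on, sequentially), assembles
eb/db totals for all $k \le n$, and reports per-order traces. The on-disk
cache keys on (subsystem, method, basis, grid signature); the grid signature
hash makes a silent grid mismatch — the most dangerous failure mode of the
accumulation scheme — impossible, at the cost of recomputing fields when the
grid changes. A warm rerun performs zero backend calls; killing a run and
restarting computes only the missing subsystems. Caches are stored as `.rds`
files, one object per key.

Internal units are atomic (Hartree, Bohr) end to end; XYZ input/output is in
Ångström and reports convert with 1 Hartree = 2625.4996394799 kJ/mol and
1 Å = 1/0.529177210903 Bohr (CODATA 2018).

## Known limitations

* The built-in engine is minimal-basis closed-shell RHF; charged or
  open-shell fragments beyond closed-shell ions, large bases, and
  correlated methods need an external engine via Molden import.
* Molden shells above d are rejected rather than approximated.
* No embedding potentials in the fragment calculations and no distance
  screening of the $k$-mer list — every subsystem through order $n$ is
  computed.
* Quadrature accuracy, not the expansion algebra, limits the correction for
  heavy fragments at low grid levels; the level is a per-run choice.
* Execution is sequential; the subsystem calculations are independent, so
  parallel dispatch is a natural extension point, deliberately left out.
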