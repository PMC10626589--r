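# dbmbe — energy- and density-based many-body expansions for molecular clusters

Fragment-based total energies for molecular clusters. The conventional,
energy-based many-body expansion (eb-MBE) approximates a cluster's energy
from calculations on monomers, dimers, trimers, …:

    E ≈ Σ_I E_I^(1) + Σ_{I<J} ΔE_IJ^(2) + … + Σ_{|S|=n} ΔE_S^(n)

with the k-mer interaction energies ΔE_S defined by inclusion–exclusion.
Truncating early makes high-level methods affordable for large clusters, but
for hydrogen-bonded systems the expansion converges slowly: cooperative
polarization leaves tens of kJ/mol in the three-body terms.

The **density-based MBE (db-MBE)** implemented here accelerates that
convergence with an orbital-free-DFT correction. The electron density is
expanded the same way, ρ^(n) = Σ_S c_S ρ_S, and the Kohn–Sham total-energy
functional E_tot[ρ] = T_s[ρ] + V_nuc[ρ] + J[ρ] + E_xc[ρ] + E_NN is
evaluated once on the expanded density and once as its own term-wise MBE:

    E_dbMBE(n) = E_ebMBE(n) + ( E_tot[ρ^(n)] − E_tot^(n) )

Only nonadditive contributions survive the difference — the inter-fragment
kinetic and exchange–correlation physics a truncated eb-MBE misses — and the
correction vanishes identically at full order. The nonadditive kinetic term
uses the PW91k (LC94) GGA, the exchange–correlation term PBE, both evaluated
by quadrature on one shared supermolecular Becke grid. Energies and
densities are independent backend choices, so a high-level energy ledger can
pair with cheap single-determinant densities.

Who this is for: method developers and practitioners of fragment-based
quantum chemistry who want a transparent, fully tested reference
implementation of the db-MBE with closed-form test oracles, plus the
plumbing (Molden ingestion, caching, reporting) to drive it from external
engines.

## What's in the box

* `mbe_engine` — subsystem enumeration, recursive/Möbius interaction
  energies, truncated totals, closed-form expansion coefficients
  c_k = (−1)^(n−k) C(N−k−1, n−k).
* `grid_numerics` — shared atom-centered Becke quadrature; densities,
  gradients and analytic Coulomb potentials as fields on the grid; signed
  field accumulation.
* `density_functionals` — PW91k and PBE energy densities (closed-shell),
  with an independent NumPy re-implementation as test oracle.
* `db_correction` — the five-term correction and db-MBE assembly, with both
  the recursive and the accumulate-then-evaluate routes.
* `qc_backend` — a built-in restricted Hartree–Fock engine
  (McMurchie–Davidson integrals in C++; STO-3G, 6-31G), an analytic
  Gaussian mock backend with closed-form everything, and Molden
  import/export (standard and Orca dialects).
* `synthetic_fixtures` — deterministic hydrogen-bonded water rings and
  Gaussian toy clusters.
* `workflow` — cached, restartable end-to-end runs; plain-text + JSON
  reports; YAML configs and a thin CLI (`inst/scripts/dbmbe`).

## Worked example

A hydrogen-bonded water trimer with the built-in RHF/STO-3G backend:

```r
library(dbmbe)

cl  <- make_water_cluster(3, seed = 7)          # cyclic H-bonded ring
be  <- hf_backend("sto-3g")
ref <- compute_energy(be, subsystem_geometry(cl, 1:3))   # supermolecular
run <- run_dbmbe(cl, be, order = 2, grid_level = 1, reference = ref)
print(run)
report_table(run)
```

```
dbmbe_run: 6 subsystems, 12 backend calls
db_mbe_result (order 2 ):
  order 1: eb-MBE = -224.8887849352  db-MBE = -224.8835223130 Hartree
  order 2: eb-MBE = -224.8830663272  db-MBE = -224.8834101335 Hartree
density-based correction, order 2 (Hartree):
  v_nuc_term   +0.0132582953
  coulomb_term -0.0136739400
  nn_term      +0.0000000000
  ts_nonadd    -0.0008812680
  xc_nonadd    +0.0009531064
  total        -0.0003438063  (-0.9027 kJ/mol)
  order        eb        db eb_error_kjmol db_error_kjmol
1     1 -224.8888 -224.8835     -11.627050       2.189963
2     2 -224.8831 -224.8834       3.387153       2.484490
```

Reading the output: the six subsystems are the 3 monomers + 3 dimers. The
`nn_term` is exactly zero (nuclear repulsion is pairwise additive, so its
expansion is already exact at order 2), the large electrostatic pieces
(`v_nuc_term`, `coulomb_term`) nearly cancel, and the small nonadditive
kinetic/xc remainder plus that electrostatic residue corrects the two-body
energy: the truncation error versus the supermolecular calculation drops
from 3.39 to 2.48 kJ/mol at order 2 (and from −11.6 to 2.2 at order 1). On
a tetramer, where cooperative effects are stronger, the order-2 error drops
from ~9.0 to ~2.9 kJ/mol — inside chemical accuracy.

The same run driven from a config file:

```yaml
# run.yaml
geometry: water3.xyz     # made by: dbmbe fixtures make-water --n 3 --seed 7 --out water3.xyz
order: 2
basis: sto-3g
grid_level: 2
cache: cache/
output: water3_report
```

```sh
Rscript inst/scripts/dbmbe run run.yaml
```

A warm rerun loads everything from `cache/` and performs zero backend calls.
Densities from external programs enter via `molden_backend()` with one
Molden file per subsystem (use `dialect = "orca"` for Orca exports).

## Notes

* Internal units are atomic (Hartree, Bohr); XYZ files are Ångström;
  reports convert with 1 Hartree = 2625.4996394799 kJ/mol (CODATA 2018).
* The built-in engine is closed-shell RHF in small bases by design; DFT,
  coupled-cluster and other correlated densities enter through Molden
  import, and their total energies through the ledger/energy table.
* See the methods vignette (`vignettes/density-based-mbe.Rmd`) for the
  model, the numerical choices (grids, clamping, tie-breaks), and known
  limitations.
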