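# Shared fixtures, memoized per test run so expensive objects (grids, SCF
# solutions, subsystem fields) are built once.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fix, inherits = FALSE)) assign(name, builder(), .fix)
  get(name, .fix, inherits = FALSE)
}

## Gaussian toy trimer with distinct exponents (closed-form oracles)
toy3 <- function() fixture("toy3", function() {
  make_gaussian_toy(3, positions = rbind(c(0, 0, 0), c(4, 0, 0), c(1.5, 3.5, 1)),
                    q = c(2, 2, 1), alphas = c(1.0, 1.3, 0.8))
})

toy3_grid <- function() fixture("toy3_grid", function() {
  build_supermolecular_grid(toy3()$cluster)
})

toy3_fields <- function() fixture("toy3_fields", function() {
  compute_subsystem_fields(toy3()$cluster, toy3()$backend, toy3_grid(), 3)
})

toy3_ledger <- function() fixture("toy3_ledger", function() {
  tl <- interaction_ledger()
  for (k in enumerate_subsystems(3, 3))
    set_total_energy(tl, k, compute_energy(toy3()$backend,
                                           subsystem_geometry(toy3()$cluster, k)))
  tl
})

## single water and its RHF/STO-3G wavefunction on the default grid
water1 <- function() fixture("water1", function() make_water_cluster(1, seed = 3))

water1_wf <- function() fixture("water1_wf", function() {
  rhf(subsystem_geometry(water1(), 1), basis = "sto-3g")
})

water1_grid <- function() fixture("water1_grid", function() {
  build_supermolecular_grid(water1())
})

water1_field <- function() fixture("water1_field", function() {
  density_on_grid(hf_fix_backend(), subsystem_geometry(water1(), 1), water1_grid())
})

hf_fix_backend <- function() fixture("hf_fix_backend", function() hf_backend("sto-3g"))

## hydrogen-bonded ring trimer of waters (used for HF pipeline checks)
water3 <- function() fixture("water3", function() make_water_cluster(3, seed = 7))

## Moebius inclusion-exclusion oracle for interaction energies
mobius_interaction <- function(ledger, key) {
  k <- length(key)
  total <- 0
  for (m in seq_len(k)) {
    idx <- utils::combn(seq_len(k), m)   # index form avoids combn(n, m) scalar pitfall
    for (j in seq_len(ncol(idx)))
      total <- total + (-1)^(k - m) * get_total_energy(ledger, key[idx[, j]])
  }
  total
}

## closed-form Coulomb integrals for unit-normalized s-Gaussians
gauss_self_coulomb <- function(q, alpha) q^2 * 0.5 * sqrt(2 * alpha / pi)
gauss_cross_coulomb <- function(q1, a1, q2, a2, R) {
  mu <- a1 * a2 / (a1 + a2)
  if (R < 1e-14) q1 * q2 * 2 * sqrt(mu / pi) else
    q1 * q2 * erf_(sqrt(mu) * R) / R
}

## analytic J[rho_S] for a set of toy fragments
toy_J_analytic <- function(toy, members) {
  be <- toy$backend
  e <- 0
  for (i in members) e <- e + gauss_self_coulomb(be$q[i], be$alphas[i])
  if (length(members) > 1) {
    pr <- utils::combn(members, 2)
    for (j in seq_len(ncol(pr))) {
      a <- pr[1, j]; b <- pr[2, j]
      R <- sqrt(sum((be$centers[a, ] - be$centers[b, ])^2))
      e <- e + gauss_cross_coulomb(be$q[a], be$alphas[a], be$q[b], be$alphas[b], R)
    }
  }
  e
}
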