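test_that("the RHF engine reproduces reference energies for tiny systems", {
  # H atom in STO-3G: one-electron exact-in-basis value
  gH <- list(elements = "H", z = 1L, coords = matrix(0, 1, 3),
             charge = 0L, n_electrons = 1L)
  eH <- compute_energy(hf_backend("sto-3g"), gH)
  expect_equal(eH, -0.466582, tolerance = 1e-5)
  # H2 at 1.4 Bohr, the classic closed-shell test case
  gH2 <- list(elements = c("H", "H"), z = c(1L, 1L),
              coords = rbind(c(0, 0, 0), c(0, 0, 1.4)),
              charge = 0L, n_electrons = 2L)
  eH2 <- compute_energy(hf_backend("sto-3g"), gH2)
  expect_equal(eH2, -1.1167, tolerance = 1e-3)
  # water in STO-3G lands in the expected region
  eW <- water1_wf()$energy
  expect_equal(eW, -74.963, tolerance = 2e-3)
})

test_that("repeated identical requests hit the memo and agree bitwise", {
  be <- hf_backend("sto-3g")
  g <- subsystem_geometry(water1(), 1)
  e1 <- compute_energy(be, g)
  e2 <- compute_energy(be, g)
  expect_identical(e1, e2)
})

test_that("open-shell requests beyond one electron are rejected explicitly", {
  gH3 <- list(elements = c("H", "H", "H"), z = c(1L, 1L, 1L),
              coords = rbind(c(0, 0, 0), c(0, 0, 1.8), c(1.8, 0, 0)),
              charge = 0L, n_electrons = 3L)
  expect_error(rhf(gH3), "open-shell")
})

test_that("backend densities integrate to the electron count and have the right far field", {
  # HF water: 10 electrons on the shared grid
  expect_lt(abs(water1_field()$electron_count - 10), 1e-12)
  expect_lt(abs(integrate_grid(water1_grid(), water1_field()$rho) - 10), 1e-4)
  # mock Gaussian fragment: closed forms to 1e-12, monopole far field exactly
  toy <- toy3()
  g <- toy3_grid()
  f1 <- toy3_fields()[["1"]]
  d <- sweep(g$points, 2, toy$backend$centers[1, ])
  r2 <- rowSums(d^2)
  rho_ref <- toy$backend$q[1] * (toy$backend$alphas[1] / pi)^1.5 *
    exp(-toy$backend$alphas[1] * r2)
  expect_lt(max(abs(f1$rho - rho_ref)), 1e-12)
  far <- matrix(c(50, 0, 0), 1, 3) + toy$backend$centers[1, , drop = FALSE]
  gfar <- list(points = far, weights = 1, signature = g$signature)
  vfar <- gaussian_fragment_field(far, toy$backend$centers[1, ],
                                  toy$backend$alphas[1], toy$backend$q[1])$vcoul
  expect_lt(abs(vfar - toy$backend$q[1] / 50), 1e-6)
  # HF water potential at 50 Bohr: monopole plus a dipole-order remainder
  farw <- water1()$coords[1, ] + c(50, 0, 0)
  vw <- cpp_esp(water1_wf()$basis_set, water1_wf()$D, matrix(farw, 1, 3))
  expect_lt(abs(vw - 10 / 50), 1e-2)
})

test_that("the mock backend's declared energy model is additive as configured", {
  toy <- toy3()
  cl <- toy$cluster
  # pairwise-only: trimer interaction vanishes
  led <- interaction_ledger()
  for (k in enumerate_subsystems(3, 3))
    set_total_energy(led, k, compute_energy(toy$backend, subsystem_geometry(cl, k)))
  expect_lt(abs(interaction_energy(led, 1:3)), 1e-13)
  # with a three-body term the trimer interaction is exactly t3 * exp(...)
  be3 <- mock_backend(cl, alphas = toy$backend$alphas, t3 = 0.01)
  led3 <- interaction_ledger()
  for (k in enumerate_subsystems(3, 3))
    set_total_energy(led3, k, compute_energy(be3, subsystem_geometry(cl, k)))
  r2s <- as.numeric(dist(toy$backend$centers))^2
  expect_lt(abs(interaction_energy(led3, 1:3) - 0.01 * exp(-be3$B * sum(r2s))),
            1e-12)
})
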