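test_that("a water Hartree-Fock density integrates to 10 electrons on the default grid", {
  err <- integrate_grid(water1_grid(), water1_field()$rho) - 10
  expect_lt(abs(err), 1e-4)
})

test_that("a normalized Gaussian on an atom integrates to one within 1e-6", {
  toy <- make_gaussian_toy(1, positions = matrix(c(0.5, -0.2, 0.1), 1, 3),
                           q = 1, alphas = 1)
  g <- build_supermolecular_grid(toy$cluster)
  f <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
  expect_lt(abs(integrate_grid(g, f$rho) - 1), 1e-6)
})

test_that("grid refinement does not increase the electron-count error", {
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = 1)
  errs <- vapply(c(1, 2, 3, 4), function(lv) {
    g <- build_supermolecular_grid(toy$cluster, level = lv)
    f <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1:2), g)
    abs(integrate_grid(g, f$rho) - 2)
  }, 0)
  expect_true(all(diff(errs) <= 0))
})

test_that("quadrature is linear and exact on zero input", {
  g <- toy3_grid()
  M <- nrow(g$points)
  expect_identical(integrate_grid(g, numeric(M)), 0)
  set.seed(9)
  f <- rnorm(M); h <- rnorm(M)
  lhs <- integrate_grid(g, 2.5 * f - 0.75 * h)
  rhs <- 2.5 * integrate_grid(g, f) - 0.75 * integrate_grid(g, h)
  expect_equal(lhs, rhs, tolerance = 1e-14)
  expect_error(integrate_grid(g, numeric(M - 1)), "match grid size")
})

test_that("nuclear attraction reproduces erf-form closed expressions", {
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = 1)
  g <- build_supermolecular_grid(toy$cluster)
  f1 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
  # unit Gaussian on its own Z=1 nucleus: -2 sqrt(1/pi)
  v <- nuclear_attraction_energy(g, f1, 1, matrix(0, 1, 3))
  expect_lt(abs(v + 2 * sqrt(1 / pi)), 1e-6)
  # zero density integrates to zero
  f0 <- field_on_grid(1, numeric(nrow(g$points)),
                      matrix(0, nrow(g$points), 3), numeric(nrow(g$points)),
                      0, g$signature)
  expect_identical(nuclear_attraction_energy(g, f0, 1, matrix(0, 1, 3)), 0)
  # cross attraction of fragment 1's density to fragment 2's nucleus:
  # full-cluster V_nuc minus own-nucleus V_nuc isolates -q Z erf(sqrt(a) R)/R
  v_both <- nuclear_attraction_energy(g, f1, c(1, 1), toy$cluster$coords)
  expect_lt(abs((v_both - v) + erf_(sqrt(1) * 4) / 4), 1e-6)
})

test_that("Coulomb energies match analytic Gaussian integrals", {
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = 1)
  g <- build_supermolecular_grid(toy$cluster)
  f1 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
  f2 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 2), g)
  f12 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1:2), g)
  expect_lt(abs(coulomb_energy(g, f1) - 0.5 * sqrt(2 / pi)), 1e-6)
  cross <- coulomb_energy(g, f12) - coulomb_energy(g, f1) - coulomb_energy(g, f2)
  expect_lt(abs(cross - erf_(sqrt(0.5) * 4) / 4), 1e-6)
  # an expanded field with a single unit term is the plain field
  ex <- expanded_field(list(list(coef = 1, field = f12)))
  expect_equal(coulomb_energy(g, ex), coulomb_energy(g, f12), tolerance = 1e-14)
})

test_that("the quadrature Coulomb kernel is symmetric between subsystems", {
  # int rho_a v_b = int rho_b v_a holds analytically; in quadrature the two
  # sides are independent approximations, so the check runs on single-electron
  # Gaussians at a fine grid level where both are converged past 1e-8
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = c(1, 0.7))
  g <- build_supermolecular_grid(toy$cluster, level = 4)
  a <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
  b <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 2), g)
  lhs <- integrate_grid(g, a$rho * b$vcoul)
  rhs <- integrate_grid(g, b$rho * a$vcoul)
  expect_lt(abs(lhs - rhs), 1e-8)
})

test_that("linear functionals of an expanded field equal the weighted per-term sums", {
  flds <- toy3_fields()
  cl <- toy3()$cluster
  g <- toy3_grid()
  ex <- expanded_density(flds, cl, 2)
  # electron count
  ne_terms <- sum(vapply(ex$terms, function(t) t$coef * integrate_grid(g, t$field$rho), 0))
  expect_equal(integrate_grid(g, ex$rho), ne_terms, tolerance = 1e-12)
  # nuclear attraction with the full-cluster nuclei
  v_acc <- nuclear_attraction_energy(g, ex, cl$z, cl$coords)
  v_terms <- sum(vapply(ex$terms, function(t)
    t$coef * nuclear_attraction_energy(g, t$field, cl$z, cl$coords), 0))
  expect_equal(v_acc, v_terms, tolerance = 1e-12)
  # accumulated-potential Coulomb equals the pairwise double sum
  expect_equal(coulomb_energy(g, ex), coulomb_energy_pairwise(g, ex),
               tolerance = 1e-10)
})

test_that("Coulomb quadrature error decreases with grid level", {
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = 1)
  errs <- vapply(c(2, 4), function(lv) {
    g <- build_supermolecular_grid(toy$cluster, level = lv)
    f <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
    abs(coulomb_energy(g, f) - 0.5 * sqrt(2 / pi))
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("grids export and re-import as plain-text tables", {
  g <- toy3_grid()
  path <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_equal(unname(g2$points), unname(g$points), tolerance = 1e-12)
  expect_equal(g2$weights, g$weights, tolerance = 1e-12)
})

test_that("fields from different grids refuse to combine", {
  f1 <- toy3_fields()[["1"]]
  other <- build_supermolecular_grid(toy3()$cluster, level = 1)
  f_other <- density_on_grid(toy3()$backend,
                             subsystem_geometry(toy3()$cluster, 1), other)
  expect_error(expanded_field(list(list(coef = 1, field = f1),
                                   list(coef = 1, field = f_other))),
               "share one grid")
})
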