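test_that("nuclear repulsion telescopes exactly at second order", {
  cl <- toy3()$cluster
  g <- toy3_grid()
  enn_full <- nuclear_repulsion(cl$z, cl$coords)
  enn_mbe2 <- mbe_of_functional_term(toy3_fields(), cl, g, 2, "enn")
  expect_equal(enn_mbe2, enn_full, tolerance = 1e-13)
  corr2 <- db_correction(toy3_fields(), cl, g, 2)
  expect_identical(corr2$nn_term, 0)
  corr1 <- db_correction(toy3_fields(), cl, g, 1)
  expect_gt(abs(corr1$nn_term), 1e-3)
})

test_that("every correction term vanishes at full expansion order", {
  corr <- db_correction(toy3_fields(), toy3()$cluster, toy3_grid(), 3)
  for (nm in c("v_nuc_term", "coulomb_term", "nn_term", "ts_nonadd",
               "xc_nonadd", "total"))
    expect_lt(abs(corr[[nm]]), 1e-8, label = nm)
})

test_that("a single-fragment system has an identically zero correction", {
  toy <- make_gaussian_toy(1, positions = matrix(0, 1, 3), q = 2)
  g <- build_supermolecular_grid(toy$cluster, level = 1)
  flds <- compute_subsystem_fields(toy$cluster, toy$backend, g, 1)
  corr <- db_correction(flds, toy$cluster, g, 1)
  expect_lt(abs(corr$total), 1e-12)
})

test_that("the Coulomb term's expansion matches analytic pairwise Gaussian sums", {
  cl <- toy3()$cluster
  g <- toy3_grid()
  j_mbe2 <- mbe_of_functional_term(toy3_fields(), cl, g, 2, "coulomb")
  # independent evaluation: signed coefficient sum of closed-form J[rho_S]
  coeffs <- expansion_coefficients(3, 2)
  j_ref <- 0
  for (key in enumerate_subsystems(3, 2))
    j_ref <- j_ref + coefficient_of(coeffs, key) * toy_J_analytic(toy3(), key)
  expect_lt(abs(j_mbe2 - j_ref), 2e-5)  # grid tolerance of this 5-electron fixture
})

test_that("recursive and coefficient routes agree for every term", {
  cl <- toy3()$cluster
  g <- toy3_grid()
  for (term in c("vnuc", "coulomb", "kinetic", "xc", "enn")) {
    a <- mbe_of_functional_term(toy3_fields(), cl, g, 2, term, route = "recursive")
    b <- mbe_of_functional_term(toy3_fields(), cl, g, 2, term, route = "coefficients")
    expect_equal(a, b, tolerance = 1e-12, label = term)
  }
})

test_that("the order-2 correction matches a direct non-recursive assembly", {
  # independent route: build rho^(2) by hand from the raw fields, evaluate
  # E_tot[rho^(2)] term by term with elementary quadrature calls, and
  # subtract the coefficient-weighted per-subsystem terms
  toy <- toy3()
  cl <- toy$cluster
  g <- toy3_grid()
  flds <- toy3_fields()
  ids2 <- vapply(enumerate_subsystems(3, 2), key_id, "")
  cs <- c(rep(-1, 3), rep(1, 3))  # N=3, n=2: monomers -1, dimers +1
  names(cs) <- ids2
  rho <- 0; grad <- 0; v <- 0
  for (id in ids2) {
    rho <- rho + cs[[id]] * flds[[id]]$rho
    grad <- grad + cs[[id]] * flds[[id]]$grad
    v <- v + cs[[id]] * flds[[id]]$vcoul
  }
  pot <- nuclear_potential_on_grid(g$points, cl$z, cl$coords)
  sig <- rowSums(grad^2)
  spec <- functional_spec()
  cl_rho <- clamp_density(rho, sig, spec$clamp)
  full <- sum(g$weights * rho * pot) +
    0.5 * sum(g$weights * rho * v) +
    sum(g$weights * kinetic_energy_density(cl_rho$rho, cl_rho$sigma, spec)) +
    sum(g$weights * xc_energy_density(cl_rho$rho, cl_rho$sigma, spec))
  mbe <- 0
  for (id in ids2) {
    key <- parse_key(id)
    geom <- subsystem_geometry(cl, key)
    f <- flds[[id]]
    potS <- nuclear_potential_on_grid(g$points, geom$z, geom$coords)
    sigS <- rowSums(f$grad^2)
    clS <- clamp_density(f$rho, sigS, spec$clamp)
    mbe <- mbe + cs[[id]] * (
      sum(g$weights * f$rho * potS) +
      0.5 * sum(g$weights * f$rho * f$vcoul) +
      sum(g$weights * kinetic_energy_density(clS$rho, clS$sigma, spec)) +
      sum(g$weights * xc_energy_density(clS$rho, clS$sigma, spec)))
  }
  direct_total <- full - mbe  # nn term is zero at order 2
  corr <- db_correction(flds, cl, g, 2)
  expect_equal(corr$total, direct_total, tolerance = 1e-10)
})

test_that("db-MBE totals assemble as eb-MBE plus correction with a telescoping trace", {
  cl <- toy3()$cluster
  res <- db_mbe_total(toy3_ledger(), toy3_fields(), cl, toy3_grid(), 3)
  expect_equal(res$db_energy, res$eb_energy + res$correction$total,
               tolerance = 1e-14)
  esup <- compute_energy(toy3()$backend, subsystem_geometry(cl, 1:3))
  expect_equal(res$trace$eb[3], esup, tolerance = 1e-12)
  expect_equal(res$trace$db[3], esup, tolerance = 1e-8)
  # per-order increments of the eb trace are the order-k interaction sums
  d32 <- res$trace$eb[3] - res$trace$eb[2]
  expect_equal(d32, interaction_energy(toy3_ledger(), 1:3), tolerance = 1e-12)
})

test_that("correction breakdown totals are the exact sum of their five terms", {
  for (n in 1:3) {
    corr <- db_correction(toy3_fields(), toy3()$cluster, toy3_grid(), n)
    expect_equal(corr$total,
                 corr$v_nuc_term + corr$coulomb_term + corr$nn_term +
                   corr$ts_nonadd + corr$xc_nonadd,
                 tolerance = 1e-14)
  }
})

test_that("requesting an order beyond the fragment count fails cleanly", {
  expect_error(db_correction(toy3_fields(), toy3()$cluster, toy3_grid(), 4),
               "exceeds")
  expect_error(mbe_of_functional_term(list(), toy3()$cluster, toy3_grid(),
                                      2, "coulomb"),
               "missing fields")
})
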