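test_that("water fixtures are rigid, reproducible, and respect distance bounds", {
  cl1 <- make_water_cluster(4, seed = 7)
  cl2 <- make_water_cluster(4, seed = 7)
  expect_identical(cl1$coords, cl2$coords)
  expect_false(identical(cl1$coords, make_water_cluster(4, seed = 8)$coords))
  # rigid monomers: every O-H bond 0.9572 A, HOH angle 104.52 deg
  r_oh <- 0.9572 * dbmbe_units$bohr_per_angstrom
  for (f in 1:4) {
    at <- cl1$coords[cl1$fragment_of == f, ]
    d1 <- sqrt(sum((at[2, ] - at[1, ])^2))
    d2 <- sqrt(sum((at[3, ] - at[1, ])^2))
    expect_equal(c(d1, d2), c(r_oh, r_oh), tolerance = 1e-10)
    cosang <- sum((at[2, ] - at[1, ]) * (at[3, ] - at[1, ])) / (d1 * d2)
    expect_equal(acos(cosang) * 180 / pi, 104.52, tolerance = 1e-8)
  }
  # neighbor O-O distances inside the declared window (ring neighbors)
  o <- cl1$coords[seq(1, 12, by = 3), ]
  min_oo <- 2.7 * dbmbe_units$bohr_per_angstrom
  max_oo <- 3.2 * dbmbe_units$bohr_per_angstrom
  for (k in 1:4) {
    d <- sqrt(sum((o[k, ] - o[if (k == 4) 1 else k + 1, ])^2))
    expect_gte(d, min_oo); expect_lte(d, max_oo)
  }
  # no steric overlap across fragments
  dall <- as.matrix(dist(cl1$coords))
  cross <- outer(cl1$fragment_of, cl1$fragment_of, `!=`)
  expect_gt(min(dall[cross]), 1.5)
})

test_that("water fixtures come out as one fragment per water in every mode", {
  expect_equal(n_fragments(make_water_cluster(1, seed = 1)), 1)
  expect_equal(length(make_water_cluster(1, seed = 1)$elements), 3)
  for (mode in c("ring", "box")) {
    cl <- make_water_cluster(6, seed = 2, mode = mode)
    path <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(cl, path)
    expect_equal(n_fragments(read_xyz(path, fragments = "auto")), 6)
  }
})

test_that("gaussian toys expose their closed-form cross Coulomb", {
  toy <- make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 4)),
                           q = 1, alphas = 1)
  g <- build_supermolecular_grid(toy$cluster)
  f1 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
  f2 <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 2), g)
  cross <- integrate_grid(g, f1$rho * f2$vcoul)
  expect_lt(abs(cross - erf_(sqrt(0.5) * 4) / 4), 1e-6)
  expect_error(make_gaussian_toy(2, positions = rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("single-fragment toys have no interactions beyond first order", {
  toy <- make_gaussian_toy(1, positions = matrix(1, 1, 3), q = 2)
  led <- interaction_ledger()
  set_total_energy(led, 1, compute_energy(toy$backend,
                                          subsystem_geometry(toy$cluster, 1)))
  expect_equal(eb_mbe_total(led, 1, 1),
               compute_energy(toy$backend, subsystem_geometry(toy$cluster, 1)))
})

test_that("pairwise-only toys make the two-body expansion exact", {
  toy <- make_gaussian_toy(4, q = 2, seed = 6)
  led <- interaction_ledger()
  for (k in enumerate_subsystems(4, 4))
    set_total_energy(led, k, compute_energy(toy$backend,
                                            subsystem_geometry(toy$cluster, k)))
  expect_equal(eb_mbe_total(led, 4, 2), eb_mbe_total(led, 4, 4),
               tolerance = 1e-12)
})

test_that("toy generation is seeded and fast", {
  t0 <- Sys.time()
  a <- make_gaussian_toy(5, seed = 9)
  b <- make_gaussian_toy(5, seed = 9)
  expect_identical(a$cluster$coords, b$cluster$coords)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})
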