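test_that("PW91k recovers Thomas-Fermi at zero gradient and vanishes with the density", {
  expect_equal(kinetic_energy_density(1, 0), C_TF, tolerance = 1e-12)
  expect_equal(kinetic_energy_density(0, 0), 0)
  # enhancement factor -> 1 as s -> 0
  expect_equal(pw91k_enhancement(1e-8), 1, tolerance = 1e-7)
  # TF-only spec ignores the gradient entirely
  spec_tf <- functional_spec(kinetic = "TF")
  expect_equal(kinetic_energy_density(0.3, 5, spec_tf),
               C_TF * 0.3^(5 / 3), tolerance = 1e-12)
})

test_that("PBE reduces to its uniform-gas limit at zero gradient", {
  rho <- c(0.05, 0.3, 1, 4)
  got <- xc_energy_density(rho, numeric(4))
  ex_lda <- -(3 / 4) * (3 / pi)^(1 / 3) * rho^(4 / 3)
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  ec_lda <- pw92_ec_unpol(rs) * rho
  expect_equal(got, ex_lda + ec_lda, tolerance = 1e-12)
  expect_equal(xc_energy_density(0, 0), 0)
})

test_that("R and Python implementations of PW91k and PBE agree at 1000 random points", {
  set.seed(2024)
  rho <- exp(runif(1000, log(1e-6), log(10)))
  sigma <- exp(runif(1000, log(1e-8), log(10)))
  oracle <- system.file("oracles", "gga_reference.py", package = "dbmbe")
  inp <- paste(sprintf("%.16e %.16e", rho, sigma), collapse = "\n")
  out <- system2("python", oracle, input = inp, stdout = TRUE)
  ref <- utils::read.table(text = out)
  tau <- kinetic_energy_density(rho, sigma)
  exc <- xc_energy_density(rho, sigma)
  expect_lt(max(abs(tau - ref$V1) / abs(ref$V1)), 1e-10)
  expect_lt(max(abs(exc - ref$V2) / abs(ref$V2)), 1e-10)
})

test_that("the kinetic functional obeys lambda^2 density scaling on Gaussians", {
  # rho_lambda(r) = lambda^3 rho(lambda r): for a normalized Gaussian this is
  # the exponent scaling alpha -> lambda^2 alpha, under which a consistent
  # GGA kinetic functional scales by lambda^2
  lam2 <- 2.25
  t_val <- vapply(c(1, lam2), function(a) {
    toy <- make_gaussian_toy(1, positions = matrix(0, 1, 3), q = 2, alphas = a)
    g <- build_supermolecular_grid(toy$cluster, level = 4)
    f <- density_on_grid(toy$backend, subsystem_geometry(toy$cluster, 1), g)
    functional_energy(g, f, functional_spec(), "kinetic")
  }, 0)
  expect_equal(t_val[2] / t_val[1], lam2, tolerance = 1e-5)
})

test_that("integrated functionals behave on degenerate and single-term input", {
  g <- toy3_grid()
  M <- nrow(g$points)
  zero <- field_on_grid(1, numeric(M), matrix(0, M, 3), numeric(M), 0,
                        g$signature)
  expect_identical(functional_energy(g, zero, which = "kinetic"), 0)
  expect_identical(functional_energy(g, zero, which = "xc"), 0)
  f <- toy3_fields()[["1.2"]]
  ex <- expanded_field(list(list(coef = 1, field = f)))
  expect_equal(functional_energy(g, ex, which = "kinetic"),
               functional_energy(g, f, which = "kinetic"), tolerance = 1e-14)
  nog <- field_on_grid(1, numeric(M), NULL, numeric(M), 0, g$signature)
  expect_error(functional_energy(g, nog, which = "xc"), "gradient")
})

test_that("the GGA kinetic energy of a water density sits near the orbital kinetic energy", {
  wf <- water1_wf()
  t_exact <- sum(wf$D * cpp_one_electron(wf$basis_set,
                                         matrix(0, 1, 3), 0)$T)
  t_gga <- functional_energy(water1_grid(), water1_field(),
                             functional_spec(), "kinetic")
  expect_lt(abs(t_gga - t_exact) / t_exact, 0.1)
})
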