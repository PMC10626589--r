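sample_points <- function() {
  set.seed(17)
  matrix(rnorm(300), 100, 3) * 2
}

test_that("a Molden export of an RHF wavefunction round-trips the density", {
  wf <- water1_wf()
  geom <- subsystem_geometry(water1(), 1)
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden(rhf_to_molden(wf, geom), path)
  bd <- molden_density_matrix(read_molden(path))
  pts <- sample_points()
  r_direct <- cpp_density_grad(wf$basis_set, wf$D, pts)$rho
  r_molden <- cpp_density_grad(bd$basis, bd$D, pts)$rho
  # the text format carries ~17 significant digits; the density matrix
  # amplifies that rounding by the squared orbital amplitudes near nuclei
  expect_lt(max(abs(r_direct - r_molden) / pmax(abs(r_direct), 1)), 1e-10)
})

test_that("a Molden water wavefunction integrates to 10 electrons on the grid", {
  wf <- water1_wf()
  geom <- subsystem_geometry(water1(), 1)
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden(rhf_to_molden(wf, geom), path)
  f <- molden_field(read_molden(path), water1_grid())
  expect_equal(f$electron_count, 10)
  expect_lt(abs(integrate_grid(water1_grid(), f$rho) - 10), 1e-4)
})

test_that("the Orca dialect fix restores d-shell wavefunctions; without it they are rejected", {
  # synthetic one-orbital wavefunction on a contracted spherical d shell
  coefs <- c(0.6, 0.5)
  md <- structure(list(
    elements = "Ne", z = 10L, coords = matrix(0, 1, 3),
    shells = list(list(atom = 1L, type = "d", exps = c(1.5, 0.5), coefs = coefs)),
    spherical_d = TRUE, mo_coef = matrix(c(1, 0, 0, 0, 0), 5, 1),
    occ = 2, energies = 0, dialect = "standard"), class = "molden_data")
  p_std <- withr::local_tempfile(fileext = ".molden")
  p_orca <- withr::local_tempfile(fileext = ".molden")
  write_molden(md, p_std)
  write_molden(md, p_orca, dialect = "orca")
  pts <- sample_points()
  bd_std <- molden_density_matrix(read_molden(p_std))
  bd_orca <- molden_density_matrix(read_molden(p_orca, dialect = "orca"))
  r_std <- cpp_density_grad(bd_std$basis, bd_std$D, pts)$rho
  r_orca <- cpp_density_grad(bd_orca$basis, bd_orca$D, pts)$rho
  expect_lt(max(abs(r_std - r_orca)), 1e-12)
  # regression guard: interpreting the orca-dialect file with the standard
  # convention breaks the shell normalization and is caught by tr(DS)
  expect_error(molden_density_matrix(read_molden(p_orca, dialect = "standard")),
               "normalization")
})

test_that("unsupported or inconsistent Molden content is rejected", {
  wf <- water1_wf()
  geom <- subsystem_geometry(water1(), 1)
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden(rhf_to_molden(wf, geom), path)
  txt <- readLines(path)
  # inject an f shell
  bad <- withr::local_tempfile(fileext = ".molden")
  writeLines(sub("^ s ", " f ", txt), bad)
  expect_error(read_molden(bad), "not supported")
  # non-integer occupations
  bad2 <- withr::local_tempfile(fileext = ".molden")
  txt2 <- txt
  txt2[grep("^Occup=", txt2)[1]] <- "Occup= 1.700000"
  writeLines(txt2, bad2)
  expect_error(read_molden(bad2), "non-integer")
})

test_that("db corrections are backend-agnostic between direct fields and Molden re-import", {
  # two-water system, order 1 correction (nonzero), fields once from the HF
  # backend and once through Molden export/import of the same wavefunctions
  cl <- make_water_cluster(2, seed = 5)
  be <- hf_backend("sto-3g")
  grid <- build_supermolecular_grid(cl, level = 1)
  fields_direct <- compute_subsystem_fields(cl, be, grid, 2)
  files <- list()
  for (key in enumerate_subsystems(2, 2)) {
    geom <- subsystem_geometry(cl, key)
    wf <- rhf(geom)
    p <- withr::local_tempfile(fileext = ".molden",
                               .local_envir = teardown_env())
    write_molden(rhf_to_molden(wf, geom), p)
    files[[key_id(key)]] <- p
  }
  mbe_backend <- molden_backend(files)
  fields_molden <- compute_subsystem_fields(cl, mbe_backend, grid, 2)
  c_direct <- db_correction(fields_direct, cl, grid, 1)
  c_molden <- db_correction(fields_molden, cl, grid, 1)
  expect_lt(abs(c_direct$total - c_molden$total), 1e-10)
  for (nm in c("v_nuc_term", "coulomb_term", "ts_nonadd", "xc_nonadd"))
    expect_lt(abs(c_direct[[nm]] - c_molden[[nm]]), 1e-10)
})
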