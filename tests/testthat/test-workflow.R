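test_that("a full toy run reports the supermolecular energy at full order", {
  toy <- toy3()
  run <- run_dbmbe(toy$cluster, toy$backend, order = 3, grid_level = 2)
  esup <- compute_energy(toy$backend, subsystem_geometry(toy$cluster, 1:3))
  expect_lt(abs(run$db_energy - esup), 1e-8)
  expect_equal(run$n_subsystems, 7)
})

test_that("warm-cache reruns perform zero backend calls and reproduce the report", {
  toy <- make_gaussian_toy(3, q = 2, seed = 13)
  cache <- withr::local_tempdir()
  r1 <- run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 1,
                  cache_dir = cache)
  expect_equal(unname(r1$n_backend_calls), c(6L, 6L))
  r2 <- run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 1,
                  cache_dir = cache)
  expect_equal(unname(r2$n_backend_calls), c(0L, 0L))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$correction$total, r2$correction$total)
})

test_that("restart after a partial run computes only the missing subsystems", {
  toy <- make_gaussian_toy(4, q = 2, seed = 14)
  cache <- withr::local_tempdir()
  # order-1 pass computes the 4 monomers
  r1 <- run_dbmbe(toy$cluster, toy$backend, order = 1, grid_level = 1,
                  cache_dir = cache)
  expect_equal(unname(r1$n_backend_calls), c(4L, 4L))
  # order-2 restart reuses them: 10 - 4 = 6 new calls of each kind
  r2 <- run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 1,
                  cache_dir = cache)
  expect_equal(unname(r2$n_backend_calls), c(6L, 6L))
  expect_equal(r2$n_subsystems, 10)
})

test_that("a grid change invalidates cached fields but not energies", {
  toy <- make_gaussian_toy(3, q = 2, seed = 15)
  cache <- withr::local_tempdir()
  run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 1,
            cache_dir = cache)
  r <- run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 2,
                 cache_dir = cache)
  expect_equal(unname(r$n_backend_calls), c(0L, 6L))
})

test_that("reports carry per-order errors in kJ/mol and round-trip through JSON", {
  toy <- toy3()
  esup <- compute_energy(toy$backend, subsystem_geometry(toy$cluster, 1:3))
  run <- run_dbmbe(toy$cluster, toy$backend, order = 2, grid_level = 2,
                   reference = esup)
  tab <- report_table(run)
  expect_true(all(c("eb_error_kjmol", "db_error_kjmol") %in% names(tab)))
  expect_equal(tab$eb_error_kjmol,
               (tab$eb - esup) * 2625.4996394799, tolerance = 1e-12)
  # without a reference the error columns are absent, not zero-filled
  run0 <- run_dbmbe(toy$cluster, toy$backend, order = 1, grid_level = 1)
  expect_false(any(grepl("error", names(report_table(run0)))))
  stem <- file.path(withr::local_tempdir(), "report")
  paths <- write_report(run, stem)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(rep$trace$db, run$trace$db, tolerance = 1e-13)
  expect_equal(rep$correction$total, run$correction$total, tolerance = 1e-13)
  expect_equal(rep$kjmol_per_hartree, 2625.4996394799)
})

test_that("config-driven runs execute the full pipeline from an XYZ file", {
  dir <- withr::local_tempdir()
  cl <- make_water_cluster(2, seed = 5)
  xyz <- file.path(dir, "w2.xyz")
  write_xyz(cl, xyz)
  cfg <- list(geometry = xyz, order = 2, basis = "sto-3g", grid_level = 1,
              output = file.path(dir, "rep"), cache = file.path(dir, "cache"))
  run <- run_from_config(cfg)
  expect_equal(run$n_subsystems, 3)
  expect_true(file.exists(file.path(dir, "rep.json")))
  # YAML path
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, yml)
  cfg2 <- read_run_config(yml)
  expect_equal(cfg2$order, 2)
  expect_equal(cfg2$kinetic, "PW91k")
})

test_that("the command-line fixture generator writes usable XYZ + sidecar files", {
  script <- system.file("scripts", "dbmbe", package = "dbmbe")
  dir <- withr::local_tempdir()
  out <- file.path(dir, "w3.xyz")
  res <- system2("Rscript", c(script, "fixtures", "make-water", "--n", "3",
                              "--seed", "2", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".frag")))
  cl <- read_xyz(out, fragments = paste0(out, ".frag"))
  expect_equal(n_fragments(cl), 3)
})
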