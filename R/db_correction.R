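## Density-based correction and db-MBE assembly. The correction is the
## difference between each term of the orbital-free total-energy functional
## evaluated on the many-body-expanded density and the many-body expansion of
## that term over subsystem densities: only nonadditive contributions
## survive, and every term cancels exactly at full order on the shared grid.

#' Compute all subsystem fields through a truncation order
#'
#' Runs the backend's density route for every k-mer with k <= n, each sampled
#' on the shared supermolecular grid.
#'
#' @param cluster a `cluster_system`
#' @param backend a backend object
#' @param grid the shared `integration_grid`
#' @param n truncation order
#' @param progress optional function called with each subsystem id
#' @return named list (canonical key ids) of `field_on_grid`
#' @export
compute_subsystem_fields <- function(cluster, backend, grid, n, progress = NULL) {
  keys <- enumerate_subsystems(n_fragments(cluster), n)
  fields <- list()
  for (key in keys) {
    id <- key_id(key)
    if (!is.null(progress)) progress(id)
    f <- density_on_grid(backend, subsystem_geometry(cluster, key), grid,
                         key = key)
    f$key <- as.integer(key)
    fields[[id]] <- f
  }
  fields
}

## per-subsystem value of one energy term; subsystem V_nuc and E_NN use only
## that subsystem's own nuclei
term_value <- function(term, field, geometry, grid, spec) {
  switch(term,
    vnuc = nuclear_attraction_energy(grid, field, geometry$z, geometry$coords),
    coulomb = coulomb_energy(grid, field),
    kinetic = functional_energy(grid, field, spec, "kinetic"),
    xc = functional_energy(grid, field, spec, "xc"),
    enn = nuclear_repulsion(geometry$z, geometry$coords),
    stop("unknown term: ", term))
}

term_values_all <- function(term, fields, cluster, grid, spec) {
  vapply(fields, function(f) {
    term_value(term, f, subsystem_geometry(cluster, f$key), grid, spec)
  }, 0)
}

#' Many-body expansion of one energy-functional term
#'
#' `X^(n) = sum_S c_S X[rho_S]` for a term X of the orbital-free total-energy
#' functional, where subsystem nuclear terms use only that subsystem's
#' nuclei. Two mathematically identical routes are implemented: the
#' `"recursive"` route evaluates k-mer increments order by order through the
#' interaction-energy recursion, the `"coefficients"` route applies the
#' closed-form signed weights directly.
#'
#' @param fields named list of subsystem fields (keys through order `n`)
#' @param cluster the `cluster_system`
#' @param grid the shared grid
#' @param n truncation order
#' @param term one of `"vnuc"`, `"coulomb"`, `"kinetic"`, `"xc"`, `"enn"`
#' @param spec a [functional_spec()]
#' @param route `"recursive"` (default) or `"coefficients"`
#' @return energy in Hartree
#' @export
mbe_of_functional_term <- function(fields, cluster, grid, n, term,
                                   spec = functional_spec(),
                                   route = c("recursive", "coefficients")) {
  route <- match.arg(route)
  N <- n_fragments(cluster)
  keys <- enumerate_subsystems(N, n)
  ids <- vapply(keys, key_id, "")
  missing <- ids[!ids %in% names(fields)]
  if (term != "enn" && length(missing))
    stop("missing fields for subsystems: ", paste(missing, collapse = ", "))
  vals <- if (term == "enn") {
    v <- vapply(keys, function(k) {
      g <- subsystem_geometry(cluster, k)
      nuclear_repulsion(g$z, g$coords)
    }, 0)
    names(v) <- ids
    v
  } else {
    term_values_all(term, fields[ids], cluster, grid, spec)
  }
  if (route == "recursive") {
    ledger <- interaction_ledger(as.list(vals))
    eb_mbe_total(ledger, N, n)
  } else {
    coeffs <- expansion_coefficients(N, n)
    sum(vapply(ids, function(id) {
      coefficient_of(coeffs, parse_key(id)) * vals[[id]]
    }, 0))
  }
}

#' Build the order-n expanded density field
#'
#' Accumulates `rho^(n) = sum_S c_S rho_S` over all subsystem fields through
#' order n, with the closed-form signed coefficients.
#'
#' @inheritParams mbe_of_functional_term
#' @return an [expanded_field()]
#' @export
expanded_density <- function(fields, cluster, n) {
  N <- n_fragments(cluster)
  coeffs <- expansion_coefficients(N, n)
  keys <- enumerate_subsystems(N, n)
  terms <- lapply(keys, function(k) {
    id <- key_id(k)
    if (is.null(fields[[id]])) stop("missing field for subsystem {", id, "}")
    list(coef = coefficient_of(coeffs, k), field = fields[[id]])
  })
  expanded_field(terms)
}

#' The density-based correction at order n
#'
#' Assembles the five-term correction: for each term of the orbital-free
#' total-energy functional (electron-nuclei attraction with the full-cluster
#' nuclei, Coulomb repulsion, nuclear repulsion, semilocal kinetic, semilocal
#' exchange-correlation), the value on the expanded density minus the
#' term's own many-body expansion. The nuclear-repulsion part vanishes
#' identically for n >= 2 (pairwise additivity); every term vanishes at
#' n = N.
#'
#' @inheritParams mbe_of_functional_term
#' @param route evaluation route for the expansion side of each difference
#' @return a `correction_breakdown`: `v_nuc_term`, `coulomb_term`, `nn_term`,
#'   `ts_nonadd`, `xc_nonadd`, `total` (all Hartree), `order`
#' @export
db_correction <- function(fields, cluster, grid, n, spec = functional_spec(),
                          route = c("recursive", "coefficients")) {
  route <- match.arg(route)
  N <- n_fragments(cluster)
  if (n > N) stop("order ", n, " exceeds fragment count ", N)
  ex <- expanded_density(fields, cluster, n)
  v_full <- nuclear_attraction_energy(grid, ex, cluster$z, cluster$coords)
  j_full <- coulomb_energy(grid, ex)
  ts_full <- functional_energy(grid, ex, spec, "kinetic")
  xc_full <- functional_energy(grid, ex, spec, "xc")
  enn_full <- nuclear_repulsion(cluster$z, cluster$coords)
  v_mbe <- mbe_of_functional_term(fields, cluster, grid, n, "vnuc", spec, route)
  j_mbe <- mbe_of_functional_term(fields, cluster, grid, n, "coulomb", spec, route)
  ts_mbe <- mbe_of_functional_term(fields, cluster, grid, n, "kinetic", spec, route)
  xc_mbe <- mbe_of_functional_term(fields, cluster, grid, n, "xc", spec, route)
  enn_mbe <- if (n >= 2) enn_full else
    mbe_of_functional_term(fields, cluster, grid, n, "enn", spec, route)
  out <- list(v_nuc_term = v_full - v_mbe,
              coulomb_term = j_full - j_mbe,
              nn_term = enn_full - enn_mbe,
              ts_nonadd = ts_full - ts_mbe,
              xc_nonadd = xc_full - xc_mbe,
              order = n)
  out$total <- out$v_nuc_term + out$coulomb_term + out$nn_term +
    out$ts_nonadd + out$xc_nonadd
  structure(out, class = "correction_breakdown")
}

#' @export
print.correction_breakdown <- function(x, ...) {
  cat(sprintf("density-based correction, order %d (Hartree):\n", x$order))
  for (nm in c("v_nuc_term", "coulomb_term", "nn_term", "ts_nonadd", "xc_nonadd"))
    cat(sprintf("  %-12s %+.10f\n", nm, x[[nm]]))
  cat(sprintf("  %-12s %+.10f  (%+.4f kJ/mol)\n", "total", x$total,
              hartree_to_kjmol(x$total)))
  invisible(x)
}

#' Density-based MBE total energy
#'
#' `E_dbMBE(n) = E_ebMBE(n) + E_dbcorr(n)`: the energy-based expansion is the
#' high level and the orbital-free functional, via the correction, the low
#' level of an ONIOM-style pairing. The per-order trace reports both
#' expansions for every k <= n.
#'
#' @param ledger `interaction_ledger` of subsystem total energies through `n`
#' @inheritParams mbe_of_functional_term
#' @return a `db_mbe_result`: `eb_energy`, `correction`
#'   (`correction_breakdown`), `db_energy`, and `trace` (data.frame with
#'   per-order eb/db totals)
#' @export
db_mbe_total <- function(ledger, fields, cluster, grid, n,
                         spec = functional_spec(),
                         route = c("recursive", "coefficients")) {
  route <- match.arg(route)
  N <- n_fragments(cluster)
  eb_k <- eb_mbe_trace(ledger, N, n)
  corr_k <- lapply(seq_len(n), function(k)
    db_correction(fields, cluster, grid, k, spec, route))
  db_k <- eb_k + vapply(corr_k, `[[`, 0, "total")
  structure(list(eb_energy = eb_k[n],
                 correction = corr_k[[n]],
                 db_energy = db_k[n],
                 trace = data.frame(order = seq_len(n), eb = eb_k, db = db_k)),
            class = "db_mbe_result")
}

#' @export
print.db_mbe_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat("db_mbe_result (order", n, "):\n")
  for (k in seq_len(n))
    cat(sprintf("  order %d: eb-MBE = %.10f  db-MBE = %.10f Hartree\n",
                k, x$trace$eb[k], x$trace$db[k]))
  print(x$correction)
  invisible(x)
}
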