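## Built-in restricted Hartree-Fock engine. Closed-shell RHF with DIIS
## convergence acceleration; the one-electron case (e.g. a hydrogen atom) is
## handled exactly as a single occupied orbital of the core Hamiltonian.
## This is the package's reference single-determinant backend for desk-scale
## fixtures; production-scale energies would come from an external program
## via the same backend contract (or Molden import for densities).

#' Nuclear repulsion energy
#' @param z nuclear charges
#' @param coords n x 3 coordinates, Bohr
#' @return energy in Hartree
#' @export
nuclear_repulsion <- function(z, coords) {
  n <- length(z)
  if (n < 2) return(0)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- e + z[i] * z[j] / sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  e
}

## symmetric orthogonalization S^{-1/2}
inv_sqrt_sym <- function(S) {
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    warning("near-linear-dependent basis (min eigenvalue ",
            signif(min(es$values), 3), ")")
  es$vectors %*% diag(1 / sqrt(es$values), nrow = length(es$values)) %*% t(es$vectors)
}

#' Restricted Hartree-Fock calculation
#'
#' Solves the closed-shell RHF equations in a built-in Gaussian basis with
#' DIIS acceleration. Convergence follows a tight criterion on both the
#' energy change and the orbital-gradient (DIIS error) norm.
#'
#' @param geometry geometry list with `elements`, `z`, `coords` (Bohr),
#'   `charge`, `n_electrons` (as from [subsystem_geometry()]), or a
#'   `cluster_system` (treated as one supermolecule)
#' @param basis basis-set name
#' @param conv_energy SCF energy convergence, Hartree
#' @param conv_error convergence on the max |FDS - SDF| element
#' @param max_iter iteration cap
#' @return an `rhf_result`: total `energy` (Hartree), orbital coefficients
#'   `C`, occupied count `nocc`, density matrix `D` (AO, trace = electrons),
#'   orbital energies `eps`, `basis_set` (`ao_basis`), `e_nn`, `converged`
#' @export
rhf <- function(geometry, basis = "sto-3g", conv_energy = 1e-10,
                conv_error = 1e-8, max_iter = 200) {
  if (inherits(geometry, "cluster_system")) {
    geometry <- subsystem_geometry(geometry, seq_len(n_fragments(geometry)))
  }
  ne <- geometry$n_electrons
  if (is.null(ne)) ne <- sum(geometry$z) - geometry$charge
  if (ne != 1 && ne %% 2 != 0)
    stop("open-shell systems are not supported by the built-in RHF engine ",
         "(got ", ne, " electrons)")
  B <- build_basis(geometry$elements, geometry$coords, basis)
  one <- cpp_one_electron(B, geometry$coords, as.numeric(geometry$z))
  H <- one$T + one$V
  X <- inv_sqrt_sym(one$S)
  e_nn <- nuclear_repulsion(geometry$z, geometry$coords)

  solve_fock <- function(F) {
    Ft <- t(X) %*% F %*% X
    es <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(es$values)
    list(C = X %*% es$vectors[, ord, drop = FALSE], eps = es$values[ord])
  }

  if (ne == 1) {
    sol <- solve_fock(H)
    C1 <- sol$C[, 1, drop = FALSE]
    D <- C1 %*% t(C1)
    energy <- sum(D * H) + e_nn
    return(structure(list(energy = energy, C = sol$C, nocc = 1L, D = D,
                          occ = c(1, rep(0, ncol(sol$C) - 1)),
                          eps = sol$eps, basis_set = B, e_nn = e_nn,
                          converged = TRUE, n_iter = 0L,
                          n_electrons = 1L, basis_name = tolower(basis)),
                     class = "rhf_result"))
  }

  nocc <- ne %/% 2L
  if (nocc > B$nbf) stop("basis too small: ", B$nbf, " functions for ",
                         ne, " electrons")
  eri <- cpp_eri(B)
  sol <- solve_fock(H)
  Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
  D <- 2 * Cocc %*% t(Cocc)
  e_old <- Inf
  converged <- FALSE
  err_list <- list(); fock_list <- list()
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    F <- H + cpp_fock_2e(eri, D)
    err <- F %*% D %*% one$S - one$S %*% D %*% F
    err <- t(X) %*% err %*% X
    max_err <- max(abs(err))
    # DIIS: keep up to 8 previous Fock matrices
    err_list <- c(err_list, list(as.vector(err)))
    fock_list <- c(fock_list, list(F))
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (m > 1) {
      Bm <- matrix(-1, m + 1, m + 1); Bm[m + 1, m + 1] <- 0
      for (a in seq_len(m)) for (b in seq_len(m))
        Bm[a, b] <- sum(err_list[[a]] * err_list[[b]])
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(Bm, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce(`+`, Map(function(w, fk) w * fk, cf, fock_list))
      }
    }
    sol <- solve_fock(F)
    Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
    D <- 2 * Cocc %*% t(Cocc)
    Fd <- H + cpp_fock_2e(eri, D)
    energy <- 0.5 * sum(D * (H + Fd)) + e_nn
    if (abs(energy - e_old) < conv_energy && max_err < conv_error) {
      converged <- TRUE
      e_old <- energy
      break
    }
    e_old <- energy
  }
  if (!converged)
    stop("SCF failed to converge in ", max_iter, " iterations (dE = ",
         signif(abs(energy - e_old), 3), ")")
  structure(list(energy = e_old, C = sol$C, nocc = nocc, D = D,
                 occ = c(rep(2, nocc), rep(0, ncol(sol$C) - nocc)),
                 eps = sol$eps, basis_set = B, e_nn = e_nn,
                 converged = TRUE, n_iter = n_iter,
                 n_electrons = ne, basis_name = tolower(basis)),
            class = "rhf_result")
}

#' @export
print.rhf_result <- function(x, ...) {
  cat(sprintf("RHF: E = %.10f Hartree (%d electrons, %d basis functions, %d iterations)\n",
              x$energy, x$n_electrons, x$basis_set$nbf, x$n_iter))
  invisible(x)
}
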