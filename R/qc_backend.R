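## Backend contract: a backend supplies per-subsystem total energies and
## electron densities / gradients / Coulomb potentials sampled on the shared
## grid. Implementations: the built-in restricted Hartree-Fock engine, the
## analytic Gaussian mock backend (every quantity has a closed form), and
## Molden import for wavefunctions computed by external programs.

#' Compute the total energy of a subsystem
#'
#' @param backend a backend object (see [hf_backend()], [mock_backend()])
#' @param geometry geometry list from [subsystem_geometry()]
#' @param ... backend-specific options
#' @return total (electronic + nuclear) energy in Hartree
#' @export
compute_energy <- function(backend, geometry, ...) UseMethod("compute_energy")

#' Sample a subsystem's density, gradient and Coulomb potential on a grid
#'
#' @param backend a backend object
#' @param geometry geometry list from [subsystem_geometry()]
#' @param grid the shared `integration_grid`
#' @param ... backend-specific options
#' @return a [field_on_grid()] (key left as `NA`; the workflow sets it)
#' @export
density_on_grid <- function(backend, geometry, grid, ...) UseMethod("density_on_grid")

geometry_digest <- function(geometry, extra = NULL) {
  digest::digest(list(geometry$elements, round(geometry$coords, 12),
                      geometry$charge, extra), algo = "xxhash64")
}

# ---------------------------------------------------------------------------
# built-in Hartree-Fock backend

#' Built-in restricted Hartree-Fock backend
#'
#' Wraps the package's RHF engine behind the backend contract. Converged
#' wavefunctions are memoized per geometry, so requesting the energy and then
#' the density of the same subsystem runs one SCF.
#'
#' @param basis basis-set name (see [basis_sets()])
#' @param conv_energy,conv_error,max_iter SCF settings passed to [rhf()]
#' @return a backend object of class `hf_backend`
#' @export
hf_backend <- function(basis = "sto-3g", conv_energy = 1e-10,
                       conv_error = 1e-8, max_iter = 200) {
  structure(list(name = paste0("RHF/", basis), method = "HF",
                 basis = tolower(basis),
                 conv_energy = conv_energy, conv_error = conv_error,
                 max_iter = max_iter,
                 memo = new.env(parent = emptyenv())),
            class = c("hf_backend", "qc_backend"))
}

hf_wavefunction <- function(backend, geometry) {
  id <- geometry_digest(geometry, backend$basis)
  if (!exists(id, backend$memo, inherits = FALSE)) {
    assign(id, rhf(geometry, basis = backend$basis,
                   conv_energy = backend$conv_energy,
                   conv_error = backend$conv_error,
                   max_iter = backend$max_iter),
           backend$memo)
  }
  get(id, backend$memo, inherits = FALSE)
}

#' @export
compute_energy.hf_backend <- function(backend, geometry, ...) {
  hf_wavefunction(backend, geometry)$energy
}

#' @export
density_on_grid.hf_backend <- function(backend, geometry, grid, ...) {
  wf <- hf_wavefunction(backend, geometry)
  dg <- cpp_density_grad(wf$basis_set, wf$D, grid$points)
  v <- cpp_esp(wf$basis_set, wf$D, grid$points)
  field_on_grid(NA_integer_, dg$rho, dg$grad, v,
                electron_count = wf$n_electrons,
                grid_signature = grid$signature)
}

#' @export
print.qc_backend <- function(x, ...) {
  cat("qc_backend:", x$name, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# analytic Gaussian mock backend

#' Analytic Gaussian mock backend
#'
#' Every fragment is represented by one normalized s-Gaussian of `q`
#' electrons centered at the fragment's heaviest atom; the declared total
#' energy is a closed-form pair potential (plus an optional three-body
#' term), and all electrostatic quantities have erf-form closed expressions.
#' This makes every expansion quantity exactly computable without any
#' self-consistent engine, which is what the toy fixtures and analytic
#' oracles in the tests rely on.
#'
#' The declared energy model for a subsystem S is
#' `E_S = sum_{I in S} e_I + sum_{I<J} A exp(-B R_IJ^2)
#'        + t3 * sum_{I<J<K} exp(-B (R_IJ^2 + R_IK^2 + R_JK^2))`
#' with `e_I = -q_I * alpha_I` — an arbitrary but fixed smooth form.
#'
#' @param cluster the `cluster_system` the backend serves
#' @param alphas Gaussian exponent per fragment (recycled)
#' @param A,B pair-potential parameters
#' @param t3 three-body strength (0 makes the energy exactly pairwise
#'   additive)
#' @return a backend object of class `mock_backend`
#' @export
mock_backend <- function(cluster, alphas = 1.0, A = 0.1, B = 0.05, t3 = 0) {
  N <- n_fragments(cluster)
  alphas <- rep_len(alphas, N)
  centers <- matrix(NA_real_, N, 3)
  q <- numeric(N)
  for (f in seq_len(N)) {
    sel <- which(cluster$fragment_of == f)
    heavy <- sel[which.max(cluster$z[sel])]
    centers[f, ] <- cluster$coords[heavy, ]
    q[f] <- fragment_electrons(cluster, f)
  }
  structure(list(name = "analytic Gaussian mock", method = "mock",
                 basis = "none", centers = centers, q = q, alphas = alphas,
                 A = A, B = B, t3 = t3),
            class = c("mock_backend", "qc_backend"))
}

## identify which fragments a subsystem geometry consists of: the fragments
## whose Gaussian centers coincide with one of the geometry's atoms
mock_members <- function(backend, geometry) {
  mem <- which(vapply(seq_len(nrow(backend$centers)), function(f) {
    any(rowSums(sweep(geometry$coords, 2, backend$centers[f, ])^2) < 1e-16)
  }, TRUE))
  if (!length(mem)) stop("geometry matches no mock fragment")
  mem
}

#' @export
compute_energy.mock_backend <- function(backend, geometry, ...) {
  mem <- mock_members(backend, geometry)
  e <- sum(-backend$q[mem] * backend$alphas[mem])
  n <- length(mem)
  r2 <- function(i, j) sum((backend$centers[mem[i], ] - backend$centers[mem[j], ])^2)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      e <- e + backend$A * exp(-backend$B * r2(i, j))
  }
  if (backend$t3 != 0 && n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
      e <- e + backend$t3 * exp(-backend$B * (r2(i, j) + r2(i, k) + r2(j, k)))
  }
  e
}

## closed-form field of one normalized s-Gaussian of q electrons
gaussian_fragment_field <- function(points, center, alpha, q) {
  d <- sweep(points, 2, center)
  r2 <- rowSums(d^2)
  rho <- q * (alpha / pi)^1.5 * exp(-alpha * r2)
  grad <- d * (-2 * alpha * rho)
  r <- sqrt(r2)
  v <- ifelse(r < 1e-12, q * 2 * sqrt(alpha / pi), q * erf_(sqrt(alpha) * r) / r)
  list(rho = rho, grad = grad, vcoul = v)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @export
density_on_grid.mock_backend <- function(backend, geometry, grid, ...) {
  mem <- mock_members(backend, geometry)
  rho <- 0; grad <- 0; v <- 0
  for (f in mem) {
    fl <- gaussian_fragment_field(grid$points, backend$centers[f, ],
                                  backend$alphas[f], backend$q[f])
    rho <- rho + fl$rho; grad <- grad + fl$grad; v <- v + fl$vcoul
  }
  field_on_grid(NA_integer_, rho, grad, v,
                electron_count = sum(backend$q[mem]),
                grid_signature = grid$signature)
}
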