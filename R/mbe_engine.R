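## Many-body expansion bookkeeping: k-mer enumeration, recursive interaction
## energies (inclusion-exclusion), truncated totals, and the signed expansion
## coefficients that reproduce a truncated density expansion as a single
## weighted sum over subsystems.

#' Canonical string form of a subsystem key
#'
#' Subsystem keys are strictly increasing integer vectors of fragment indices;
#' the dot-joined string is the canonical cache key.
#'
#' @param key integer vector of fragment indices
#' @return character scalar, e.g. `"1.3.4"`
#' @export
key_id <- function(key) paste(as.integer(key), collapse = ".")

#' Parse a canonical key string back into an integer vector
#' @param id string from [key_id()]
#' @return integer vector
#' @export
parse_key <- function(id) as.integer(strsplit(id, ".", fixed = TRUE)[[1]])

validate_key <- function(key, N = NULL) {
  key <- as.integer(key)
  if (length(key) < 1) stop("empty subsystem key")
  if (anyDuplicated(key)) stop("duplicate indices in subsystem key")
  if (is.unsorted(key, strictly = TRUE)) stop("subsystem key must be strictly increasing")
  if (!is.null(N) && any(key < 1L | key > N)) stop("fragment index out of range 1..", N)
  key
}

#' Enumerate all subsystems up to a truncation order
#'
#' Returns every k-mer key with 1 <= k <= n over N fragments, ordered by
#' order then lexicographically. The count is `sum_{k=1..n} choose(N, k)` —
#' the number of individual calculations a truncated expansion requires.
#'
#' @param N number of fragments
#' @param n truncation order
#' @return list of integer vectors (subsystem keys)
#' @export
enumerate_subsystems <- function(N, n) {
  N <- as.integer(N); n <- as.integer(n)
  if (n < 1L || n > N) stop("truncation order must satisfy 1 <= n <= N (got n=",
                            n, ", N=", N, ")")
  out <- list()
  for (k in seq_len(n)) {
    cmb <- utils::combn(N, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

#' Create an interaction ledger
#'
#' The ledger stores per-subsystem total energies (Hartree) and memoizes the
#' interaction energies derived from them.
#'
#' @param total_energies optional named numeric vector of total energies,
#'   names in [key_id()] form
#' @return an `interaction_ledger` object
#' @export
interaction_ledger <- function(total_energies = NULL) {
  env <- new.env(parent = emptyenv())
  env$total <- new.env(parent = emptyenv())
  env$delta <- new.env(parent = emptyenv())
  if (!is.null(total_energies)) {
    for (id in names(total_energies)) assign(id, total_energies[[id]], env$total)
  }
  structure(env, class = "interaction_ledger")
}

#' @export
print.interaction_ledger <- function(x, ...) {
  ids <- ls(x$total)
  ords <- lengths(lapply(ids, parse_key))
  cat("interaction_ledger: ", length(ids), " subsystem energies",
      if (length(ids)) paste0(" (orders ", min(ords), "..", max(ords), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Store a subsystem total energy
#' @param ledger an `interaction_ledger`
#' @param key subsystem key
#' @param energy total energy, Hartree
#' @return the ledger, invisibly
#' @export
set_total_energy <- function(ledger, key, energy) {
  assign(key_id(validate_key(key)), energy, ledger$total)
  invisible(ledger)
}

#' Retrieve a subsystem total energy
#' @param ledger an `interaction_ledger`
#' @param key subsystem key
#' @return energy in Hartree
#' @export
get_total_energy <- function(ledger, key) {
  id <- key_id(key)
  if (!exists(id, ledger$total, inherits = FALSE))
    stop("no total energy stored for subsystem {", id, "}")
  get(id, ledger$total, inherits = FALSE)
}

#' Has a total energy been stored for a key?
#' @param ledger an `interaction_ledger`
#' @param key subsystem key
#' @return logical
#' @export
has_total_energy <- function(ledger, key) {
  exists(key_id(key), ledger$total, inherits = FALSE)
}

proper_subsets <- function(key) {
  k <- length(key)
  out <- list()
  for (m in seq_len(k - 1L)) {
    cmb <- utils::combn(k, m)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) key[cmb[, j]]))
  }
  out
}

#' Recursive k-mer interaction energy
#'
#' The interaction energy of a subsystem S is its total energy minus the
#' interaction energies of all proper subsets,
#' `dE_S = E_S - sum_{T subset S} dE_T`, computed recursively with
#' memoization. For a monomer it is the monomer total energy. The recursion is
#' equivalent to the Moebius (inclusion-exclusion) form
#' `dE_S = sum_{T subseteq S} (-1)^{|S|-|T|} E_T`.
#'
#' @param ledger an `interaction_ledger` holding total energies for the key
#'   and all its subsets
#' @param key subsystem key
#' @return interaction energy in Hartree
#' @export
interaction_energy <- function(ledger, key) {
  key <- validate_key(key)
  id <- key_id(key)
  if (exists(id, ledger$delta, inherits = FALSE))
    return(get(id, ledger$delta, inherits = FALSE))
  e <- get_total_energy(ledger, key)
  if (length(key) > 1L) {
    for (sub in proper_subsets(key)) e <- e - interaction_energy(ledger, sub)
  }
  assign(id, e, ledger$delta)
  e
}

#' Truncated energy-based MBE total
#'
#' Sums all interaction energies of order up to `n`:
#' `E_ebMBE(n) = sum_{k=1..n} sum_{|S|=k} dE_S`. At `n = N` this telescopes
#' to the supermolecular total energy exactly.
#'
#' @param ledger an `interaction_ledger` complete through order `n`
#' @param N number of fragments
#' @param n truncation order
#' @return total energy in Hartree
#' @export
eb_mbe_total <- function(ledger, N, n) {
  keys <- enumerate_subsystems(N, n)
  missing <- vapply(keys, function(k) !has_total_energy(ledger, k), TRUE)
  if (any(missing))
    stop("ledger incomplete through order ", n, "; missing: ",
         paste(vapply(keys[missing], key_id, ""), collapse = ", "))
  sum(vapply(keys, function(k) interaction_energy(ledger, k), 0))
}

#' Per-order trace of the energy-based MBE
#' @param ledger an `interaction_ledger`
#' @param N number of fragments
#' @param n maximum order
#' @return numeric vector `e[k] = eb_mbe_total(k)` for k = 1..n
#' @export
eb_mbe_trace <- function(ledger, N, n) {
  vapply(seq_len(n), function(k) eb_mbe_total(ledger, N, k), 0)
}

#' Signed expansion coefficients of the truncated density MBE
#'
#' The order-n truncated many-body expansion of the density,
#' `rho^(n) = sum_I rho_I + sum_{I<J} drho_IJ + ...`, collapses into a single
#' weighted sum over subsystems, `rho^(n) = sum_S c_|S| rho_S`, with the
#' closed-form weights `c_k = (-1)^(n-k) * choose(N-k-1, n-k)` for every
#' subsystem of order k <= n. The same weights apply to any quantity that is
#' linear in the subsystem contributions. They satisfy the electron-count
#' identity `sum_S c_|S| * (electrons in S) = total electrons`.
#'
#' @param N number of fragments
#' @param n truncation order
#' @return an `expansion_coefficients` object: list with `N`, `n`, and
#'   `by_order` (numeric vector, `by_order[k]` is the weight of every order-k
#'   subsystem)
#' @export
expansion_coefficients <- function(N, n) {
  N <- as.integer(N); n <- as.integer(n)
  if (n < 1L || n > N) stop("truncation order must satisfy 1 <= n <= N")
  ck <- vapply(seq_len(n), function(k) (-1)^(n - k) * choose(N - k - 1, n - k), 0)
  structure(list(N = N, n = n, by_order = ck),
            class = "expansion_coefficients")
}

#' @export
print.expansion_coefficients <- function(x, ...) {
  cat("expansion_coefficients: N =", x$N, ", order n =", x$n, "\n")
  for (k in seq_len(x$n))
    cat(sprintf("  order %d subsystems: c = %+g\n", k, x$by_order[k]))
  invisible(x)
}

#' Coefficient of one subsystem in a truncated expansion
#' @param coeffs an [expansion_coefficients()] object
#' @param key subsystem key
#' @return numeric weight
#' @export
coefficient_of <- function(coeffs, key) {
  k <- length(validate_key(key, coeffs$N))
  if (k > coeffs$n) 0 else coeffs$by_order[k]
}
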