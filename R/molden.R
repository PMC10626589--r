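## Molden file ingestion and export. Molden is the interchange format that
## lets densities computed by external quantum-chemistry programs (with
## Gaussian-type orbitals) enter the density-based correction: geometry,
## contracted shells, molecular-orbital coefficients and occupations.
##
## Dialects: "standard" follows the common convention in which contraction
## coefficients refer to normalized Cartesian primitives (axial component for
## l >= 2) and describe normalized contracted functions (the writer
## renormalizes on export; the reader verifies via tr(DS)). The "orca"
## dialect differs for high angular momentum: its coefficients for l >= 2
## shells must be rescaled by sqrt((2l-1)!!) (d: sqrt 3, f: sqrt 15,
## g: sqrt 105) before the standard processing — the documented
## normalization-correction procedure for Orca-generated files. Shells up to
## d are supported (spherical [5D] or Cartesian); f/g raise an error.

.orca_l_scale <- c(s = 1, p = 1, sp = 1, d = sqrt(3), f = sqrt(15), g = sqrt(105))

# real solid-harmonic d components as raw Cartesian monomial combinations,
# Molden [5D] order: d0, d+1, d-1, d+2, d-2
.sph_d_terms <- list(
  list(mono = rbind(c(0, 0, 2), c(2, 0, 0), c(0, 2, 0)), coef = c(1, -0.5, -0.5)),
  list(mono = rbind(c(1, 0, 1)), coef = sqrt(3)),
  list(mono = rbind(c(0, 1, 1)), coef = sqrt(3)),
  list(mono = rbind(c(2, 0, 0), c(0, 2, 0)), coef = c(sqrt(3) / 2, -sqrt(3) / 2)),
  list(mono = rbind(c(1, 1, 0)), coef = sqrt(3))
)

# Molden Cartesian d order: xx, yy, zz, xy, xz, yz
.cart_d_order <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                       c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))

## expand one Molden shell into AOs. The file's contraction coefficients are
## trusted to describe normalized contracted functions over normalized
## primitives (the writer guarantees this), so no renormalization happens
## here — which is exactly what lets the tr(DS) electron-count check expose
## wrong-dialect normalization errors.
molden_shell_aos <- function(sh, center, spherical_d = TRUE) {
  if (sh$type == "s") {
    list(make_ao(sh$exps, sh$coefs, c(0L, 0L, 0L), center, renormalize = FALSE))
  } else if (sh$type == "p") {
    lapply(1:3, function(k) make_ao(sh$exps, sh$coefs,
                                    as.integer(k == 1:3), center,
                                    renormalize = FALSE))
  } else if (sh$type == "sp") {
    c(list(make_ao(sh$exps, sh$coefs, c(0L, 0L, 0L), center,
                   renormalize = FALSE)),
      lapply(1:3, function(k) make_ao(sh$exps, sh$coefs_p,
                                      as.integer(k == 1:3), center,
                                      renormalize = FALSE)))
  } else if (sh$type == "d") {
    if (spherical_d) {
      lapply(.sph_d_terms, function(term) {
        nterm <- nrow(term$mono)
        nprim <- length(sh$exps)
        # solid harmonic as raw monomials over axial-normalized primitives;
        # the monomial coefficients are scaled so a normalized contraction
        # yields a normalized spherical AO
        ao <- list(
          exp = rep(sh$exps, times = nterm),
          coef = as.vector(outer(sh$coefs * prim_norm(sh$exps, 2, 0, 0),
                                 term$coef)),
          l = term$mono[rep(seq_len(nterm), each = nprim), , drop = FALSE],
          center = matrix(rep(center, each = nterm * nprim), ncol = 3))
        storage.mode(ao$l) <- "integer"
        ao
      })
    } else {
      lapply(seq_len(6), function(k)
        make_ao(sh$exps, sh$coefs, .cart_d_order[k, ], center,
                renormalize = FALSE))
    }
  } else {
    stop("unsupported shell type in Molden file: ", sh$type,
         " (supported: s, p, sp, d)")
  }
}

#' Read a Molden file
#'
#' Parses geometry, Gaussian shells and molecular orbitals; shells up to d
#' (spherical `[5D]` or Cartesian) are supported. The `"orca"` dialect
#' applies the documented rescaling of l >= 2 contraction coefficients
#' before normalization.
#'
#' @param path Molden file
#' @param dialect `"standard"` or `"orca"`
#' @return a `molden_data`: `elements`, `z`, `coords` (Bohr), `shells`,
#'   `spherical_d`, `mo_coef` (nbf x nmo), `occ`, `energies`
#' @export
read_molden <- function(path, dialect = c("standard", "orca")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  secline <- grep("^\\s*\\[", lines)
  secname <- tolower(gsub(".*\\[(.*)\\].*", "\\1", lines[secline]))
  section <- function(name) {
    i <- which(secname == name)
    if (!length(i)) return(NULL)
    from <- secline[i[1]] + 1
    to <- if (i[1] < length(secline)) secline[i[1] + 1] - 1 else length(lines)
    lines[seq(from, length.out = max(0, to - from + 1))]
  }
  hdr <- lines[secline[secname == "atoms"]]
  if (!length(hdr)) stop("Molden file has no [Atoms] section: ", path)
  in_au <- grepl("AU", hdr[1], ignore.case = FALSE)
  at <- section("atoms")
  at <- at[nzchar(trimws(at))]
  toks <- strsplit(trimws(at), "\\s+")
  elements <- vapply(toks, `[[`, "", 1)
  z <- as.integer(vapply(toks, `[[`, "", 3))
  coords <- t(vapply(toks, function(t) as.numeric(t[4:6]), numeric(3)))
  if (!in_au) coords <- coords * dbmbe_units$bohr_per_angstrom
  gto <- section("gto")
  if (is.null(gto)) stop("Molden file has no [GTO] section: ", path)
  shells <- list()
  i <- 1
  gto <- c(gto, "")  # sentinel
  while (i <= length(gto)) {
    ln <- trimws(gto[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    tk <- strsplit(ln, "\\s+")[[1]]
    atom_idx <- suppressWarnings(as.integer(tk[1]))
    if (is.na(atom_idx)) stop("malformed [GTO] block near line: ", ln)
    i <- i + 1
    repeat {
      if (i > length(gto) || !nzchar(trimws(gto[i]))) { i <- i + 1; break }
      tk <- strsplit(trimws(gto[i]), "\\s+")[[1]]
      type <- tolower(tk[1])
      if (!type %in% c("s", "p", "sp", "d", "f", "g"))
        stop("unknown shell label in Molden [GTO]: ", tk[1])
      if (type %in% c("f", "g"))
        stop("unsupported angular momentum in Molden file: ", type,
             " shells are not supported")
      nprim <- as.integer(tk[2])
      i <- i + 1
      prim <- strsplit(trimws(gto[seq(i, length.out = nprim)]), "\\s+")
      num <- function(s) as.numeric(gsub("[dD]", "e", s))
      exps <- vapply(prim, function(p) num(p[1]), 0)
      coefs <- vapply(prim, function(p) num(p[2]), 0)
      sc <- .orca_l_scale[[type]] %||% 1
      if (dialect == "orca") coefs <- coefs * sc
      sh <- list(atom = atom_idx, type = type, exps = exps, coefs = coefs)
      if (type == "sp") {
        cp <- vapply(prim, function(p) num(p[3]), 0)
        sh$coefs_p <- cp
      }
      shells[[length(shells) + 1]] <- sh
      i <- i + nprim
    }
  }
  spherical_d <- "5d" %in% secname
  mo <- section("mo")
  if (is.null(mo)) stop("Molden file has no [MO] section: ", path)
  aos_per_shell <- vapply(shells, function(sh) switch(sh$type, s = 1L, p = 3L,
                                                      sp = 4L,
                                                      d = if (spherical_d) 5L else 6L), 0L)
  nbf <- sum(aos_per_shell)
  occ <- numeric(); energies <- numeric(); comat <- list()
  cur <- NULL
  flush_mo <- function() {
    if (!is.null(cur)) comat[[length(comat) + 1]] <<- cur
  }
  for (ln in mo) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (grepl("^Sym\\s*=", t, ignore.case = TRUE)) { flush_mo(); cur <- numeric(nbf) }
    else if (grepl("^Ene\\s*=", t, ignore.case = TRUE))
      energies <- c(energies, as.numeric(sub(".*=", "", t)))
    else if (grepl("^Spin\\s*=", t, ignore.case = TRUE)) {
      if (!grepl("alpha", t, ignore.case = TRUE))
        stop("only closed-shell (Alpha-only) Molden files are supported")
    } else if (grepl("^Occup\\s*=", t, ignore.case = TRUE))
      occ <- c(occ, as.numeric(sub(".*=", "", t)))
    else {
      tk <- strsplit(t, "\\s+")[[1]]
      if (is.null(cur)) cur <- numeric(nbf)
      cur[as.integer(tk[1])] <- as.numeric(gsub("[dD]", "e", tk[2]))
    }
  }
  flush_mo()
  if (!length(comat)) stop("no molecular orbitals found in ", path)
  mo_coef <- do.call(cbind, comat)
  if (length(occ) != ncol(mo_coef))
    stop("occupation count does not match orbital count in ", path)
  ne <- sum(occ)
  if (abs(ne - round(ne)) > 1e-8)
    stop("occupations sum to non-integer electron count: ", ne)
  structure(list(elements = elements, z = z, coords = coords,
                 shells = shells, spherical_d = spherical_d,
                 mo_coef = mo_coef, occ = occ, energies = energies,
                 dialect = dialect),
            class = "molden_data")
}

#' @export
print.molden_data <- function(x, ...) {
  cat("molden_data:", length(x$elements), "atoms,", length(x$shells),
      "shells,", ncol(x$mo_coef), "MOs,", sum(x$occ), "electrons\n")
  invisible(x)
}

#' Build the AO basis and density matrix of a Molden wavefunction
#'
#' @param molden a `molden_data`
#' @return list with `basis` (an `ao_basis`) and `D` (AO density matrix,
#'   trace = electron count)
#' @export
molden_density_matrix <- function(molden) {
  aos <- list()
  for (sh in molden$shells) {
    aos <- c(aos, molden_shell_aos(sh, molden$coords[sh$atom, ],
                                   molden$spherical_d))
  }
  B <- ao_basis(aos)
  if (B$nbf != nrow(molden$mo_coef))
    stop("AO count mismatch: basis has ", B$nbf, ", MO matrix has ",
         nrow(molden$mo_coef))
  C <- molden$mo_coef
  D <- C %*% (molden$occ * t(C))
  # consistency: tr(DS) must equal the electron count
  S <- cpp_one_electron(B, matrix(0, 1, 3), 0)$S
  trDS <- sum(D * S)
  if (abs(trDS - sum(molden$occ)) > 1e-6)
    stop("Molden normalization inconsistency: tr(DS) = ", trDS,
         " but occupations sum to ", sum(molden$occ),
         " (wrong dialect for this file?)")
  list(basis = B, D = D)
}

#' Sample a Molden wavefunction's field on a grid
#'
#' @param molden a `molden_data`
#' @param grid an `integration_grid`
#' @return a [field_on_grid()]
#' @export
molden_field <- function(molden, grid) {
  bd <- molden_density_matrix(molden)
  dg <- cpp_density_grad(bd$basis, bd$D, grid$points)
  v <- cpp_esp(bd$basis, bd$D, grid$points)
  field_on_grid(NA_integer_, dg$rho, dg$grad, v,
                electron_count = sum(molden$occ),
                grid_signature = grid$signature)
}

#' Convert an RHF result to Molden data
#'
#' @param wf an `rhf_result`
#' @param geometry the geometry it was computed for
#' @return a `molden_data`
#' @export
rhf_to_molden <- function(wf, geometry) {
  lib <- .basis_library[[wf$basis_name]]
  shells <- list()
  for (i in seq_along(geometry$elements)) {
    for (sh in lib[[geometry$elements[i]]]) {
      rec <- list(atom = i, type = sh$l, exps = sh$exps, coefs = sh$coefs)
      if (sh$l == "sp") rec$coefs_p <- sh$coefs_p
      shells[[length(shells) + 1]] <- rec
    }
  }
  structure(list(elements = geometry$elements, z = geometry$z,
                 coords = geometry$coords, shells = shells,
                 spherical_d = TRUE, mo_coef = wf$C, occ = wf$occ,
                 energies = wf$eps, dialect = "standard"),
            class = "molden_data")
}

#' Write Molden data to a file
#'
#' The `"orca"` dialect emits l >= 2 contraction coefficients divided by the
#' rescaling factor, reproducing files that require the dialect fix on read
#' (used as a regression guard in the tests).
#'
#' @param molden a `molden_data`
#' @param path output file
#' @param dialect `"standard"` or `"orca"`
#' @return `path`, invisibly
#' @export
write_molden <- function(molden, path, dialect = c("standard", "orca")) {
  dialect <- match.arg(dialect)
  out <- c("[Molden Format]", "[Atoms] AU")
  for (i in seq_along(molden$elements)) {
    out <- c(out, sprintf("%-3s %4d %4d %18.10f %18.10f %18.10f",
                          molden$elements[i], i, molden$z[i],
                          molden$coords[i, 1], molden$coords[i, 2],
                          molden$coords[i, 3]))
  }
  out <- c(out, "[GTO]")
  axial <- list(s = c(0L, 0L, 0L), p = c(1L, 0L, 0L), d = c(2L, 0L, 0L))
  for (i in seq_along(molden$elements)) {
    out <- c(out, sprintf("%d 0", i))
    for (sh in molden$shells) {
      if (sh$atom != i) next
      out <- c(out, sprintf(" %-2s %4d 1.00", sh$type, length(sh$exps)))
      sc <- if (dialect == "orca") .orca_l_scale[[sh$type]] else 1
      # emit normalized contractions (idempotent for already-normalized input)
      renorm <- function(coefs, lx) {
        coefs / sqrt(contracted_self_overlap(sh$exps, coefs, lx[1], lx[2], lx[3]))
      }
      if (sh$type == "sp") {
        cs <- renorm(sh$coefs, axial$s)
        cp <- renorm(sh$coefs_p, axial$p)
        for (p in seq_along(sh$exps))
          out <- c(out, sprintf("  %25.17e %25.17e %25.17e", sh$exps[p],
                                cs[p] / sc, cp[p] / sc))
      } else {
        cc <- renorm(sh$coefs, axial[[sh$type]])
        for (p in seq_along(sh$exps))
          out <- c(out, sprintf("  %25.17e %25.17e", sh$exps[p],
                                cc[p] / sc))
      }
    }
    out <- c(out, "")
  }
  if (molden$spherical_d) out <- c(out, "[5D]")
  out <- c(out, "[MO]")
  for (m in seq_len(ncol(molden$mo_coef))) {
    ene <- if (length(molden$energies) >= m) molden$energies[m] else 0
    out <- c(out, "Sym= A", sprintf("Ene= %18.10f", ene), "Spin= Alpha",
             sprintf("Occup= %.6f", molden$occ[m]),
             sprintf("%6d %24.16e", seq_len(nrow(molden$mo_coef)),
                     molden$mo_coef[, m]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Molden-file backend
#'
#' Serves subsystem energies and densities from user-supplied tables: a named
#' list of Molden files (canonical subsystem ids as names) and a matching
#' named vector of total energies from the external program's output. This is
#' how wavefunctions from methods the package does not implement (DFT,
#' orbital-optimized coupled cluster) enter the expansion.
#'
#' @param files named list/vector of Molden paths, names from [key_id()]
#' @param energies named numeric vector of total energies (Hartree)
#' @param dialect Molden dialect of the files
#' @return a backend of class `molden_backend`
#' @export
molden_backend <- function(files, energies = NULL,
                           dialect = c("standard", "orca")) {
  dialect <- match.arg(dialect)
  structure(list(name = paste0("Molden import (", dialect, ")"),
                 method = "molden", basis = "external",
                 files = files, energies = energies, dialect = dialect),
            class = c("molden_backend", "qc_backend"))
}

#' @export
compute_energy.molden_backend <- function(backend, geometry, ..., key = NULL) {
  if (is.null(backend$energies) || is.null(key))
    stop("molden_backend needs an energy table and a subsystem key")
  id <- key_id(key)
  if (!id %in% names(backend$energies))
    stop("no energy supplied for subsystem {", id, "}")
  backend$energies[[id]]
}

#' @export
density_on_grid.molden_backend <- function(backend, geometry, grid, ...,
                                           key = NULL) {
  if (is.null(key)) stop("molden_backend needs the subsystem key")
  id <- key_id(key)
  path <- backend$files[[id]]
  if (is.null(path)) stop("no Molden file supplied for subsystem {", id, "}")
  molden_field(read_molden(path, backend$dialect), grid)
}
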