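## Cluster representation: atoms partitioned into whole-molecule fragments.
## Coordinates are stored in Bohr; XYZ I/O is in Angstrom.

# Elements H..Kr: nuclear charge and covalent radius (Angstrom, Cordero 2008).
.element_table <- local({
  sym <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
           "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
           "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni",
           "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr")
  rcov <- c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
            1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06,
            2.03, 1.76, 1.70, 1.60, 1.53, 1.39, 1.39, 1.32, 1.26, 1.24,
            1.32, 1.22, 1.22, 1.20, 1.19, 1.20, 1.20, 1.16)
  data.frame(symbol = sym, z = seq_along(sym), rcov = rcov,
             stringsAsFactors = FALSE)
})

#' Nuclear charge of an element symbol
#' @param symbol chemical symbol(s), e.g. "O"
#' @return integer nuclear charge(s)
#' @export
element_z <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(symbol[is.na(i)], collapse = ", "))
  .element_table$z[i]
}

covalent_radius_bohr <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  .element_table$rcov[i] * dbmbe_units$bohr_per_angstrom
}

#' Construct a fragmented molecular cluster
#'
#' A `cluster_system` holds atoms (elements and Cartesian coordinates in Bohr)
#' partitioned into non-overlapping fragments — the expansion universe of the
#' many-body expansion. Fragments are whole molecules; each carries a net
#' charge and a spin multiplicity (closed-shell singlet by default).
#'
#' @param elements character vector of chemical symbols, one per atom
#' @param coords numeric n x 3 matrix of coordinates in Bohr
#' @param fragment_of integer vector, 1-based fragment index per atom
#' @param charges integer vector of per-fragment net charges (default all 0),
#'   or a named list/vector mapping fragment index to charge
#' @param multiplicities integer vector of per-fragment spin multiplicities
#'   (default all 1)
#' @param name label for the cluster
#' @return an object of class `cluster_system`
#' @export
cluster_system <- function(elements, coords, fragment_of,
                           charges = NULL, multiplicities = NULL,
                           name = "cluster") {
  coords <- as.matrix(coords)
  n <- length(elements)
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  z <- element_z(elements)
  fragment_of <- as.integer(fragment_of)
  if (length(fragment_of) != n) stop("fragment_of must have one entry per atom")
  nfrag <- max(fragment_of)
  if (!setequal(unique(fragment_of), seq_len(nfrag)))
    stop("fragment indices must cover 1..nfrag with no gaps")
  chg <- integer(nfrag)
  if (!is.null(charges)) {
    if (!is.null(names(charges))) {
      idx <- as.integer(names(charges))
      chg[idx] <- as.integer(unlist(charges))
    } else {
      stopifnot(length(charges) == nfrag)
      chg <- as.integer(charges)
    }
  }
  mult <- if (is.null(multiplicities)) rep(1L, nfrag) else as.integer(multiplicities)
  stopifnot(length(mult) == nfrag, all(mult >= 1))
  for (f in seq_len(nfrag)) {
    ne <- sum(z[fragment_of == f]) - chg[f]
    if (ne < 0) stop("fragment ", f, " has negative electron count")
    if (ne == 0) stop("fragment ", f, " has zero electrons")
  }
  structure(list(elements = elements, z = z, coords = coords,
                 fragment_of = fragment_of, charges = chg,
                 multiplicities = mult, name = name),
            class = "cluster_system")
}

#' @export
print.cluster_system <- function(x, ...) {
  cat("cluster_system '", x$name, "': ", length(x$elements), " atoms in ",
      n_fragments(x), " fragments, total charge ", sum(x$charges), "\n",
      sep = "")
  for (f in seq_len(n_fragments(x))) {
    sel <- x$fragment_of == f
    cat(sprintf("  fragment %d: %s  charge %+d  (%d electrons)\n", f,
                paste(x$elements[sel], collapse = ""), x$charges[f],
                fragment_electrons(x, f)))
  }
  invisible(x)
}

#' Number of fragments in a cluster
#' @param cluster a `cluster_system`
#' @return integer fragment count
#' @export
n_fragments <- function(cluster) length(cluster$charges)

#' Electron count of one fragment
#' @param cluster a `cluster_system`
#' @param i fragment index
#' @return integer electron count (sum of nuclear charges minus net charge)
#' @export
fragment_electrons <- function(cluster, i) {
  sum(cluster$z[cluster$fragment_of == i]) - cluster$charges[i]
}

#' Total electron count of a cluster
#' @param cluster a `cluster_system`
#' @return integer
#' @export
cluster_electrons <- function(cluster) {
  sum(cluster$z) - sum(cluster$charges)
}

#' Geometry of a k-mer subsystem
#'
#' Concatenates the atoms of the selected fragments into a single geometry.
#' The subsystem charge is the sum of fragment charges; the multiplicity
#' follows closed-shell bookkeeping (singlet unless unpaired electrons force
#' a higher value, which for the closed-shell fragments treated here means
#' singlet throughout).
#'
#' @param cluster a `cluster_system`
#' @param key strictly increasing integer vector of fragment indices
#' @return list with `elements`, `z`, `coords` (Bohr), `charge`,
#'   `multiplicity`, `n_electrons`
#' @export
subsystem_geometry <- function(cluster, key) {
  key <- as.integer(key)
  if (anyDuplicated(key)) stop("duplicate fragment indices in subsystem key")
  if (is.unsorted(key, strictly = TRUE)) stop("subsystem key must be strictly increasing")
  if (any(key < 1L | key > n_fragments(cluster))) stop("fragment index out of range")
  sel <- cluster$fragment_of %in% key
  ne <- sum(vapply(key, function(i) fragment_electrons(cluster, i), 0L))
  unpaired <- sum(cluster$multiplicities[key] - 1L)
  list(elements = cluster$elements[sel],
       z = cluster$z[sel],
       coords = cluster$coords[sel, , drop = FALSE],
       charge = sum(cluster$charges[key]),
       multiplicity = if (unpaired > 0L) unpaired + 1L else if (ne %% 2L == 1L) 2L else 1L,
       n_electrons = ne)
}

## connected components of the covalent-radius bond graph;
## bonded iff d < 1.2 * (rcov_a + rcov_b)
auto_fragment <- function(elements, coords) {
  n <- length(elements)
  r <- covalent_radius_bohr(elements)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < 1.2 * (r[i] + r[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Read a cluster from an XYZ file
#'
#' Standard XYZ dialect: atom count, comment line, then one `element x y z`
#' row per atom in Angstrom. Coordinates are converted to Bohr internally.
#' Fragments are assigned either automatically (connected components of the
#' covalent bond graph, bonded when the distance is below 1.2 times the sum of
#' covalent radii) or from explicit per-atom labels.
#'
#' @param path XYZ file path
#' @param fragments `"auto"`, an integer vector of per-atom fragment labels,
#'   or a path to a sidecar file holding one integer label per atom line
#' @param charges optional per-fragment charge map (named by fragment index)
#'   or full vector; fragments default to neutral singlets
#' @param multiplicities optional per-fragment multiplicities
#' @param name cluster label (defaults to the XYZ comment line, or file name)
#' @return a [cluster_system()]
#' @export
read_xyz <- function(path, fragments = "auto", charges = NULL,
                     multiplicities = NULL, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ (", path, "): fewer than 2 lines")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("malformed XYZ (", path, "): line 1 is not an atom count")
  if (length(lines) < nat + 2) stop("malformed XYZ (", path, "): expected ",
                                    nat, " atom lines")
  elements <- character(nat)
  coords <- matrix(NA_real_, nat, 3)
  for (i in seq_len(nat)) {
    toks <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
    if (length(toks) < 4) stop("malformed XYZ (", path, "): line ", i + 2)
    elements[i] <- toks[1]
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz)) stop("malformed XYZ (", path, "): line ", i + 2,
                         " has non-numeric coordinates")
    coords[i, ] <- xyz
  }
  coords <- coords * dbmbe_units$bohr_per_angstrom
  if (is.character(fragments) && length(fragments) == 1 && fragments == "auto") {
    frag <- auto_fragment(elements, coords)
  } else if (is.character(fragments) && length(fragments) == 1) {
    lab <- as.integer(readLines(fragments, warn = FALSE))
    if (length(lab) != nat) stop("fragment sidecar has ", length(lab),
                                 " labels for ", nat, " atoms")
    frag <- match(lab, sort(unique(lab)))
  } else {
    lab <- as.integer(fragments)
    if (length(lab) != nat) stop("fragment labels must have one entry per atom")
    frag <- match(lab, sort(unique(lab)))
  }
  if (is.null(name)) {
    name <- trimws(lines[2])
    if (!nzchar(name)) name <- basename(path)
  }
  cluster_system(elements, coords, frag, charges = charges,
                 multiplicities = multiplicities, name = name)
}

#' Write a cluster (or subsystem geometry) to an XYZ file
#'
#' @param x a `cluster_system` or a geometry list from [subsystem_geometry()]
#' @param path output path; a sidecar `<path>.frag` with per-atom fragment
#'   labels is written alongside when `sidecar = TRUE` and `x` is a cluster
#' @param sidecar write the fragment sidecar file
#' @return `path`, invisibly
#' @export
write_xyz <- function(x, path, sidecar = FALSE) {
  ang <- x$coords * dbmbe_units$angstrom_per_bohr
  lines <- c(as.character(length(x$elements)),
             if (!is.null(x$name)) x$name else "",
             sprintf("%-3s %20.12f %20.12f %20.12f",
                     x$elements, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  if (sidecar && !is.null(x$fragment_of))
    writeLines(as.character(x$fragment_of), paste0(path, ".frag"))
  invisible(path)
}
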