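## Gaussian basis sets and the flattened AO representation consumed by the
## C++ integral engine. An AO is a list of Cartesian primitives (exponent,
## powers, center, coefficient); normalization is folded into the
## coefficients here so the integral code never revisits it.

double_factorial <- function(n) {
  # (-1)!! = 1 by convention
  vapply(n, function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2)), 0)
}

prim_norm <- function(alpha, lx, ly, lz) {
  l <- lx + ly + lz
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) /
    sqrt(double_factorial(2 * lx - 1) * double_factorial(2 * ly - 1) *
         double_factorial(2 * lz - 1))
}

## self-overlap of a contracted same-center Cartesian AO with normalized-
## primitive coefficients c (used to renormalize the contraction)
contracted_self_overlap <- function(exps, coefs, lx, ly, lz) {
  s <- 0
  n <- length(exps)
  dfs <- double_factorial(2 * lx - 1) * double_factorial(2 * ly - 1) *
    double_factorial(2 * lz - 1)
  l <- lx + ly + lz
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- exps[i] + exps[j]
    s <- s + coefs[i] * coefs[j] *
      prim_norm(exps[i], lx, ly, lz) * prim_norm(exps[j], lx, ly, lz) *
      (pi / p)^1.5 * dfs / (2 * p)^l
  }
  s
}

# Built-in segmented basis sets. Each element maps to a list of shells;
# a shell is list(l = "s" | "sp" | "p" | "d", exps, coefs [, coefs_p for sp]).
.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = "s",
                  exps = c(3.425250914, 0.6239137298, 0.1688554040),
                  coefs = c(0.1543289673, 0.5353281423, 0.4446345422))),
    C = list(list(l = "s",
                  exps = c(71.61683735, 13.04509632, 3.530512160),
                  coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
             list(l = "sp",
                  exps = c(2.941249355, 0.6834830964, 0.2222899159),
                  coefs = c(-0.09996722919, 0.3995128261, 0.7001154689),
                  coefs_p = c(0.1559162750, 0.6076837186, 0.3919573931))),
    N = list(list(l = "s",
                  exps = c(99.10616896, 18.05231239, 4.885660238),
                  coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
             list(l = "sp",
                  exps = c(3.780455879, 0.8784966449, 0.2857143744),
                  coefs = c(-0.09996722919, 0.3995128261, 0.7001154689),
                  coefs_p = c(0.1559162750, 0.6076837186, 0.3919573931))),
    O = list(list(l = "s",
                  exps = c(130.7093200, 23.80886100, 6.443608313),
                  coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
             list(l = "sp",
                  exps = c(5.033151319, 1.169596125, 0.3803889600),
                  coefs = c(-0.09996722919, 0.3995128261, 0.7001154689),
                  coefs_p = c(0.1559162750, 0.6076837186, 0.3919573931)))
  ),
  "6-31g" = list(
    H = list(list(l = "s",
                  exps = c(18.73113696, 2.825394365, 0.6401216923),
                  coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
             list(l = "s", exps = 0.1612777588, coefs = 1.0)),
    O = list(list(l = "s",
                  exps = c(5484.671660, 825.2349460, 188.0469580,
                           52.96450000, 16.89757040, 5.799635340),
                  coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                            0.2327143360, 0.4701928980, 0.3585208530)),
             list(l = "sp",
                  exps = c(15.53961625, 3.599933586, 1.013761750),
                  coefs = c(-0.1107775495, -0.1480262627, 1.130767015),
                  coefs_p = c(0.07087426823, 0.3397528391, 0.7271585773)),
             list(l = "sp", exps = 0.2700058226, coefs = 1.0, coefs_p = 1.0))
  )
)

#' Available built-in basis sets
#' @return character vector of basis-set names
#' @export
basis_sets <- function() names(.basis_library)

cart_components <- function(l) {
  # canonical Cartesian component ordering per angular momentum
  switch(as.character(l),
         "0" = matrix(c(0, 0, 0), 1, 3),
         "1" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
         "2" = rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                     c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
         stop("unsupported angular momentum l=", l))
}

## assemble one contracted Cartesian AO as a primitive table; coefficients
## refer to normalized primitives, and the contraction itself is
## renormalized unless renormalize = FALSE (Molden read path, which trusts
## the file's normalized contractions)
make_ao <- function(exps, coefs, lxyz, center, renormalize = TRUE) {
  cn <- coefs * prim_norm(exps, lxyz[1], lxyz[2], lxyz[3])
  if (renormalize) {
    s <- contracted_self_overlap(exps, coefs, lxyz[1], lxyz[2], lxyz[3])
    cn <- cn / sqrt(s)
  }
  list(exp = exps, coef = cn,
       l = matrix(rep(lxyz, each = length(exps)), ncol = 3),
       center = matrix(rep(center, each = length(exps)), ncol = 3))
}

#' Build an AO basis for a geometry
#'
#' Expands a built-in basis set over the atoms of a geometry into the flat
#' primitive table used by the integral routines.
#'
#' @param elements character vector of element symbols
#' @param coords n x 3 matrix, Bohr
#' @param basis basis-set name (see [basis_sets()])
#' @return an `ao_basis` object (flattened primitive table plus labels)
#' @export
build_basis <- function(elements, coords, basis = "sto-3g") {
  bname <- tolower(basis)
  lib <- .basis_library[[bname]]
  if (is.null(lib)) stop("unknown basis set: ", basis,
                         " (available: ", paste(basis_sets(), collapse = ", "), ")")
  aos <- list()
  labels <- character()
  for (i in seq_along(elements)) {
    el <- elements[i]
    shells <- lib[[el]]
    if (is.null(shells)) stop("basis ", basis, " has no entry for element ", el)
    for (sh in shells) {
      if (sh$l == "s") {
        aos <- c(aos, list(make_ao(sh$exps, sh$coefs, c(0L, 0L, 0L), coords[i, ])))
        labels <- c(labels, paste0(el, i, ".s"))
      } else if (sh$l == "sp") {
        aos <- c(aos, list(make_ao(sh$exps, sh$coefs, c(0L, 0L, 0L), coords[i, ])))
        labels <- c(labels, paste0(el, i, ".s"))
        for (comp in c("x", "y", "z")) {
          lxyz <- as.integer(comp == c("x", "y", "z"))
          aos <- c(aos, list(make_ao(sh$exps, sh$coefs_p, lxyz, coords[i, ])))
          labels <- c(labels, paste0(el, i, ".p", comp))
        }
      } else if (sh$l == "p") {
        for (comp in c("x", "y", "z")) {
          lxyz <- as.integer(comp == c("x", "y", "z"))
          aos <- c(aos, list(make_ao(sh$exps, sh$coefs, lxyz, coords[i, ])))
          labels <- c(labels, paste0(el, i, ".p", comp))
        }
      } else stop("unsupported shell type ", sh$l)
    }
  }
  ao_basis(aos, labels)
}

#' Assemble an `ao_basis` from a list of AO primitive tables
#'
#' Low-level constructor used by [build_basis()], the Molden reader and the
#' analytic toy backend.
#'
#' @param aos list of AOs as produced by the internal AO builder: each a list
#'   with `exp`, `coef`, `l` (nprim x 3 integer), `center` (nprim x 3)
#' @param labels optional AO labels
#' @return an `ao_basis`: list with `nprim`, `exp`, `coef`, `l`, `center`,
#'   `labels`, `nbf`
#' @export
ao_basis <- function(aos, labels = NULL) {
  structure(list(
    nprim = vapply(aos, function(a) length(a$exp), 0L),
    exp = unlist(lapply(aos, `[[`, "exp")),
    coef = unlist(lapply(aos, `[[`, "coef")),
    l = do.call(rbind, lapply(aos, `[[`, "l")),
    center = do.call(rbind, lapply(aos, `[[`, "center")),
    labels = if (is.null(labels)) paste0("ao", seq_along(aos)) else labels,
    nbf = length(aos)
  ), class = "ao_basis")
}

#' @export
print.ao_basis <- function(x, ...) {
  cat("ao_basis:", x$nbf, "contracted functions,",
      length(x$exp), "primitives\n")
  invisible(x)
}
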