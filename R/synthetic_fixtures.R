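## Deterministic test-input generators: hydrogen-bonded-style water clusters
## (rigid gas-phase monomers, constrained O-O separations) and analytic
## Gaussian toy clusters whose every expansion quantity has a closed form.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

## rigid gas-phase water monomer, O at origin (Bohr)
water_monomer_coords <- function() {
  r <- 0.9572 * dbmbe_units$bohr_per_angstrom
  half <- 104.52 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = r * c(sin(half), cos(half), 0),
        H2 = r * c(-sin(half), cos(half), 0))
}

#' Generate a deterministic water-cluster fixture
#'
#' Places `n` rigid water monomers (r_OH = 0.9572 Angstrom, HOH angle =
#' 104.52 degrees). Two placement modes:
#' \describe{
#'   \item{`"ring"` (default)}{a cyclic hydrogen-bonded arrangement: oxygens
#'     on a regular polygon with neighbor O-O distance in the middle of
#'     `[min_oo, max_oo]`, each water donating one O-H toward the next
#'     oxygen and pointing its free hydrogen alternately above/below the
#'     ring plane — the classic cooperative cluster motif, where three-body
#'     polarization is substantial. A small seeded jitter (rigid-body
#'     rotations up to ~5 degrees and oxygen displacements up to 0.1 Bohr)
#'     breaks symmetry reproducibly.}
#'   \item{`"box"`}{random growth: each new oxygen at a random direction and
#'     distance in `[min_oo, max_oo]` from a previously placed oxygen, with
#'     a random monomer orientation.}
#' }
#' In both modes no O-O pair falls below `min_oo` and no interatomic
#' distance across fragments falls below 1.5 Bohr. The defaults emulate
#' hydrogen-bonded clusters with O-O separations of about 2.7-3.2 Angstrom.
#' Reproducible from the seed.
#'
#' @param n number of waters
#' @param seed RNG seed
#' @param mode `"ring"` or `"box"`
#' @param min_oo,max_oo neighbor O-O distance bounds, Bohr
#' @param max_tries placement retries before giving up (box mode)
#' @return a [cluster_system()] with one fragment per water
#' @export
make_water_cluster <- function(n, seed = 1, mode = c("ring", "box"),
                               min_oo = 2.7 * dbmbe_units$bohr_per_angstrom,
                               max_oo = 3.2 * dbmbe_units$bohr_per_angstrom,
                               max_tries = 500) {
  stopifnot(n >= 1)
  mode <- match.arg(mode)
  if (n <= 2 || mode == "box") coords <- water_box_coords(n, seed, min_oo, max_oo, max_tries)
  else coords <- water_ring_coords(n, seed, (min_oo + max_oo) / 2)
  cluster_system(rep(c("O", "H", "H"), n), coords,
                 rep(seq_len(n), each = 3),
                 name = sprintf("water%d_%s_seed%d", n, mode, seed))
}

water_ring_coords <- function(n, seed, d_oo) {
  with_seed(seed, {
    r_oh <- 0.9572 * dbmbe_units$bohr_per_angstrom
    theta <- 104.52 * pi / 180
    radius <- d_oo / (2 * sin(pi / n))
    coords <- NULL
    ang <- 2 * pi * (seq_len(n) - 1) / n
    oxy <- cbind(radius * cos(ang), radius * sin(ang), 0)
    oxy <- oxy + matrix(stats::runif(3 * n, -0.1, 0.1), n, 3)  # jitter
    for (k in seq_len(n)) {
      o <- oxy[k, ]
      nxt <- oxy[if (k == n) 1 else k + 1, ]
      u <- nxt - o; u <- u / sqrt(sum(u^2))       # donor O-H direction
      zax <- c(0, 0, 1) * (-1)^k
      w <- zax - sum(zax * u) * u; w <- w / sqrt(sum(w^2))
      h1 <- o + r_oh * u
      h2 <- o + r_oh * (cos(theta) * u + sin(theta) * w)
      mono <- rbind(o, h1, h2)
      # small rigid-body jitter rotation about the oxygen
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      angj <- stats::runif(1, -5, 5) * pi / 180
      K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
      Rj <- diag(3) + sin(angj) * K + (1 - cos(angj)) * K %*% K
      mono <- t(Rj %*% (t(mono) - o)) + rep(o, each = 3)
      coords <- rbind(coords, mono)
    }
    rownames(coords) <- NULL
    coords
  })
}

water_box_coords <- function(n, seed, min_oo, max_oo, max_tries) {
  with_seed(seed, {
    mono <- water_monomer_coords()
    oxygens <- matrix(0, n, 3)
    coords <- t(random_rotation() %*% t(mono))
    placed <- 1L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " waters after ", max_tries, " tries")
      anchor <- oxygens[sample.int(placed, 1), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      d <- stats::runif(1, min_oo, max_oo)
      o_new <- anchor + d * dir
      d_oo <- sqrt(rowSums(sweep(oxygens[seq_len(placed), , drop = FALSE], 2, o_new)^2))
      if (any(d_oo < min_oo)) next
      cand <- t(random_rotation() %*% t(mono)) + rep(o_new, each = 3)
      dmin <- min(apply(cand, 1, function(p)
        min(sqrt(rowSums(sweep(coords, 2, p)^2)))))
      if (dmin < 1.5) next
      placed <- placed + 1L
      oxygens[placed, ] <- o_new
      coords <- rbind(coords, cand)
    }
    coords
  })
}

#' Generate an analytic Gaussian toy cluster with its mock backend
#'
#' Each fragment is a single pseudo-atom carrying `q` electrons as one
#' normalized s-Gaussian (nuclear charge equal to `q`, so fragments are
#' neutral), served by the closed-form [mock_backend()]. Positions may be
#' given explicitly or are drawn at random within a cube.
#'
#' @param n_fragments fragment count
#' @param positions optional n x 3 matrix, Bohr; random in a cube of side
#'   `4 * n_fragments^(1/3) + 4` Bohr otherwise, with a minimum separation of
#'   2 Bohr
#' @param q electrons per fragment (recycled); must match an element's
#'   nuclear charge
#' @param alphas Gaussian exponents (recycled)
#' @param A,B,t3 energy-model parameters of [mock_backend()]
#' @param seed RNG seed for random positions
#' @return list with `cluster` (a `cluster_system`) and `backend` (the
#'   matching `mock_backend`)
#' @export
make_gaussian_toy <- function(n_fragments, positions = NULL, q = 2,
                              alphas = 1.0, A = 0.1, B = 0.05, t3 = 0,
                              seed = 1) {
  q <- rep_len(as.integer(q), n_fragments)
  if (is.null(positions)) {
    side <- 4 * n_fragments^(1 / 3) + 4
    positions <- with_seed(seed, {
      pos <- matrix(NA_real_, n_fragments, 3)
      pos[1, ] <- stats::runif(3, 0, side)
      placed <- 1L
      tries <- 0L
      while (placed < n_fragments) {
        tries <- tries + 1L
        if (tries > 10000) stop("could not place toy fragments")
        p <- stats::runif(3, 0, side)
        if (min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2, p)^2))) < 2)
          next
        placed <- placed + 1L
        pos[placed, ] <- p
      }
      pos
    })
  }
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == n_fragments)
  if (any(stats::dist(positions) < 1e-8)) stop("duplicate fragment positions")
  elements <- .element_table$symbol[match(q, .element_table$z)]
  if (anyNA(elements)) stop("no element with nuclear charge ", q[is.na(elements)][1])
  cluster <- cluster_system(elements, positions, seq_len(n_fragments),
                            name = sprintf("gaussian_toy%d", n_fragments))
  list(cluster = cluster,
       backend = mock_backend(cluster, alphas = alphas, A = A, B = B, t3 = t3))
}
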