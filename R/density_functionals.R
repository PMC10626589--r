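## Semilocal (GGA) energy densities evaluated pointwise on the grid:
## the PW91k (LC94) gradient-corrected kinetic-energy functional and the PBE
## exchange-correlation functional, plus their gradient-free limits
## (Thomas-Fermi and the PW92 uniform gas). Closed-shell densities only.
## Implemented from the published parameterizations; an independent Python
## re-implementation under inst/oracles/ serves as the double-entry check in
## the tests.

C_TF <- 0.3 * (3 * pi^2)^(2 / 3)  # Thomas-Fermi constant, a.u.

#' Functional specification
#'
#' Names the semilocal functionals used for the nonadditive kinetic and
#' exchange-correlation terms of the density-based correction, and the
#' density clamp threshold applied before evaluating them on signed
#' (expanded) densities.
#'
#' @param kinetic kinetic functional: `"PW91k"` (default) or `"TF"`
#' @param xc exchange-correlation functional: `"PBE"` (default) or `"LDA"`
#' @param clamp densities below this (a.u.) are set to zero, with their
#'   gradients, before functional evaluation; semilocal functionals are
#'   undefined for negative density and an expanded density is a signed sum
#' @return a `functional_spec`
#' @export
functional_spec <- function(kinetic = "PW91k", xc = "PBE", clamp = 1e-10) {
  kinetic <- match.arg(toupper(kinetic), c("PW91K", "TF"))
  xc <- match.arg(toupper(xc), c("PBE", "LDA"))
  structure(list(kinetic = kinetic, xc = xc, clamp = clamp),
            class = "functional_spec")
}

clamp_density <- function(rho, sigma, clamp) {
  bad <- !is.finite(rho) | rho < clamp
  rho[bad] <- 0
  sigma[bad] <- 0
  sigma[sigma < 0] <- 0
  list(rho = rho, sigma = sigma)
}

# PW91k / LC94 enhancement factor over Thomas-Fermi,
# s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))
pw91k_enhancement <- function(s) {
  A1 <- 0.093907; A2 <- 0.26608; A3 <- 0.0809615
  A4 <- 100; A <- 76.32; B1 <- 0.000057767
  as_ <- A1 * s * asinh(A * s)
  num <- 1 + as_ + (A2 - A3 * exp(-A4 * s^2)) * s^2
  den <- 1 + as_ + B1 * s^4
  num / den
}

#' Kinetic-energy density of a semilocal functional
#'
#' Thomas-Fermi `C_TF rho^(5/3)` times, for PW91k, the LC94 enhancement
#' factor `F(s)` of the reduced gradient `s`. Vectorized over points.
#'
#' @param rho density values (a.u.), already clamped nonnegative
#' @param sigma contracted gradient `|grad rho|^2` (a.u.)
#' @param spec a [functional_spec()]
#' @return kinetic energy density per point (a.u.)
#' @export
kinetic_energy_density <- function(rho, sigma, spec = functional_spec()) {
  tau <- C_TF * rho^(5 / 3)
  if (spec$kinetic == "TF") return(tau)
  pos <- rho > 0
  s <- numeric(length(rho))
  s[pos] <- sqrt(sigma[pos]) / (2 * (3 * pi^2)^(1 / 3) * rho[pos]^(4 / 3))
  tau[pos] <- tau[pos] * pw91k_enhancement(s[pos])
  tau
}

# PW92 uniform-gas correlation energy per particle, unpolarized (zeta = 0)
pw92_ec_unpol <- function(rs) {
  A <- 0.0310907; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  q0 <- -2 * A * (1 + a1 * rs)
  srs <- sqrt(rs)
  q1 <- 2 * A * (b1 * srs + b2 * rs + b3 * rs * srs + b4 * rs^2)
  q0 * log(1 + 1 / q1)
}

pbe_exchange_density <- function(rho, sigma) {
  # epsilon_x^LDA * F_x(s) * rho
  kappa <- 0.804; mu <- 0.2195149727645171
  ex_lda <- -(3 / 4) * (3 / pi)^(1 / 3) * rho^(1 / 3)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  s2 <- sigma / (4 * kf^2 * rho^2)
  Fx <- 1 + kappa - kappa / (1 + mu * s2 / kappa)
  ex_lda * Fx * rho
}

pbe_correlation_density <- function(rho, sigma) {
  beta <- 0.06672455060314922
  gamma <- (1 - log(2)) / pi^2
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  ec <- pw92_ec_unpol(rs)
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks <- sqrt(4 * kf / pi)
  t2 <- sigma / (4 * ks^2 * rho^2)
  expfac <- exp(-ec / gamma)
  Aa <- (beta / gamma) / (expfac - 1)
  # limit A -> infinity as ec -> 0-: H -> 0 there; guard the division
  Aa[!is.finite(Aa)] <- 1e30
  num <- 1 + Aa * t2
  den <- 1 + Aa * t2 + Aa^2 * t2^2
  H <- gamma * log(1 + (beta / gamma) * t2 * num / den)
  (ec + H) * rho
}

#' Exchange-correlation energy density
#'
#' PBE exchange plus PBE correlation (PW92 uniform-gas limit at zero
#' gradient), per grid point; `"LDA"` drops both gradient corrections.
#'
#' @inheritParams kinetic_energy_density
#' @return xc energy density per point (a.u.)
#' @export
xc_energy_density <- function(rho, sigma, spec = functional_spec()) {
  out <- numeric(length(rho))
  pos <- rho > 0
  if (!any(pos)) return(out)
  r <- rho[pos]
  sg <- if (spec$xc == "LDA") numeric(length(r)) else sigma[pos]
  out[pos] <- pbe_exchange_density(r, sg) + pbe_correlation_density(r, sg)
  out
}

#' Integrated semilocal functional of a field
#'
#' Quadrature of the selected energy density over a (possibly signed, then
#' clamped) density and gradient on the shared grid.
#'
#' @param grid an `integration_grid`
#' @param field a `field_on_grid` or `expanded_field`
#' @param spec a [functional_spec()]
#' @param which `"kinetic"` or `"xc"`
#' @return energy in Hartree
#' @export
functional_energy <- function(grid, field, spec = functional_spec(),
                              which = c("kinetic", "xc")) {
  which <- match.arg(which)
  if (is.null(field$grad)) stop("field carries no density gradient")
  sigma <- rowSums(field$grad^2)
  cl <- clamp_density(field$rho, sigma, spec$clamp)
  ed <- if (which == "kinetic") kinetic_energy_density(cl$rho, cl$sigma, spec)
        else xc_energy_density(cl$rho, cl$sigma, spec)
  integrate_grid(grid, ed)
}
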