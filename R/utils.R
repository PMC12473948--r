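# Shared constants and small numeric helpers.

# Molarity of pure n-octanol: density 0.8262 g/cm^3 over 130.23 g/mol.
OCTANOL_MOLARITY <- 6.344

# Gas constant, J mol^-1 K^-1, as used in the log K_OA relation.
GAS_CONSTANT_J <- 8.314

# Boltzmann constant in kcal mol^-1 K^-1 (molar form), for the Monte Carlo toy.
KB_KCAL <- 1.987204e-3

KCAL_TO_KJ <- 4.184

# Standard atomic masses, g/mol, for mass-weighted centroids.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used for all percentages and reported concentrations in this package),
#' unlike [round()], which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(41.15, 1)  # 41.2
#' round_half_up(0.01875, 3)  # 0.019
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # nudge by a relative epsilon so values that are exact halves in decimal but
  # land just below .5 in binary (e.g. 0.01875 * 1000 = 18.74999...) round up
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# internal: stop with a formatted message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize a 3-vector; error on zero length
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("cannot normalize a zero-length vector")
  v / n
}

# rotation matrix mapping the z axis onto unit vector `n`
rotation_to <- function(n) {
  n <- unit3(n)
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2], z[3] * n[1] - z[1] * n[3], z[1] * n[2] - z[2] * n[1])
  c_ <- sum(z * n)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# uniformly random unit vector (uses the current RNG stream)
random_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}
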