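#' Stock analytic energy landscapes
#'
#' Builds a single-particle [particle_system()] living on an analytic
#' surface with known energetics, used as the desk-scale stand-in for a
#' rugged biomolecular energy surface when validating enhanced-sampling
#' machinery.
#'
#' * `"double_well_1d"` — `V(x) = a * (x^2 - b)^2` along x (y, z are held
#'   by stiff tethers): wells at `x = +/- sqrt(b)`, barrier `a * b^2` at
#'   `x = 0`.
#' * `"mueller_brown_2d"` — the classical Mueller-Brown surface in the
#'   x-y plane (z tethered), a standard three-minimum test surface for
#'   sampling methods.
#'
#' The returned system carries an `analytic` field with the energy,
#' gradient and — for the 1D double well — the Boltzmann density
#' `density(x, temperature)` and the partition-normalised free-energy
#' profile, so tests can use closed-form oracles.
#'
#' @param kind `"double_well_1d"` or `"mueller_brown_2d"`.
#' @param a,b double-well parameters (barrier `a*b^2` must be > 0).
#' @param confine_kappa tether stiffness holding the unused axes.
#' @return a one-particle `particle_system` with an `analytic` field.
#' @examples
#' sys <- make_analytic_landscape("double_well_1d", a = 1, b = 1)
#' sys$analytic$energy(c(0, 0, 0)) # barrier top = a * b^2 = 1
#' @export
make_analytic_landscape <- function(kind = c("double_well_1d",
                                             "mueller_brown_2d"),
                                    a = 1, b = 1, confine_kappa = 100) {
  kind <- match.arg(kind)
  sys <- particle_system(1)
  if (kind == "double_well_1d") {
    if (a * b^2 <= 0) stop("barrier height a*b^2 must be > 0", call. = FALSE)
    sys <- add_double_well(sys, 1, axis = 1, a = a, b = b)
    sys <- add_tether(sys, 1, kappa = c(0, confine_kappa, confine_kappa),
                      ref = c(0, 0, 0))
    energy <- function(x) a * (x[1]^2 - b)^2
    gradient <- function(x) c(4 * a * x[1] * (x[1]^2 - b), 0, 0)
    density <- function(x, temperature) {
      v <- a * (x^2 - b)^2
      z <- stats::integrate(function(u) exp(-a * (u^2 - b)^2 / temperature),
                            -Inf, Inf)$value
      exp(-v / temperature) / z
    }
    sys$analytic <- list(
      kind = kind, energy = energy, gradient = gradient,
      minima = cbind(x = c(-sqrt(b), sqrt(b)), y = 0, z = 0),
      barrier = a * b^2, density = density
    )
  } else {
    mb <- .mueller_brown()
    sys <- add_landscape_term(sys, 1, "mueller_brown", mb$energy, mb$gradient)
    sys <- add_tether(sys, 1, kappa = c(0, 0, confine_kappa), ref = c(0, 0, 0))
    sys$analytic <- list(kind = kind, energy = mb$energy,
                         gradient = mb$gradient, starts = mb$starts)
  }
  sys <- set_labels(sys, walker = 1)
  sys
}

# Mueller-Brown potential with the standard parameterisation
.mueller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7)
  bb <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    sum(A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2))
  }
  gradient <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    e <- A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2)
    c(sum(e * (2 * aa * dx + bb * dy)), sum(e * (bb * dx + 2 * cc * dy)), 0)
  }
  # conventional starting points near the three minima
  starts <- cbind(x = c(-0.55, 0.6, -0.05), y = c(1.45, 0.03, 0.47))
  list(energy = energy, gradient = gradient, starts = starts)
}
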