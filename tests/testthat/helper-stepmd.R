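# central-difference gradient oracle shared across force tests
fd_forces <- function(system, coords, h = 1e-5) {
  n <- nrow(coords)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (ax in 1:3) {
      xp <- coords; xp[i, ax] <- xp[i, ax] + h
      xm <- coords; xm[i, ax] <- xm[i, ax] - h
      out[i, ax] <- -(compute_forces(system, xp)$energy -
                        compute_forces(system, xm)$energy) / (2 * h)
    }
  }
  out
}

expect_forces_match_fd <- function(system, coords, tol = 1e-5) {
  analytic <- compute_forces(system, coords)$forces
  fd <- fd_forces(system, coords)
  scale <- max(1, max(abs(analytic)))
  expect_lt(max(abs(analytic - fd)) / scale, tol)
}

# a small mixed-term system exercising every force-field term family
make_mixed_system <- function() {
  sys <- particle_system(4, masses = c(1, 2, 1.5, 1))
  sys <- add_bond(sys, 1, 2, kappa = 3, r0 = 1.2)
  sys <- add_tether(sys, 3, kappa = c(2, 0.5, 1), ref = c(0.2, -0.1, 0.4))
  sys <- add_double_well(sys, 4, axis = 2, a = 0.8, b = 1.5, center = 0.3)
  sys <- add_pair(sys, 1, 3, eps = 0.7, sigma = 0.9, cutoff = 3,
                  style = "lj")
  sys <- add_pair(sys, 2, 4, eps = 1.1, sigma = 0.4, cutoff = 2.5,
                  style = "gauss", r0 = 1.3)
  sys
}

mixed_coords <- function(seed = 1) {
  set.seed(seed)
  matrix(rnorm(12, sd = 0.8), 4, 3) +
    matrix(c(0, 1.2, 0.3, -0.6), 4, 3)[, c(1, 1, 1)] * 0.5
}

# a two-bead system whose progress metric equals the bead distance
metric_probe_system <- function(d) {
  sys <- particle_system(2)
  sys <- set_labels(sys, scissile = 1, cat1 = 2)
  sys$coords_at <- function(dist) rbind(c(0, 0, 0), c(dist, 0, 0))
  sys
}

single_pair_spec <- function() progress_metric_spec(list(c("scissile", "cat1")))

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}
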