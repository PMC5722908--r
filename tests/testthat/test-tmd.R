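test_that("the steering energy follows the N-scaled spring form", {
  # 100 targeted atoms displaced rigidly by 5 along z, fit pinned on a
  # separate scaffold: measured RMSD is exactly 5
  set.seed(11)
  n_t <- 100
  target_t <- matrix(rnorm(3 * n_t, sd = 3), n_t, 3)
  scaffold <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(5, 5, 0))
  target_full <- rbind(scaffold, target_t)
  coords <- target_full
  coords[5:(n_t + 4), 3] <- coords[5:(n_t + 4), 3] + 5
  sys <- particle_system(n_t + 4)
  tp <- tmd_params(k = 0.25, targeted_indices = 5:(n_t + 4),
                   target_coords = target_full, fit_indices = 1:4,
                   schedule = list(t_start = 0, t_end = 10,
                                   rmsd_initial = 5, rmsd_final = 3))
  ev <- tmd_energy_forces(sys, coords, t = 10, tp) # RMSD* = 3
  expect_equal(ev$rmsd, 5, tolerance = 1e-9)
  expect_equal(ev$energy, 0.5 * (0.25 / 100) * (5 - 3)^2, tolerance = 1e-9)
  # k_per_atom convenience: k = 0.25 * N
  tp2 <- tmd_params(k_per_atom = 0.25, targeted_indices = 5:(n_t + 4),
                    target_coords = target_full, fit_indices = 1:4,
                    schedule = list(t_start = 0, t_end = 10,
                                    rmsd_initial = 5, rmsd_final = 3))
  expect_equal(tp2$k, 0.25 * 100)
})

test_that("zero steering gap gives zero energy and forces", {
  set.seed(12)
  X <- matrix(rnorm(18), 6, 3)
  sys <- particle_system(6)
  tp <- tmd_params(k = 2, targeted_indices = 1:6, target_coords = X,
                   schedule = list(t_start = 0, t_end = 1,
                                   rmsd_initial = 0, rmsd_final = 0))
  ev <- tmd_energy_forces(sys, X, 0.5, tp)
  expect_equal(ev$rmsd, 0, tolerance = 1e-9)
  expect_equal(ev$energy, 0)
  expect_equal(ev$forces, matrix(0, 6, 3))
})

test_that("the schedule is linear inside and clamped outside", {
  tp <- tmd_params(k = 1, targeted_indices = 1:3,
                   target_coords = diag(3),
                   schedule = list(t_start = 2, t_end = 12,
                                   rmsd_initial = 10, rmsd_final = 4))
  expect_equal(tmd_reference_rmsd(tp, -5), 10)
  expect_equal(tmd_reference_rmsd(tp, 2), 10)
  expect_equal(tmd_reference_rmsd(tp, 7), 7)
  expect_equal(tmd_reference_rmsd(tp, 12), 4)
  expect_equal(tmd_reference_rmsd(tp, 99), 4)
  expect_error(
    tmd_params(k = 1, targeted_indices = 1:3, target_coords = diag(3),
               schedule = list(t_start = 3, t_end = 1, rmsd_initial = 1,
                               rmsd_final = 0)), "t_end")
  expect_error(
    tmd_params(k = 1, targeted_indices = 1:3, target_coords = diag(3),
               schedule = list(t_start = 0, t_end = 1, rmsd_initial = 1,
                               rmsd_final = 2)), "rmsd_initial")
})

test_that("steering forces match finite differences of the potential", {
  set.seed(13)
  n <- 7
  target <- matrix(rnorm(3 * n), n, 3)
  sys <- particle_system(n, masses = runif(n, 0.5, 2))
  for (weights in list("uniform", "mass")) {
    tp <- tmd_params(k = 1.7, targeted_indices = 2:6,
                     target_coords = target, weights = weights,
                     schedule = list(t_start = 0, t_end = 1,
                                     rmsd_initial = 2, rmsd_final = 1))
    coords <- target + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    ev <- tmd_energy_forces(sys, coords, 0.4, tp)
    h <- 1e-6
    fd <- matrix(0, n, 3)
    for (i in seq_len(n)) for (ax in 1:3) {
      xp <- coords; xp[i, ax] <- xp[i, ax] + h
      xm <- coords; xm[i, ax] <- xm[i, ax] - h
      fd[i, ax] <- -(tmd_energy_forces(sys, xp, 0.4, tp)$energy -
                       tmd_energy_forces(sys, xm, 0.4, tp)$energy) / (2 * h)
    }
    expect_lt(max(abs(ev$forces - fd)), 1e-5 * max(1, max(abs(fd))))
    expect_equal(ev$forces[c(1, 7), ], matrix(0, 2, 3)) # only targeted
  }
})

test_that("positional restraints are harmonic with analytic forces", {
  ref <- matrix(0, 3, 3)
  sys <- particle_system(3)
  r <- positional_restraint(1:3, k_restraint = 0.1, reference = ref)
  at_ref <- restraint_energy_forces(sys, ref, r)
  expect_equal(at_ref$energy, 0)
  expect_equal(at_ref$forces, matrix(0, 3, 3))
  x <- ref; x[2, ] <- c(1, 0, 0)
  ev <- restraint_energy_forces(sys, x, r)
  expect_equal(ev$energy, 0.05)
  expect_equal(ev$forces[2, ], c(-0.1, 0, 0))
  # finite differences
  set.seed(14)
  x2 <- matrix(rnorm(9), 3, 3)
  ev2 <- restraint_energy_forces(sys, x2, r)
  h <- 1e-6
  for (i in 1:3) for (ax in 1:3) {
    xp <- x2; xp[i, ax] <- xp[i, ax] + h
    xm <- x2; xm[i, ax] <- xm[i, ax] - h
    fd <- -(restraint_energy_forces(sys, xp, r)$energy -
              restraint_energy_forces(sys, xm, r)$energy) / (2 * h)
    expect_equal(ev2$forces[i, ax], fd, tolerance = 1e-6)
  }
  expect_warning(positional_restraint(1:2, 0.1, ref[1:2, ],
                                      targeted_indices = 2:3), "overlap")
})

test_that("a stiff steering spring tracks the scheduled RMSD", {
  # strongly-sprung steering on the reduced docking fixture: the
  # time-averaged tracking error stays well inside the schedule sweep
  sys <- make_domain_docking_model()
  tp <- tmd_params(k_per_atom = 20, targeted_indices = 9:14,
                   target_coords = sys$poses$docked, fit_indices = 1:8,
                   schedule = list(t_start = 0, t_end = 30,
                                   rmsd_initial = 3.508, rmsd_final = 0.5))
  p <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                     n_steps = 3000, save_interval = 10, seed = 21)
  traj <- run_md(sys, p, biases = tmd_bias(tp),
                 initial = sys$poses$undocked)
  s <- tmd_rmsd_series(traj)
  expect_lt(mean(abs(s$rmsd - s$rmsd_target)), 0.3)
  expect_lt(tail(s$rmsd, 1), 1.2)
})
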