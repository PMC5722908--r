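#' Engine parameters for a Langevin dynamics run
#'
#' @param dt integration time step, > 0.
#' @param temperature target thermal energy kB·T (in the system's energy
#'   units; use [thermal_energy()] for kelvin in physical mode). >= 0.
#' @param friction Langevin collision rate (1/time), >= 0. With
#'   `friction = 0` and `temperature = 0` the integrator reduces to
#'   velocity Verlet (NVE).
#' @param n_steps number of integration steps, >= 0.
#' @param save_interval store a frame every this many steps (frame 0, the
#'   initial state, is always stored).
#' @param seed RNG seed for the thermostat noise and velocity draws.
#' @param explode_bound potential energy above which the run is aborted
#'   with an integration-failure error (a time step too large for the
#'   stiffest term shows up this way).
#' @return an object of class `engine_params`.
#' @export
engine_params <- function(dt, temperature = 1, friction = 1,
                          n_steps = 1000L, save_interval = 10L,
                          seed = 1L, explode_bound = 1e8) {
  stopifnot(dt > 0, temperature >= 0, friction >= 0, n_steps >= 0,
            save_interval >= 1, explode_bound > 0)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), explode_bound = explode_bound),
            class = "engine_params")
}

#' Construct a single trajectory frame
#'
#' @param time simulation time of the frame.
#' @param coords `n x 3` coordinate matrix (finite).
#' @param velocities optional `n x 3` velocity matrix.
#' @param potential_energy optional scalar potential energy.
#' @param bias_values optional named numeric vector of per-channel bias
#'   energies ΔV.
#' @return an object of class `md_frame`.
#' @export
md_frame <- function(time, coords, velocities = NULL,
                     potential_energy = NA_real_, bias_values = NULL) {
  coords <- .as_coords(coords)
  if (any(!is.finite(coords))) stop("frame coords must be finite", call. = FALSE)
  if (!is.null(velocities)) {
    velocities <- .as_coords(velocities)
    if (!all(dim(velocities) == dim(coords))) {
      stop("velocities must match coords shape", call. = FALSE)
    }
  }
  structure(list(time = time, coords = coords, velocities = velocities,
                 potential_energy = potential_energy,
                 bias_values = bias_values),
            class = "md_frame")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param system a [particle_system()].
#' @param temperature thermal energy kB·T.
#' @return `n x 3` velocity matrix with per-component variance `kB·T/m`.
#' @export
draw_velocities <- function(system, temperature) {
  stopifnot(inherits(system, "particle_system"), temperature >= 0)
  n <- system$n_particles
  matrix(stats::rnorm(3 * n, sd = rep(sqrt(temperature / system$masses), 3)),
         n, 3)
}

# Dispatch point for bias potentials: returns list(forces, dv) where
# `forces` is the additive force correction and `dv` a named vector of
# bias energies per channel. `base` is the unbiased compute_forces() result.
bias_contribution <- function(bias, system, coords, t, base) {
  UseMethod("bias_contribution")
}

#' @export
bias_contribution.default <- function(bias, system, coords, t, base) {
  stop("not a bias object: ", paste(class(bias), collapse = "/"),
       call. = FALSE)
}

#' Run Langevin (BAOAB) dynamics
#'
#' Integrates the system with the BAOAB splitting of Langevin dynamics,
#' applying any bias potentials (accelerated-MD boost, targeted-MD
#' steering, positional restraints) on top of the system forces. With
#' `friction = 0` and `temperature = 0` the scheme reduces to velocity
#' Verlet and conserves energy. Runs are bit-reproducible for a fixed
#' seed.
#'
#' @param system a [particle_system()].
#' @param params an [engine_params()].
#' @param biases list of bias objects ([amd_bias()], [tmd_bias()],
#'   [positional_restraint()]).
#' @param initial an [md_frame()] (or bare `n x 3` coordinate matrix) to
#'   start from. Missing velocities are drawn from the Maxwell-Boltzmann
#'   distribution at `params$temperature`.
#' @param start_time time assigned to the initial frame.
#' @return an object of class `md_trajectory`: saved times, coordinates,
#'   potential energies and per-channel bias energies ΔV, sampled every
#'   `params$save_interval` steps (the initial state is frame 1).
#' @export
run_md <- function(system, params, biases = list(), initial,
                   start_time = 0) {
  stopifnot(inherits(system, "particle_system"),
            inherits(params, "engine_params"))
  if (inherits(initial, "md_frame")) {
    coords <- initial$coords
    velocities <- initial$velocities
  } else {
    coords <- .as_coords(initial, system$n_particles)
    velocities <- NULL
  }
  coords <- .as_coords(coords, system$n_particles)
  if (inherits(biases, c("amd_bias", "tmd_bias", "restraint_bias"))) {
    biases <- list(biases)
  }
  set.seed(params$seed)
  if (is.null(velocities)) {
    velocities <- draw_velocities(system, params$temperature)
  }
  system <- .compile_terms(system)
  n <- system$n_particles
  m <- system$masses
  dt <- params$dt
  c1 <- exp(-params$friction * dt)
  c2 <- sqrt((1 - c1^2) * params$temperature / m) # per-particle sd factor
  eval_all <- function(coords, t) {
    base <- compute_forces_core(system, coords)
    f <- base$forces
    dv <- numeric(0)
    for (b in biases) {
      contrib <- bias_contribution(b, system, coords, t, base)
      f <- f + contrib$forces
      dv <- c(dv, contrib$dv)
    }
    list(energy = base$energy, forces = f, dv = dv)
  }

  t0 <- start_time
  ev <- eval_all(coords, t0)
  n_saved <- params$n_steps %/% params$save_interval + 1L
  times <- numeric(n_saved)
  coords_arr <- array(NA_real_, c(n, 3, n_saved))
  vel_arr <- array(NA_real_, c(n, 3, n_saved))
  energy <- numeric(n_saved)
  bias_mat <- matrix(NA_real_, n_saved, length(ev$dv),
                     dimnames = list(NULL, names(ev$dv)))
  save_frame <- function(k, t, ev, coords, velocities) {
    times[k] <<- t
    coords_arr[, , k] <<- coords
    vel_arr[, , k] <<- velocities
    energy[k] <<- ev$energy
    if (ncol(bias_mat)) bias_mat[k, ] <<- ev$dv
  }
  save_frame(1L, t0, ev, coords, velocities)
  k <- 1L
  for (step in seq_len(params$n_steps)) {
    # B: half kick
    velocities <- velocities + (dt / 2) * ev$forces / m
    # A: half drift
    coords <- coords + (dt / 2) * velocities
    # O: Ornstein-Uhlenbeck
    if (params$friction > 0) {
      velocities <- c1 * velocities +
        c2 * matrix(stats::rnorm(3 * n), n, 3)
    }
    # A: half drift
    coords <- coords + (dt / 2) * velocities
    # B: half kick with fresh forces
    t_now <- t0 + step * dt
    ev <- eval_all(coords, t_now)
    if (!is.finite(ev$energy) || ev$energy > params$explode_bound) {
      stop(sprintf(
        "integration failure at step %d: potential energy %g exceeds bound %g (reduce dt)",
        step, ev$energy, params$explode_bound), call. = FALSE)
    }
    velocities <- velocities + (dt / 2) * ev$forces / m
    if (step %% params$save_interval == 0L) {
      k <- k + 1L
      save_frame(k, t_now, ev, coords, velocities)
    }
  }
  new_md_trajectory(
    times = times[seq_len(k)],
    coords = coords_arr[, , seq_len(k), drop = FALSE],
    energy = energy[seq_len(k)],
    bias = bias_mat[seq_len(k), , drop = FALSE],
    velocities = vel_arr[, , seq_len(k), drop = FALSE],
    final_velocities = velocities,
    system = system,
    metadata = list(seed = params$seed, params = params,
                    n_biases = length(biases))
  )
}

#' Assemble a trajectory from frames
#'
#' Builds an `md_trajectory` from a list of [md_frame()] objects (all with
#' the same particle count, strictly increasing times). Useful for
#' constructing synthetic trajectories in analyses and tests; [run_md()]
#' produces trajectories directly.
#'
#' @param frames list of [md_frame()] objects (may be empty if
#'   `n_particles` is given).
#' @param system optional [particle_system()] to attach.
#' @param n_particles particle count, required when `frames` is empty.
#' @return an `md_trajectory`.
#' @export
md_trajectory <- function(frames = list(), system = NULL,
                          n_particles = NULL) {
  if (length(frames) == 0) {
    np <- if (!is.null(system)) system$n_particles else n_particles
    if (is.null(np)) stop("empty trajectory needs n_particles",
                          call. = FALSE)
    return(new_md_trajectory(numeric(0), array(0, c(np, 3, 0)), numeric(0),
                             matrix(0, 0, 0), system))
  }
  stopifnot(all(vapply(frames, inherits, logical(1), "md_frame")))
  np <- nrow(frames[[1]]$coords)
  if (!all(vapply(frames, function(f) nrow(f$coords), integer(1)) == np)) {
    stop("all frames must have the same particle count", call. = FALSE)
  }
  nf <- length(frames)
  coords <- array(NA_real_, c(np, 3, nf))
  for (i in seq_len(nf)) coords[, , i] <- frames[[i]]$coords
  dv_names <- names(frames[[1]]$bias_values)
  bias <- if (length(dv_names)) {
    do.call(rbind, lapply(frames, function(f) f$bias_values[dv_names]))
  } else {
    matrix(0, nf, 0)
  }
  if (length(dv_names)) colnames(bias) <- dv_names
  new_md_trajectory(
    times = vapply(frames, function(f) f$time, numeric(1)),
    coords = coords,
    energy = vapply(frames, function(f) f$potential_energy, numeric(1)),
    bias = bias, system = system)
}

new_md_trajectory <- function(times, coords, energy, bias, system,
                              metadata = list(), velocities = NULL,
                              final_velocities = NULL) {
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, coords = coords, energy = energy,
                 bias = bias, velocities = velocities,
                 final_velocities = final_velocities,
                 system = system, metadata = metadata),
            class = "md_trajectory")
}

#' Number of frames in a trajectory
#' @param trajectory an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  length(trajectory$times)
}

#' Extract one frame of a trajectory
#'
#' @param trajectory an `md_trajectory`.
#' @param i frame index (1-based).
#' @return an [md_frame()].
#' @export
traj_frame <- function(trajectory, i) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  i <- as.integer(i)
  if (i < 1 || i > n_frames(trajectory)) stop("frame index out of range",
                                              call. = FALSE)
  bias <- if (ncol(trajectory$bias)) trajectory$bias[i, ] else NULL
  vel <- if (!is.null(trajectory$velocities)) {
    .as_coords(trajectory$velocities[, , i])
  }
  md_frame(trajectory$times[i], trajectory$coords[, , i],
           velocities = vel,
           potential_energy = trajectory$energy[i], bias_values = bias)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames, ",
      dim(x$coords)[1], " particles, t = [",
      format(x$times[1]), ", ", format(x$times[length(x$times)]), "]\n",
      sep = "")
  if (ncol(x$bias)) {
    cat("  bias channels: ", paste(colnames(x$bias), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Convert a trajectory to a tidy tibble
#'
#' One row per frame and particle, with columns `frame`, `time`,
#' `particle`, `x`, `y`, `z`, `potential_energy` and one `dv_*` column per
#' bias channel.
#'
#' @param x an `md_trajectory`.
#' @param ... unused.
#' @return a tibble.
#' @export
as_tibble.md_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  np <- dim(x$coords)[1]
  xs <- as.vector(x$coords[, 1, ])
  ys <- as.vector(x$coords[, 2, ])
  zs <- as.vector(x$coords[, 3, ])
  pe <- rep(x$energy, each = np)
  tm <- rep(x$times, each = np)
  out <- tibble::tibble(
    frame = rep(seq_len(nf), each = np),
    time = tm,
    particle = rep(seq_len(np), nf),
    x = xs, y = ys, z = zs,
    potential_energy = pe
  )
  if (ncol(x$bias)) {
    for (ch in colnames(x$bias)) {
      out[[paste0("dv_", ch)]] <- rep(x$bias[, ch], each = np)
    }
  }
  out
}

# deterministic seed derivation for replica streams: a small multiplicative
# hash keeping results in [1, 2^31 - 2]
derive_seed <- function(master_seed, ...) {
  parts <- c(master_seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}
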