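#' Targeted-MD steering parameters
#'
#' The steering potential is `U = 0.5 * (k / N) * (RMSD(t) - RMSD*(t))^2`,
#' where `RMSD(t)` is the instantaneous best-fit (optionally
#' mass-weighted) RMSD of the targeted atoms from the target coordinates,
#' `N` the number of targeted atoms (the spring constant is scaled down by
#' `N`), and the reference `RMSD*(t)` decreases linearly from
#' `rmsd_initial` at `t_start` to `rmsd_final` at `t_end`. Outside the
#' schedule the reference is clamped to the nearest endpoint, so a run
#' extended past `t_end` relaxes against a constant target.
#'
#' @param k spring constant (energy/length^2). Alternatively give
#'   `k_per_atom`, the per-targeted-atom constant (so `k = k_per_atom *
#'   N`), which is how such constants are usually quoted.
#' @param targeted_indices indices of the atoms steered (N >= 3).
#' @param target_coords `N x 3` target coordinates for the targeted atoms
#'   (or full-system matrix, subset internally).
#' @param schedule list with `t_start`, `t_end`, `rmsd_initial`,
#'   `rmsd_final` (`t_end > t_start`, `rmsd_initial >= rmsd_final >= 0`).
#' @param weights `"uniform"`, `"mass"` (mass-weighted RMSD), or a numeric
#'   vector of per-atom weights.
#' @param k_per_atom optional per-atom spring constant, used when `k` is
#'   missing.
#' @param fit_indices atoms used for the best-fit superposition before the
#'   RMSD is measured. Defaults to the targeted atoms themselves (the
#'   classic self-fit formulation). Steering a rigidly moving domain needs
#'   a fit on a *different* selection (e.g. the scaffold), otherwise the
#'   superposition absorbs the domain displacement; this mirrors steering
#'   one domain while aligning on the rest of the structure. When
#'   `fit_indices` differ from the targeted set, `target_coords` must be a
#'   full-system matrix.
#' @return an object of class `tmd_params`.
#' @export
tmd_params <- function(k = NULL, targeted_indices, target_coords, schedule,
                       weights = "uniform", k_per_atom = NULL,
                       fit_indices = NULL) {
  targeted_indices <- as.integer(targeted_indices)
  N <- length(targeted_indices)
  if (N < 3) stop("need at least 3 targeted atoms", call. = FALSE)
  if (anyDuplicated(targeted_indices)) {
    stop("targeted indices must be unique", call. = FALSE)
  }
  if (is.null(k)) {
    if (is.null(k_per_atom)) stop("give k or k_per_atom", call. = FALSE)
    k <- k_per_atom * N
  }
  stopifnot(k > 0)
  target_coords <- .as_coords(target_coords)
  if (!is.null(fit_indices)) {
    fit_indices <- as.integer(fit_indices)
    if (length(fit_indices) < 3) {
      stop("need at least 3 fit atoms", call. = FALSE)
    }
    if (nrow(target_coords) < max(fit_indices, targeted_indices)) {
      stop("target_coords must be full-system when fit_indices are given",
           call. = FALSE)
    }
    target <- target_coords[targeted_indices, , drop = FALSE]
    fit_target <- target_coords[fit_indices, , drop = FALSE]
  } else {
    fit_target <- NULL
    if (nrow(target_coords) == N) {
      target <- target_coords
    } else if (nrow(target_coords) >= max(targeted_indices)) {
      target <- target_coords[targeted_indices, , drop = FALSE]
    } else {
      stop("target_coords must cover the targeted atoms", call. = FALSE)
    }
  }
  need <- c("t_start", "t_end", "rmsd_initial", "rmsd_final")
  if (!all(need %in% names(schedule))) {
    stop("schedule needs ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (schedule$t_end <= schedule$t_start) {
    stop("schedule requires t_end > t_start", call. = FALSE)
  }
  if (schedule$rmsd_final < 0 ||
      schedule$rmsd_initial < schedule$rmsd_final) {
    stop("schedule requires rmsd_initial >= rmsd_final >= 0", call. = FALSE)
  }
  structure(list(k = k, targeted_indices = targeted_indices, N = N,
                 target = target, schedule = schedule, weights = weights,
                 fit_indices = fit_indices, fit_target = fit_target),
            class = "tmd_params")
}

#' Scheduled reference RMSD at a given time
#'
#' @param params a [tmd_params()].
#' @param t time(s); clamped to the schedule window.
#' @return the linear reference `RMSD*(t)`.
#' @export
tmd_reference_rmsd <- function(params, t) {
  s <- params$schedule
  frac <- pmin(pmax((t - s$t_start) / (s$t_end - s$t_start), 0), 1)
  s$rmsd_initial + frac * (s$rmsd_final - s$rmsd_initial)
}

.tmd_weights <- function(params, system) {
  w <- params$weights
  if (is.character(w)) {
    if (w == "mass") return(system$masses[params$targeted_indices])
    if (w == "uniform") return(rep(1, params$N))
    stop("unknown weight mode: ", w, call. = FALSE)
  }
  w <- as.numeric(w)
  if (length(w) != params$N || any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative, length N, not all zero",
         call. = FALSE)
  }
  w
}

#' Evaluate the targeted-MD steering energy and forces
#'
#' Returns the steering energy and the forces on the full coordinate set
#' (zero on non-targeted atoms). The RMSD gradient retains only the
#' explicit coordinate dependence after the optimal superposition — the
#' rotation- and translation-gradient terms vanish at the optimum — which
#' makes the force exact at the best-fit point:
#' `F_i = -(k/N) * (RMSD - RMSD*) * w_i * (x_i - y_fit_i) / (RMSD * sum w)`.
#'
#' @param system a [particle_system()].
#' @param coords full `n x 3` coordinate matrix.
#' @param t current time (sets `RMSD*(t)`).
#' @param params a [tmd_params()].
#' @return list with `energy`, `forces` (`n x 3`), `rmsd` and
#'   `rmsd_target`.
#' @export
tmd_energy_forces <- function(system, coords, t, params) {
  stopifnot(inherits(params, "tmd_params"))
  coords <- .as_coords(coords, system$n_particles)
  idx <- params$targeted_indices
  X <- coords[idx, , drop = FALSE]
  w <- .tmd_weights(params, system)
  if (is.null(params$fit_indices)) {
    fit <- kabsch_superpose(X, params$target, weights = w)
    Y_fit <- fit$Y_fit
    R <- fit$rmsd
  } else {
    # align the target onto the current frame using the fit selection,
    # then measure the weighted RMSD of the targeted atoms only
    fit <- kabsch_superpose(coords[params$fit_indices, , drop = FALSE],
                            params$fit_target)
    Y_fit <- sweep(params$target %*% t(fit$rotation), 2, fit$translation,
                   FUN = "+")
    R <- sqrt(sum((w / sum(w)) * rowSums((X - Y_fit)^2)))
  }
  Rstar <- tmd_reference_rmsd(params, t)
  keff <- params$k / params$N
  gap <- R - Rstar
  energy <- 0.5 * keff * gap^2
  forces <- matrix(0, system$n_particles, 3)
  if (R > 1e-12) {
    grad_R <- (w / sum(w)) * (X - Y_fit) / R
    forces[idx, ] <- -keff * gap * grad_R
  }
  list(energy = energy, forces = forces, rmsd = R, rmsd_target = Rstar)
}

#' Create a targeted-MD bias for the dynamics engine
#'
#' @param params a [tmd_params()].
#' @return a bias object for [run_md()]. The steering energy is recorded
#'   per frame in bias channel `tmd`, and the instantaneous best-fit RMSD
#'   in channel `tmd_rmsd` (an observable, not an energy).
#' @export
tmd_bias <- function(params) {
  stopifnot(inherits(params, "tmd_params"))
  structure(list(params = params), class = "tmd_bias")
}

#' @export
bias_contribution.tmd_bias <- function(bias, system, coords, t, base) {
  ev <- tmd_energy_forces(system, coords, t, bias$params)
  list(forces = ev$forces,
       dv = c(tmd = ev$energy, tmd_rmsd = ev$rmsd,
              tmd_rmsd_target = ev$rmsd_target))
}

#' Harmonic positional restraint
#'
#' Per-atom harmonic wells `0.5 * k_restraint * |x_i - ref_i|^2` on a set
#' of atoms, the usual weak tether applied to low-fluctuation atoms
#' outside the steered selection to prevent whole-solute drift during
#' targeted runs.
#'
#' @param indices restrained atom indices.
#' @param k_restraint force constant (energy/length^2), e.g. 0.1
#'   kcal/mol/A^2 in physical mode.
#' @param reference reference coordinates (`length(indices) x 3`, or a
#'   full-system matrix subset internally).
#' @param targeted_indices optional steered selection; a warning is
#'   issued if the two sets overlap.
#' @return a bias object of class `restraint_bias` for [run_md()].
#' @export
positional_restraint <- function(indices, k_restraint, reference,
                                 targeted_indices = NULL) {
  indices <- as.integer(indices)
  stopifnot(length(indices) >= 1, k_restraint >= 0)
  reference <- .as_coords(reference)
  if (nrow(reference) != length(indices)) {
    if (nrow(reference) >= max(indices)) {
      reference <- reference[indices, , drop = FALSE]
    } else {
      stop("reference must cover the restrained atoms", call. = FALSE)
    }
  }
  if (!is.null(targeted_indices) &&
      length(intersect(indices, targeted_indices))) {
    warning("restrained and targeted selections overlap", call. = FALSE)
  }
  structure(list(indices = indices, k = k_restraint, reference = reference),
            class = "restraint_bias")
}

#' Evaluate a positional restraint
#'
#' @param system a [particle_system()].
#' @param coords full `n x 3` coordinate matrix.
#' @param restraint a [positional_restraint()].
#' @return list with `energy` and full-system `forces`.
#' @export
restraint_energy_forces <- function(system, coords, restraint) {
  stopifnot(inherits(restraint, "restraint_bias"))
  coords <- .as_coords(coords, system$n_particles)
  d <- coords[restraint$indices, , drop = FALSE] - restraint$reference
  forces <- matrix(0, system$n_particles, 3)
  forces[restraint$indices, ] <- -restraint$k * d
  list(energy = 0.5 * restraint$k * sum(d * d), forces = forces)
}

#' @export
bias_contribution.restraint_bias <- function(bias, system, coords, t, base) {
  ev <- restraint_energy_forces(system, coords, bias)
  list(forces = ev$forces, dv = c(restraint = ev$energy))
}

#' Measured and scheduled RMSD series of a targeted run
#'
#' @param trajectory an `md_trajectory` produced with a [tmd_bias()].
#' @return tibble with `time`, `rmsd` (measured best-fit) and
#'   `rmsd_target` (scheduled reference).
#' @export
tmd_rmsd_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  if (!all(c("tmd_rmsd", "tmd_rmsd_target") %in% colnames(trajectory$bias))) {
    stop("trajectory carries no targeted-MD channels", call. = FALSE)
  }
  tibble::tibble(time = trajectory$times,
                 rmsd = trajectory$bias[, "tmd_rmsd"],
                 rmsd_target = trajectory$bias[, "tmd_rmsd_target"])
}
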