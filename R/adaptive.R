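#' Progress-metric specification
#'
#' The docking progress metric is the geometric mean of labelled
#' site-pair distances — in the docking fixture, the distances from the
#' scissile-site bead to the two catalytic-site beads. Smaller values
#' mean a conformation closer to the docked (catalytic-like) state.
#'
#' @param pairs list of length-2 character vectors of site labels;
#'   default the scissile-to-catalytic pairs of the docking fixture.
#' @return object of class `progress_metric_spec`.
#' @export
progress_metric_spec <- function(pairs = list(c("scissile", "cat1"),
                                              c("scissile", "cat2"))) {
  if (!length(pairs)) stop("need at least one pair", call. = FALSE)
  pairs <- lapply(pairs, function(p) {
    p <- as.character(p)
    if (length(p) != 2) stop("each pair needs two labels", call. = FALSE)
    p
  })
  structure(list(pairs = pairs), class = "progress_metric_spec")
}

#' Evaluate the progress metric on one configuration
#'
#' @param coords `n x 3` coordinate matrix (or an [md_frame()]).
#' @param system the [particle_system()] whose labels resolve the pairs.
#' @param spec a [progress_metric_spec()].
#' @return the geometric mean of the pair distances (length units).
#' @examples
#' # distances 4 and 9 have geometric mean 6
#' @export
progress_metric <- function(coords, system, spec = progress_metric_spec()) {
  if (inherits(coords, "md_frame")) coords <- coords$coords
  coords <- .as_coords(coords, system$n_particles)
  d <- vapply(spec$pairs, function(p) {
    i <- site_index(system, p[1]); j <- site_index(system, p[2])
    sqrt(sum((coords[i, ] - coords[j, ])^2))
  }, numeric(1))
  if (any(d <= 0)) stop("coincident sites give a zero distance",
                        call. = FALSE)
  exp(mean(log(d)))
}

#' Progress-metric time series of a trajectory
#'
#' @param trajectory an `md_trajectory` (must carry its system).
#' @param spec a [progress_metric_spec()].
#' @param system optional override of the trajectory's system.
#' @return tibble with `frame`, `time`, `metric`.
#' @export
metric_series <- function(trajectory, spec = progress_metric_spec(),
                          system = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  system <- system %||% trajectory$system
  if (is.null(system)) stop("trajectory carries no system", call. = FALSE)
  nf <- n_frames(trajectory)
  m <- vapply(seq_len(nf),
              function(i) progress_metric(trajectory$coords[, , i], system,
                                          spec),
              numeric(1))
  tibble::tibble(frame = seq_len(nf), time = trajectory$times, metric = m)
}

#' Select the seed frame minimising the progress metric
#'
#' Scans saved frames of one or more trajectories (optionally nested by
#' cycle) and returns the frame with the smallest metric. Ties are broken
#' deterministically in favour of the earlier cycle, then the lower
#' replica index, then the earlier frame.
#'
#' @param trajectories a single `md_trajectory`, a list of them (one
#'   cycle), or a list of such lists (multiple cycles).
#' @param spec a [progress_metric_spec()].
#' @param system optional system override.
#' @return list with `frame` (an [md_frame()]), `metric`, `cycle`,
#'   `replica`, `frame_index`.
#' @export
select_seed <- function(trajectories, spec = progress_metric_spec(),
                        system = NULL) {
  if (inherits(trajectories, "md_trajectory")) {
    trajectories <- list(list(trajectories))
  } else if (is.list(trajectories) && length(trajectories) &&
             inherits(trajectories[[1]], "md_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (!length(trajectories) || !length(trajectories[[1]])) {
    stop("no trajectories to select from", call. = FALSE)
  }
  best <- NULL
  for (ci in seq_along(trajectories)) {
    for (ri in seq_along(trajectories[[ci]])) {
      traj <- trajectories[[ci]][[ri]]
      if (is.null(traj)) next
      ms <- metric_series(traj, spec, system = system)
      k <- which.min(ms$metric) # which.min returns the earliest minimum
      if (is.null(best) || ms$metric[k] < best$metric) {
        best <- list(frame = traj_frame(traj, k), metric = ms$metric[k],
                     cycle = ci, replica = ri, frame_index = k)
      }
    }
  }
  if (is.null(best)) stop("no frames available", call. = FALSE)
  best
}

#' Campaign settings for the step-by-step ensemble protocol
#'
#' Each cycle launches `n_replicas` unbiased runs seeded from the frame
#' with the lowest progress metric found in the previous cycle
#' (`selection_scope = "previous_cycle"`, the literal protocol) or in all
#' cycles so far (`"best_so_far"`, under which the per-cycle minimum
#' series is non-increasing by construction). The campaign stops early
#' when the relative change of the per-cycle minimum stays below
#' `convergence$relative_tolerance` over `convergence$window` consecutive
#' cycles.
#'
#' @param n_cycles maximum number of cycles.
#' @param n_replicas ensemble size per cycle (default 10).
#' @param run_length integration steps per replica run.
#' @param selection_scope `"previous_cycle"` or `"best_so_far"`.
#' @param convergence list with `window` (cycles) and
#'   `relative_tolerance`.
#' @param master_seed campaign seed; replica streams are derived as
#'   `hash(master_seed, cycle, replica)`.
#' @return object of class `campaign_spec`.
#' @export
campaign_spec <- function(n_cycles = 4L, n_replicas = 10L,
                          run_length = 6000L,
                          selection_scope = c("previous_cycle",
                                              "best_so_far"),
                          convergence = list(window = 2L,
                                             relative_tolerance = 0.05),
                          master_seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  stopifnot(n_cycles >= 0, n_replicas >= 1, run_length >= 0,
            convergence$window >= 1, convergence$relative_tolerance > 0)
  structure(list(n_cycles = as.integer(n_cycles),
                 n_replicas = as.integer(n_replicas),
                 run_length = as.integer(run_length),
                 selection_scope = selection_scope,
                 convergence = convergence,
                 master_seed = as.integer(master_seed)),
            class = "campaign_spec")
}

#' Run a step-by-step adaptive ensemble campaign
#'
#' Cycles of unbiased replica ensembles, each cycle reseeded from the
#' snapshot minimising the progress metric (see [campaign_spec()]).
#' Velocities are redrawn from the Maxwell-Boltzmann distribution at each
#' reseeding. A replica whose integration fails is logged and dropped;
#' the cycle proceeds as long as at least one replica survives.
#'
#' @param system a [particle_system()].
#' @param engine a template [engine_params()]; `n_steps` and `seed` are
#'   overridden per replica from the campaign spec.
#' @param spec a [campaign_spec()].
#' @param metric_spec a [progress_metric_spec()].
#' @param initial starting [md_frame()] or coordinate matrix (e.g. the
#'   fixture's undocked pose).
#' @return object of class `stepwise_campaign`: `seed_frame` (the final
#'   selected frame), `series` (tibble of per-cycle minimum metrics and
#'   selections), `trajectories` (list of per-cycle replica lists),
#'   `manifest` (run ledger tibble), `converged`, `failures`.
#' @export
run_stepwise_campaign <- function(system, engine, spec = campaign_spec(),
                                  metric_spec = progress_metric_spec(),
                                  initial) {
  stopifnot(inherits(system, "particle_system"),
            inherits(engine, "engine_params"),
            inherits(spec, "campaign_spec"))
  if (!inherits(initial, "md_frame")) {
    initial <- md_frame(0, .as_coords(initial, system$n_particles))
  }
  m0 <- progress_metric(initial$coords, system, metric_spec)
  if (spec$n_cycles == 0L) {
    return(structure(list(
      seed_frame = initial, series = tibble::tibble(
        cycle = integer(0), min_metric = numeric(0),
        seed_cycle = integer(0), seed_replica = integer(0)),
      trajectories = list(), manifest = manifest(), converged = FALSE,
      failures = list(), initial_metric = m0, spec = spec),
      class = "stepwise_campaign"))
  }
  seed_frame <- initial
  all_traj <- list()
  series <- numeric(0)
  seed_cycle <- integer(0); seed_replica <- integer(0)
  failures <- list()
  manifest_rows <- list()
  converged <- FALSE
  conv <- spec$convergence
  for (cycle in seq_len(spec$n_cycles)) {
    cycle_traj <- vector("list", spec$n_replicas)
    ok <- 0L
    for (rep_i in seq_len(spec$n_replicas)) {
      p <- engine
      p$n_steps <- spec$run_length
      p$seed <- derive_seed(spec$master_seed, cycle, rep_i)
      start <- md_frame(0, seed_frame$coords) # velocities redrawn (MB)
      res <- tryCatch(run_md(system, p, initial = start),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          list(cycle = cycle, replica = rep_i,
               message = conditionMessage(res))
        next
      }
      cycle_traj[[rep_i]] <- res
      ok <- ok + 1L
    }
    if (ok == 0L) {
      stop("all replicas failed in cycle ", cycle, call. = FALSE)
    }
    all_traj[[cycle]] <- cycle_traj
    manifest_rows[[cycle]] <- manifest(
      group = sprintf("C%d", cycle), method = "cMDens",
      start_note = if (cycle == 1) "initial structure" else
        sprintf("selected from %s",
                if (spec$selection_scope == "previous_cycle")
                  sprintf("C%d", cycle - 1) else "best so far"),
      time_per_run_ns = spec$run_length * engine$dt, n_runs = ok)
    scope_traj <- if (spec$selection_scope == "previous_cycle") {
      list(cycle_traj)
    } else {
      all_traj
    }
    sel <- select_seed(scope_traj, metric_spec, system = system)
    seed_frame <- sel$frame
    series[cycle] <- sel$metric
    seed_cycle[cycle] <- if (spec$selection_scope == "previous_cycle")
      cycle else sel$cycle
    seed_replica[cycle] <- sel$replica
    if (cycle > conv$window) {
      idx <- (cycle - conv$window):cycle
      rel <- abs(diff(series[idx])) / series[idx[-length(idx)]]
      if (all(rel < conv$relative_tolerance)) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(
    seed_frame = seed_frame,
    series = tibble::tibble(cycle = seq_along(series), min_metric = series,
                            seed_cycle = seed_cycle,
                            seed_replica = seed_replica),
    trajectories = all_traj,
    manifest = dplyr::bind_rows(manifest_rows),
    converged = converged, failures = failures,
    initial_metric = m0, spec = spec),
    class = "stepwise_campaign")
}

#' @export
print.stepwise_campaign <- function(x, ...) {
  cat("<stepwise_campaign> ", nrow(x$series), " cycle(s), ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  cat("  metric: ", format(x$initial_metric, digits = 4), " -> ",
      format(x$seed_metric %||% utils::tail(x$series$min_metric, 1),
             digits = 4), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
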