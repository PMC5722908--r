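#' Accelerated-MD boost energy
#'
#' The non-negative boost added to a potential-energy channel when it
#' falls below the threshold `E`:
#' `dV = (E - V)^2 / (alpha + (E - V))` for `V < E`, else 0. The boosted
#' potential `V + dV` is bounded in `(E - alpha, E]` for `V < E`, is
#' monotone increasing in `V`, and flattens basins without touching the
#' landscape above the threshold.
#'
#' @param V instantaneous potential energy of the boosted channel
#'   (vectorised).
#' @param E threshold energy.
#' @param alpha acceleration factor (> 0, same units as energy); larger
#'   `alpha` means a gentler, shallower boost.
#' @return the boost energy dV (>= 0).
#' @examples
#' amd_boost(0, E = 10, alpha = 5) # 100/15
#' @export
amd_boost <- function(V, E, alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0)) {
    stop("alpha must be > 0", call. = FALSE)
  }
  ifelse(V >= E, 0, (E - V)^2 / (alpha + (E - V)))
}

#' Accelerated-MD force scale factor
#'
#' Derivative of the boosted potential with respect to the unbiased one,
#' `d(V + dV)/dV = alpha^2 / (alpha + E - V)^2` for `V < E` and 1 above the
#' threshold: the multiplier applied to the channel's unbiased force. Lies
#' in (0, 1] and is continuous at `V = E`.
#'
#' @inheritParams amd_boost
#' @return the force scale factor.
#' @export
amd_force_factor <- function(V, E, alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0)) {
    stop("alpha must be > 0", call. = FALSE)
  }
  ifelse(V >= E, 1, alpha^2 / (alpha + E - V)^2)
}

#' Accelerated-MD boost parameters
#'
#' In `"dihedral_only"` mode a single channel (the system's
#' internal-coordinate terms — the toy analog of the dihedral energy) is
#' boosted; in `"dual"` mode the total potential receives an additional
#' independent boost. The total bias `dV` recorded per frame is the sum of
#' the channel boosts, and the biased force is
#' `f_tot * F_total + (f_dih - 1) * F_dih` with `f = amd_force_factor()`
#' per channel.
#'
#' @param mode `"dihedral_only"` or `"dual"`.
#' @param E_dihedral,alpha_dihedral threshold and acceleration factor for
#'   the internal-coordinate channel.
#' @param E_total,alpha_total threshold and acceleration factor for the
#'   total-potential channel (dual mode only).
#' @return an object of class `amd_params`.
#' @seealso [amd_bias()], [estimate_amd_params()]
#' @export
amd_params <- function(mode = c("dihedral_only", "dual"),
                       E_dihedral, alpha_dihedral,
                       E_total = NULL, alpha_total = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(E_dihedral), alpha_dihedral > 0)
  if (mode == "dual") {
    if (is.null(E_total) || is.null(alpha_total)) {
      stop("dual mode requires E_total and alpha_total", call. = FALSE)
    }
    stopifnot(alpha_total > 0)
  } else if (!is.null(E_total) || !is.null(alpha_total)) {
    stop("dihedral_only mode takes a single channel", call. = FALSE)
  }
  structure(list(mode = mode, E_dihedral = E_dihedral,
                 alpha_dihedral = alpha_dihedral,
                 E_total = E_total, alpha_total = alpha_total),
            class = "amd_params")
}

#' Estimate boost parameters from conventional-MD statistics
#'
#' The standard recipe sets, per channel, `E = <V> + cE * size` and
#' `alpha = c_alpha * size`, where `<V>` is the channel's mean energy from
#' an unbiased run and `size` is the system-size measure appropriate to
#' the channel (a residue-analog count for the internal-coordinate
#' channel, the particle count for the total channel). The coefficients
#' default to the shape of the standard protein recipe
#' (dihedral: 3.5 and 0.7 per residue; total: 0.175 and 0.175 per atom)
#' and are configurable, since published variants differ.
#'
#' @param cmd_stats list with `mean_dihedral` (mean internal-coordinate
#'   channel energy), `size_dihedral`, and for dual mode `mean_total` and
#'   `size_total`.
#' @param mode `"dihedral_only"` or `"dual"`.
#' @param cE_dihedral,calpha_dihedral,cE_total,calpha_total recipe
#'   coefficients.
#' @return an [amd_params()] object.
#' @examples
#' estimate_amd_params(list(mean_dihedral = 100, size_dihedral = 10))
#' @export
estimate_amd_params <- function(cmd_stats,
                                mode = c("dihedral_only", "dual"),
                                cE_dihedral = 3.5, calpha_dihedral = 0.7,
                                cE_total = 0.175, calpha_total = 0.175) {
  mode <- match.arg(mode)
  need <- c("mean_dihedral", "size_dihedral")
  if (mode == "dual") need <- c(need, "mean_total", "size_total")
  missing <- setdiff(need, names(cmd_stats))
  if (length(missing)) {
    stop("cmd_stats missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(vapply(cmd_stats[need], is.finite, logical(1))))
  a_dih <- calpha_dihedral * cmd_stats$size_dihedral
  if (a_dih <= 0) stop("alpha (dihedral channel) computes to <= 0",
                       call. = FALSE)
  E_dih <- cmd_stats$mean_dihedral + cE_dihedral * cmd_stats$size_dihedral
  if (mode == "dihedral_only") {
    return(amd_params("dihedral_only", E_dih, a_dih))
  }
  a_tot <- calpha_total * cmd_stats$size_total
  if (a_tot <= 0) stop("alpha (total channel) computes to <= 0",
                       call. = FALSE)
  E_tot <- cmd_stats$mean_total + cE_total * cmd_stats$size_total
  amd_params("dual", E_dih, a_dih, E_tot, a_tot)
}

#' Create an accelerated-MD bias for the dynamics engine
#'
#' @param params an [amd_params()].
#' @return a bias object usable in [run_md()]. Per-frame boost energies
#'   are recorded in the trajectory's bias channels `amd_dihedral` (and
#'   `amd_total` in dual mode).
#' @export
amd_bias <- function(params) {
  stopifnot(inherits(params, "amd_params"))
  structure(list(params = params), class = "amd_bias")
}

#' @export
bias_contribution.amd_bias <- function(bias, system, coords, t, base) {
  p <- bias$params
  dv_d <- amd_boost(base$channel_energy, p$E_dihedral, p$alpha_dihedral)
  f_d <- amd_force_factor(base$channel_energy, p$E_dihedral,
                          p$alpha_dihedral)
  forces <- (f_d - 1) * base$channel_forces
  dv <- c(amd_dihedral = dv_d)
  if (p$mode == "dual") {
    dv_t <- amd_boost(base$energy, p$E_total, p$alpha_total)
    f_t <- amd_force_factor(base$energy, p$E_total, p$alpha_total)
    forces <- forces + (f_t - 1) * base$forces
    dv <- c(dv, amd_total = dv_t)
  }
  list(forces = forces, dv = dv)
}

#' Reweight a biased trajectory into a free-energy profile
#'
#' Recovers the unbiased free energy along an observable from a boosted
#' run by exponential reweighting: each frame gets weight
#' `exp(dV / temperature)` with `dV` the total recorded bias energy, and
#' the profile is `F(bin) = -temperature * log(sum of weights in bin)`,
#' shifted so the minimum is zero. A second-order cumulant estimator
#' (`log` mean weight approximated by `<dV> + var(dV)/2T` per bin) is
#' available, which trades bias for variance when the boost is large.
#' Empty bins are reported with `NA` free energy, not zero.
#'
#' @param trajectory an `md_trajectory` whose frames carry bias channels
#'   (any channel named `amd_*` contributes to `dV`), or a data frame /
#'   tibble with columns `observable` and `dv`.
#' @param observable for a trajectory input: a function mapping an
#'   `n x 3` coordinate matrix to a scalar, or a numeric vector of
#'   precomputed per-frame values.
#' @param temperature thermal energy kB·T of the run.
#' @param breaks bin breaks (passed to [base::cut()]) or a single bin
#'   count.
#' @param estimator `"exponential"` (default) or `"cumulant2"`.
#' @return a tibble with one row per bin: `bin`, `center`, `count`,
#'   `free_energy` (minimum zero, `NA` for empty bins).
#' @export
reweight_profile <- function(trajectory, observable = NULL, temperature,
                             breaks = 50,
                             estimator = c("exponential", "cumulant2")) {
  estimator <- match.arg(estimator)
  stopifnot(temperature > 0)
  if (inherits(trajectory, "md_trajectory")) {
    if (is.function(observable)) {
      nf <- n_frames(trajectory)
      obs <- vapply(seq_len(nf),
                    function(i) observable(trajectory$coords[, , i]),
                    numeric(1))
    } else if (is.numeric(observable)) {
      obs <- observable
      if (length(obs) != n_frames(trajectory)) {
        stop("observable length must match frame count", call. = FALSE)
      }
    } else {
      stop("observable must be a function or numeric vector", call. = FALSE)
    }
    amd_cols <- grep("^amd_", colnames(trajectory$bias))
    dv <- if (length(amd_cols)) {
      rowSums(trajectory$bias[, amd_cols, drop = FALSE])
    } else {
      rep(0, n_frames(trajectory))
    }
  } else {
    df <- as.data.frame(trajectory)
    if (!all(c("observable", "dv") %in% names(df))) {
      stop("data-frame input needs columns `observable` and `dv`",
           call. = FALSE)
    }
    obs <- df$observable
    dv <- df$dv
  }
  if (length(breaks) == 1) {
    breaks <- seq(min(obs), max(obs), length.out = breaks + 1)
  }
  bin <- cut(obs, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(centers)
  # work with dv shifted by its max so exp() cannot overflow; the shift is
  # an additive constant in F and is removed by the min-zero convention
  dvs <- dv - max(dv)
  lw <- vapply(seq_len(nb), function(b) {
    sel <- which(bin == b)
    if (!length(sel)) return(NA_real_)
    if (estimator == "exponential") {
      log(sum(exp(dvs[sel] / temperature)))
    } else {
      mean(dvs[sel]) / temperature +
        (if (length(sel) > 1) stats::var(dvs[sel]) else 0) /
          (2 * temperature^2) + log(length(sel))
    }
  }, numeric(1))
  fe <- -temperature * lw
  fe <- fe - min(fe, na.rm = TRUE)
  counts <- tabulate(bin, nb)
  tibble::tibble(bin = seq_len(nb), center = centers,
                 count = counts, free_energy = fe)
}
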