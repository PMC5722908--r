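#' Create a bead-model particle system
#'
#' A `particle_system` is the container the dynamics engine and all analysis
#' functions operate on: a set of point beads with masses, a list of
#' potential terms (harmonic bonds, per-axis harmonic tethers, quartic
#' double wells, short-range pair terms, analytic landscapes), named site
#' labels (e.g. `"scissile"`, `"cat1"`) and named groups (e.g.
#' `"mobile_domain"`, `"scaffold"`).
#'
#' Potential terms are added with [add_bond()], [add_tether()],
#' [add_double_well()], [add_pair()] and [add_landscape_term()]; labels and
#' groups with [set_labels()] and [set_groups()]. All indices are 1-based.
#'
#' @param n_particles number of beads.
#' @param masses per-particle masses, recycled to length `n_particles`.
#'   Must be positive.
#' @param mode `"reduced"` (kB = 1, dimensionless units; the default) or
#'   `"physical"` (kcal/mol, Angstrom, masses in amu).
#' @return an object of class `particle_system`.
#' @seealso [compute_forces()], [make_domain_docking_model()],
#'   [make_analytic_landscape()]
#' @export
particle_system <- function(n_particles, masses = 1,
                            mode = c("reduced", "physical")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_particles), length(n_particles) == 1,
            n_particles >= 1, n_particles == round(n_particles))
  masses <- rep_len(as.numeric(masses), n_particles)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be finite and > 0", call. = FALSE)
  }
  structure(
    list(
      n_particles = as.integer(n_particles),
      masses = masses,
      mode = mode,
      terms = list(),
      labels = integer(0),
      groups = list(),
      boost_terms = integer(0) # term indices forming the "dihedral" channel
    ),
    class = "particle_system"
  )
}

#' @export
print.particle_system <- function(x, ...) {
  kinds <- vapply(x$terms, function(t) t$kind, character(1))
  cat("<particle_system> ", x$n_particles, " beads (", x$mode, " units)\n",
      sep = "")
  if (length(kinds)) {
    tab <- table(kinds)
    cat("  terms: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$labels)) {
    cat("  labels: ", paste(names(x$labels), collapse = ", "), "\n", sep = "")
  }
  if (length(x$groups)) {
    cat("  groups: ",
        paste(sprintf("%s(%d)", names(x$groups), lengths(x$groups)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

.check_index <- function(system, i, what = "index") {
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > system$n_particles)) {
    stop(what, " out of range [1, ", system$n_particles, "]", call. = FALSE)
  }
  i
}

#' Add a harmonic bond term
#'
#' Energy `0.5 * kappa * (|r_i - r_j| - r0)^2`.
#'
#' @param system a [particle_system()].
#' @param i,j particle indices (1-based, distinct).
#' @param kappa spring constant (energy/length^2), > 0.
#' @param r0 rest length, >= 0.
#' @return the modified system.
#' @export
add_bond <- function(system, i, j, kappa, r0) {
  stopifnot(inherits(system, "particle_system"), kappa > 0, r0 >= 0)
  i <- .check_index(system, i); j <- .check_index(system, j)
  if (i == j) stop("bond requires distinct particles", call. = FALSE)
  system$terms <- c(system$terms, list(list(
    kind = "bond", i = i, j = j, kappa = as.numeric(kappa), r0 = as.numeric(r0)
  )))
  .invalidate_compiled(system)
}

#' Add a per-axis harmonic tether
#'
#' Energy `0.5 * sum_ax k[ax] * (x[ax] - ref[ax])^2`. A zero component of
#' `kappa` leaves that axis free, which is how scaffold beads are pinned
#' while a docking coordinate stays mobile.
#'
#' @inheritParams add_bond
#' @param kappa length-1 or length-3 spring constant(s), >= 0.
#' @param ref length-3 reference position.
#' @return the modified system.
#' @export
add_tether <- function(system, i, kappa, ref) {
  stopifnot(inherits(system, "particle_system"), length(ref) == 3,
            all(is.finite(ref)))
  i <- .check_index(system, i)
  kappa <- rep_len(as.numeric(kappa), 3)
  if (any(kappa < 0)) stop("tether kappa must be >= 0", call. = FALSE)
  system$terms <- c(system$terms, list(list(
    kind = "tether", i = i, kappa = kappa, ref = as.numeric(ref)
  )))
  .invalidate_compiled(system)
}

#' Add a quartic double well along one axis
#'
#' Energy `a * ((x - center)^2 - b)^2` in the chosen coordinate of one
#' particle: minima at `center +/- sqrt(b)`, barrier height `a * b^2` at
#' `x = center`. These terms form the internal-coordinate ("dihedral"
#' analog) boost channel used by the accelerated-MD bias.
#'
#' @inheritParams add_bond
#' @param axis 1, 2 or 3 (x, y, z).
#' @param a quartic coefficient, > 0 (sets the barrier `a * b^2`).
#' @param b squared half-separation of the wells, > 0.
#' @param center well midpoint coordinate.
#' @return the modified system.
#' @export
add_double_well <- function(system, i, axis, a, b, center = 0) {
  stopifnot(inherits(system, "particle_system"), axis %in% 1:3,
            a > 0, b > 0, is.finite(center))
  i <- .check_index(system, i)
  system$terms <- c(system$terms, list(list(
    kind = "dwell", i = i, axis = as.integer(axis),
    a = as.numeric(a), b = as.numeric(b), center = as.numeric(center)
  )))
  system$boost_terms <- c(system$boost_terms, length(system$terms))
  .invalidate_compiled(system)
}

#' Add a short-range pair term
#'
#' Two styles of truncated, shifted pair potential:
#' * `"lj"` — Lennard-Jones `4*eps*((sigma/r)^12 - (sigma/r)^6)`,
#'   minimum depth `-eps` at `2^(1/6)*sigma`;
#' * `"gauss"` — attractive Gaussian well
#'   `-eps * exp(-(r - r0)^2 / (2*sigma^2))`, minimum `-eps` at `r0`.
#'
#' Both are shifted so the energy is exactly zero at and beyond `cutoff`.
#'
#' @inheritParams add_bond
#' @param eps well depth, > 0.
#' @param sigma length scale (LJ sigma, or Gaussian width), > 0.
#' @param cutoff truncation distance, > 0.
#' @param style `"lj"` or `"gauss"`.
#' @param r0 Gaussian well position (ignored for `"lj"`).
#' @return the modified system.
#' @export
add_pair <- function(system, i, j, eps, sigma, cutoff,
                     style = c("lj", "gauss"), r0 = 0) {
  style <- match.arg(style)
  stopifnot(inherits(system, "particle_system"), eps > 0, sigma > 0)
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be > 0", call. = FALSE)
  }
  i <- .check_index(system, i); j <- .check_index(system, j)
  if (i == j) stop("pair term requires distinct particles", call. = FALSE)
  system$terms <- c(system$terms, list(list(
    kind = "pair", i = i, j = j, style = style, eps = as.numeric(eps),
    sigma = as.numeric(sigma), r0 = as.numeric(r0),
    cutoff = as.numeric(cutoff)
  )))
  .invalidate_compiled(system)
}

#' Add an analytic landscape term
#'
#' Binds one particle to an analytic energy surface (see
#' [make_analytic_landscape()] for the stock surfaces). `energy_fn(x)` takes
#' a length-3 position and returns a scalar; `gradient_fn(x)` its length-3
#' gradient. Landscape terms join the internal-coordinate boost channel.
#'
#' @inheritParams add_bond
#' @param id character tag for the surface.
#' @param energy_fn,gradient_fn analytic energy and gradient functions.
#' @return the modified system.
#' @export
add_landscape_term <- function(system, i, id, energy_fn, gradient_fn) {
  stopifnot(inherits(system, "particle_system"),
            is.function(energy_fn), is.function(gradient_fn))
  i <- .check_index(system, i)
  system$terms <- c(system$terms, list(list(
    kind = "landscape", i = i, id = as.character(id),
    energy = energy_fn, gradient = gradient_fn
  )))
  system$boost_terms <- c(system$boost_terms, length(system$terms))
  .invalidate_compiled(system)
}

#' Name individual beads as sites
#'
#' @param system a [particle_system()].
#' @param ... named 1-based indices, e.g. `scissile = 1, cat1 = 5`.
#' @return the modified system.
#' @export
set_labels <- function(system, ...) {
  stopifnot(inherits(system, "particle_system"))
  new <- c(...)
  if (length(new) == 0) return(system)
  if (is.null(names(new)) || any(names(new) == "")) {
    stop("labels must be named", call. = FALSE)
  }
  new <- vapply(new, function(i) .check_index(system, i, "label index"),
                integer(1))
  labels <- c(system$labels[setdiff(names(system$labels), names(new))], new)
  if (anyDuplicated(names(labels))) {
    stop("label names must be unique", call. = FALSE)
  }
  system$labels <- labels
  system
}

#' Name index sets as groups
#'
#' @param system a [particle_system()].
#' @param ... named integer vectors, e.g. `mobile_domain = 4:9`.
#' @return the modified system.
#' @export
set_groups <- function(system, ...) {
  stopifnot(inherits(system, "particle_system"))
  new <- list(...)
  if (length(new) == 0) return(system)
  if (is.null(names(new)) || any(names(new) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  new <- lapply(new, function(ix) .check_index(system, ix, "group index"))
  system$groups[names(new)] <- new
  system
}

#' Resolve a site label to its particle index
#'
#' @param system a [particle_system()].
#' @param label site name.
#' @return 1-based particle index.
#' @export
site_index <- function(system, label) {
  stopifnot(inherits(system, "particle_system"))
  if (!label %in% names(system$labels)) {
    stop("unknown site label: ", label, call. = FALSE)
  }
  unname(system$labels[[label]])
}

#' Resolve a group name (or raw index vector) to particle indices
#'
#' @param system a [particle_system()].
#' @param selection group name, or an integer vector of indices passed
#'   through after range checking; `NULL` selects all particles.
#' @return integer vector of 1-based indices.
#' @export
group_indices <- function(system, selection = NULL) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(selection)) return(seq_len(system$n_particles))
  if (is.character(selection)) {
    if (length(selection) != 1 || !selection %in% names(system$groups)) {
      stop("unknown group: ", paste(selection, collapse = ","), call. = FALSE)
    }
    return(system$groups[[selection]])
  }
  .check_index(system, selection, "selection index")
}

# Compiled term tables are cached on the system for fast force evaluation.
.invalidate_compiled <- function(system) {
  system$compiled <- NULL
  system
}

.compile_terms <- function(system) {
  if (!is.null(system$compiled)) return(system)
  terms <- system$terms
  n <- system$n_particles
  kinds <- vapply(terms, function(t) t$kind, character(1))
  pick <- function(k) terms[kinds == k]
  mat <- function(lst, fields) {
    if (length(lst) == 0) return(NULL)
    do.call(rbind, lapply(lst, function(t) unlist(t[fields], use.names = FALSE)))
  }
  # scatter matrix: n x nterm, +1 at i (and -1 at j for two-body terms), so
  # per-particle forces are a single matrix product per term family
  scatter <- function(i, j = NULL) {
    S <- matrix(0, n, length(i))
    S[cbind(i, seq_along(i))] <- 1
    if (!is.null(j)) S[cbind(j, seq_along(j))] <- S[cbind(j, seq_along(j))] - 1
    S
  }
  bonds <- pick("bond")
  tethers <- pick("tether")
  dwells <- pick("dwell")
  pairs <- pick("pair")
  bond <- mat(bonds, c("i", "j", "kappa", "r0"))
  pair <- if (length(pairs)) do.call(rbind, lapply(pairs, function(t) {
    c(t$i, t$j, if (t$style == "lj") 1 else 2, t$eps, t$sigma, t$r0,
      t$cutoff)
  })) else NULL
  tether_i <- vapply(tethers, function(t) t$i, integer(1))
  system$compiled <- list(
    bond = bond,
    bond_scatter = if (!is.null(bond)) scatter(bond[, 1], bond[, 2]),
    tether_i = tether_i,
    tether_scatter = if (length(tether_i)) scatter(tether_i),
    tether_k = mat(tethers, "kappa"),
    tether_ref = mat(tethers, "ref"),
    dwell = mat(dwells, c("i", "axis", "a", "b", "center")),
    pair = pair,
    pair_scatter = if (!is.null(pair)) scatter(pair[, 1], pair[, 2]),
    landscape = pick("landscape")
  )
  system
}

#' Evaluate the potential energy and forces of a system
#'
#' Sums all potential terms; forces are the exact analytic negative
#' gradient. The energy and forces of the internal-coordinate boost channel
#' (double-well and landscape terms) are returned alongside, which is what
#' the accelerated-MD dual-boost bias consumes.
#'
#' @param system a [particle_system()].
#' @param coords `n x 3` coordinate matrix.
#' @return list with `energy` (scalar), `forces` (`n x 3`),
#'   `channel_energy` and `channel_forces` for the boost channel.
#' @export
compute_forces <- function(system, coords) {
  stopifnot(inherits(system, "particle_system"))
  coords <- .as_coords(coords, system$n_particles)
  system <- .compile_terms(system)
  compute_forces_core(system, coords)
}

# validated fast path shared with the integrator (system must be compiled)
compute_forces_core <- function(system, coords) {
  if (any(!is.finite(coords))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  cmp <- system$compiled
  n <- system$n_particles
  energy <- 0
  forces <- matrix(0, n, 3)
  ch_energy <- 0
  ch_forces <- matrix(0, n, 3)

  if (!is.null(cmp$bond)) {
    i <- cmp$bond[, 1]; j <- cmp$bond[, 2]
    dx <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(.rowSums(dx * dx, length(i), 3))
    dr <- r - cmp$bond[, 4]
    energy <- energy + sum(0.5 * cmp$bond[, 3] * dr^2)
    # force on i: -kappa * dr * unit(i->j); guard r=0 (direction undefined)
    fac <- -cmp$bond[, 3] * dr / r
    fac[r == 0] <- 0
    forces <- forces + cmp$bond_scatter %*% (dx * fac)
  }
  if (length(cmp$tether_i)) {
    d <- coords[cmp$tether_i, , drop = FALSE] - cmp$tether_ref
    energy <- energy + 0.5 * sum(cmp$tether_k * d * d)
    forces <- forces + cmp$tether_scatter %*% (-cmp$tether_k * d)
  }
  if (!is.null(cmp$dwell)) {
    ia <- cbind(cmp$dwell[, 1], cmp$dwell[, 2])
    x <- coords[ia] - cmp$dwell[, 5]
    u <- x * x - cmp$dwell[, 4]
    e <- cmp$dwell[, 3] * u^2
    f <- -4 * cmp$dwell[, 3] * u * x
    energy <- energy + sum(e)
    ch_energy <- ch_energy + sum(e)
    forces[ia] <- forces[ia] + f
    ch_forces[ia] <- ch_forces[ia] + f
  }
  if (!is.null(cmp$pair)) {
    i <- cmp$pair[, 1]; j <- cmp$pair[, 2]
    dx <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(.rowSums(dx * dx, length(i), 3))
    eps <- cmp$pair[, 4]; sig <- cmp$pair[, 5]; r0 <- cmp$pair[, 6]
    rc <- cmp$pair[, 7]
    lj <- cmp$pair[, 3] == 1
    e <- numeric(length(r)); dVdr <- numeric(length(r))
    if (any(lj)) {
      s6 <- (sig[lj] / r[lj])^6
      s6c <- (sig[lj] / rc[lj])^6
      e[lj] <- 4 * eps[lj] * (s6^2 - s6) - 4 * eps[lj] * (s6c^2 - s6c)
      dVdr[lj] <- 4 * eps[lj] * (-12 * s6^2 + 6 * s6) / r[lj]
    }
    if (!all(lj)) {
      g <- !lj
      z <- (r[g] - r0[g]) / sig[g]
      zc <- (rc[g] - r0[g]) / sig[g]
      e[g] <- -eps[g] * (exp(-0.5 * z^2) - exp(-0.5 * zc^2))
      dVdr[g] <- eps[g] * z / sig[g] * exp(-0.5 * z^2)
    }
    outside <- r >= rc
    e[outside] <- 0; dVdr[outside] <- 0
    energy <- energy + sum(e)
    fac <- -dVdr / r
    fac[r == 0] <- 0
    forces <- forces + cmp$pair_scatter %*% (dx * fac)
  }
  for (t in cmp$landscape) {
    x <- coords[t$i, ]
    e <- t$energy(x)
    g <- t$gradient(x)
    energy <- energy + e
    ch_energy <- ch_energy + e
    forces[t$i, ] <- forces[t$i, ] - g
    ch_forces[t$i, ] <- ch_forces[t$i, ] - g
  }
  list(energy = energy, forces = forces,
       channel_energy = ch_energy, channel_forces = ch_forces)
}

.as_coords <- function(coords, n = NULL) {
  if (is.null(dim(coords)) && is.numeric(coords) &&
      length(coords) %% 3 == 0) {
    # single-particle frames drop to a bare vector when sliced from the
    # coordinate array; restore the n x 3 layout (column-major)
    coords <- matrix(coords, ncol = 3)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coordinates must be n x 3", call. = FALSE)
  if (!is.null(n) && nrow(coords) != n) {
    stop("coordinate rows (", nrow(coords), ") do not match particle count (",
         n, ")", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  coords
}
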