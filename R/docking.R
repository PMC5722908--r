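#' Geometry parameters for the domain-docking fixture
#'
#' The fixture emulates a mobile nuclease domain tethered to a scaffold,
#' switching between an undocked pose (active-site beads far from the
#' scissile-site bead) and a docked pose (close). The progress metric —
#' the geometric mean of the scissile-to-catalytic-site distances — takes
#' the designed values exactly at the two poses. Defaults echo the
#' experimental scale of the docking transition: undocked metric ~9.5
#' length units, docked 6.
#'
#' @param docked_metric designed progress-metric value of the docked pose.
#' @param undocked_metric designed value of the undocked pose (must exceed
#'   `docked_metric`).
#' @param lateral in-plane half-separation of the two catalytic-site
#'   beads.
#' @param cat_drop drop of the catalytic beads below the domain anchor.
#' @param barrier double-well barrier between the poses (energy units).
#' @param ion_eps,ion_sigma per-contact depth and width of the ion's
#'   attractive wells to the two catalytic beads and the scissile bead.
#' @param stiff_kappa intra-domain bond stiffness.
#' @param scaffold_kappa scaffold tether stiffness.
#' @param xy_kappa lateral (x, y) tether stiffness on mobile beads
#'   (suppresses domain rotation; the docking z coordinate stays free).
#' @param linker_kappa flexible linker stiffness.
#' @param ion_tether_kappa stiffness pinning the ion near the reaction
#'   interface.
#' @param contact_eps,contact_frac strength and position (as a fraction of
#'   `docked_metric`) of the purely repulsive excluded-volume wall between
#'   the scissile bead and each catalytic bead, which keeps the docked
#'   contact from being compressed below its designed separation.
#' @param jitter amplitude of the seeded jitter applied to unlabeled
#'   scaffold filler beads.
#' @return a list of class `docking_geometry`.
#' @export
docking_geometry <- function(docked_metric = 6, undocked_metric = 9.5,
                             lateral = 0.5, cat_drop = 0.5, barrier = 3.5,
                             ion_eps = 4, ion_sigma = 0.2,
                             stiff_kappa = 100, scaffold_kappa = 200,
                             xy_kappa = 10, linker_kappa = 0.02,
                             ion_tether_kappa = 100, contact_eps = 2,
                             contact_frac = 0.985, jitter = 0.05) {
  geom <- list(docked_metric = docked_metric,
               undocked_metric = undocked_metric, lateral = lateral,
               cat_drop = cat_drop, barrier = barrier, ion_eps = ion_eps,
               ion_sigma = ion_sigma, stiff_kappa = stiff_kappa,
               scaffold_kappa = scaffold_kappa, xy_kappa = xy_kappa,
               linker_kappa = linker_kappa,
               ion_tether_kappa = ion_tether_kappa,
               contact_eps = contact_eps, contact_frac = contact_frac,
               jitter = jitter)
  stopifnot(all(vapply(geom, function(x) is.numeric(x) && is.finite(x),
                       logical(1))))
  if (docked_metric <= lateral || barrier <= 0) {
    stop("docked_metric must exceed lateral and barrier must be > 0",
         call. = FALSE)
  }
  class(geom) <- "docking_geometry"
  geom
}

#' Build the synthetic domain-docking bead model
#'
#' Constructs a scaffold (8 pinned beads carrying the scissile-site bead
#' and two FRET-analog label sites), a 6-bead quasi-rigid mobile domain
#' (anchor, two catalytic-site beads, a third FRET-analog site) joined to
#' the scaffold by two flexible linkers, and — when `ion_present` — an
#' ion bead pinned at the reaction interface whose short-range attraction
#' to the catalytic beads makes the docked pose the deeper free-energy
#' minimum. A quartic double well on the anchor's docking coordinate
#' places the two poses at the designed progress-metric values.
#'
#' The returned system carries:
#' * groups `scaffold`, `mobile_domain` (and label `ion` if present);
#' * labels `scissile`, `cat1`, `cat2`, `fretA`, `fretB`, `fretC`;
#' * `poses$docked` / `poses$undocked` — full coordinate matrices of the
#'   two designed poses;
#' * `design` — the designed metric values and the exact docked-pose
#'   stabilisation `ion_depth` contributed by the removable ion term.
#'
#' Construction is deterministic for a given `(geometry, seed)`; the seed
#' only jitters the unlabeled scaffold filler beads (tether references
#' move with them, so the poses remain exact minima).
#'
#' @param geometry a [docking_geometry()].
#' @param ion_present include the ion bead and its attraction terms?
#' @param seed integer construction seed.
#' @param mode unit mode passed to [particle_system()].
#' @return a [particle_system()] with the fields described above.
#' @export
make_domain_docking_model <- function(geometry = docking_geometry(),
                                      ion_present = TRUE, seed = 1L,
                                      mode = c("reduced", "physical")) {
  stopifnot(inherits(geometry, "docking_geometry"))
  mode <- match.arg(mode)
  g <- geometry
  if (g$docked_metric >= g$undocked_metric) {
    stop("degenerate geometry: docked metric must be below undocked metric",
         call. = FALSE)
  }
  # anchor heights realising the designed metrics:
  # d(scissile, cat) = sqrt(lateral^2 + (h - cat_drop)^2) = metric
  h_of <- function(metric) g$cat_drop + sqrt(metric^2 - g$lateral^2)
  h_d <- h_of(g$docked_metric)
  h_u <- h_of(g$undocked_metric)
  scale_xy <- g$docked_metric / 6 # keep proportions across rescaled fixtures

  scaffold_xy <- rbind(
    scissile = c(0, 0, 0),
    fretA    = c(4, 0, 0.5),
    fretC    = c(-4, 0, 0.5),
    linkL    = c(2.5, 2.5, 1),
    linkR    = c(-2.5, 2.5, 1),
    fill1    = c(0, -3, 0),
    fill2    = c(2, -2, 0.5),
    fill3    = c(-2, -2, 0.5)
  ) * scale_xy
  set.seed(as.integer(seed))
  jit <- matrix(stats::rnorm(9, sd = g$jitter), 3, 3)
  scaffold_xy[c("fill1", "fill2", "fill3"), ] <-
    scaffold_xy[c("fill1", "fill2", "fill3"), ] + jit

  mobile_local <- rbind( # offsets from the anchor
    anchor = c(0, 0, 0),
    cat1   = c(g$lateral, 0, -g$cat_drop),
    cat2   = c(-g$lateral, 0, -g$cat_drop),
    fretB  = c(0, 0.9 * scale_xy, 0.6 * scale_xy),
    m5     = c(0.9 * scale_xy, 0.6 * scale_xy, 0.8 * scale_xy),
    m6     = c(-0.9 * scale_xy, 0.6 * scale_xy, 0.8 * scale_xy)
  )
  pose_coords <- function(h, ion_pos = NULL) {
    mob <- sweep(mobile_local, 2, c(0, 0, h), FUN = "+")
    out <- rbind(scaffold_xy, mob)
    if (!is.null(ion_pos)) out <- rbind(out, ion = ion_pos)
    rownames(out) <- NULL
    out
  }
  i_scaffold <- 1:8
  i_mobile <- 9:14
  idx <- c(scissile = 1L, fretA = 2L, fretC = 3L, linkL = 4L, linkR = 5L,
           anchor = 9L, cat1 = 10L, cat2 = 11L, fretB = 12L,
           m5 = 13L, m6 = 14L)

  # ion design point: centroid of cat1/cat2/scissile in the docked pose
  docked_nofix <- pose_coords(h_d)
  ion_pos <- colMeans(docked_nofix[c(idx["cat1"], idx["cat2"],
                                     idx["scissile"]), ])
  n <- if (ion_present) 15L else 14L
  sys <- particle_system(n, masses = 1, mode = mode)

  for (i in i_scaffold) {
    sys <- add_tether(sys, i, kappa = g$scaffold_kappa,
                      ref = scaffold_xy[i, ])
  }
  # quasi-rigid mobile domain: anchor spokes plus bracing bonds
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  braces <- rbind(
    cbind(rep(idx["anchor"], 5), c(idx["cat1"], idx["cat2"], idx["fretB"],
                                   idx["m5"], idx["m6"])),
    c(idx["cat1"], idx["cat2"]), c(idx["cat1"], idx["m5"]),
    c(idx["cat2"], idx["m6"]), c(idx["fretB"], idx["m5"]),
    c(idx["fretB"], idx["m6"]), c(idx["m5"], idx["m6"]),
    c(idx["cat1"], idx["fretB"]), c(idx["cat2"], idx["fretB"])
  )
  for (r in seq_len(nrow(braces))) {
    i <- braces[r, 1]; j <- braces[r, 2]
    sys <- add_bond(sys, i, j, kappa = g$stiff_kappa,
                    r0 = dist3(docked_nofix[i, ], docked_nofix[j, ]))
  }
  # lateral tethers keep the domain oriented; z stays free for docking
  for (i in i_mobile) {
    sys <- add_tether(sys, i, kappa = c(g$xy_kappa, g$xy_kappa, 0),
                      ref = c(docked_nofix[i, 1:2], 0))
  }
  # flexible linkers, rest length midway between the poses
  undocked_nofix <- pose_coords(h_u)
  for (lk in list(c(idx["linkL"], idx["m5"]), c(idx["linkR"], idx["m6"]))) {
    r0 <- (dist3(docked_nofix[lk[1], ], docked_nofix[lk[2], ]) +
           dist3(undocked_nofix[lk[1], ], undocked_nofix[lk[2], ])) / 2
    sys <- add_bond(sys, lk[1], lk[2], kappa = g$linker_kappa, r0 = r0)
  }
  # docking double well on the anchor's z coordinate
  center <- (h_d + h_u) / 2
  b <- ((h_u - h_d) / 2)^2
  a <- g$barrier / b^2
  sys <- add_double_well(sys, idx[["anchor"]], axis = 3, a = a, b = b,
                         center = center)
  # excluded-volume walls: truncated-at-minimum (purely repulsive) LJ
  # between the scissile bead and each catalytic bead, zero at the poses
  wall <- g$contact_frac * g$docked_metric
  for (partner in c("cat1", "cat2")) {
    sys <- add_pair(sys, idx[["scissile"]], idx[[partner]],
                    eps = g$contact_eps, sigma = wall / 2^(1 / 6),
                    cutoff = wall, style = "lj")
  }

  ion_depth <- 0
  if (ion_present) {
    i_ion <- 15L
    sys <- add_tether(sys, i_ion, kappa = g$ion_tether_kappa, ref = ion_pos)
    shift_frac <- exp(-0.5 * 16) # wells truncated at r0 + 4 sigma
    for (partner in c("cat1", "cat2")) {
      r0 <- dist3(ion_pos, docked_nofix[idx[partner], ])
      sys <- add_pair(sys, i_ion, idx[[partner]], eps = g$ion_eps,
                      sigma = g$ion_sigma, cutoff = r0 + 4 * g$ion_sigma,
                      style = "gauss", r0 = r0)
      ion_depth <- ion_depth + g$ion_eps * (1 - shift_frac)
    }
    r0s <- dist3(ion_pos, docked_nofix[idx[["scissile"]], ])
    sys <- add_pair(sys, i_ion, idx[["scissile"]], eps = g$ion_eps,
                    sigma = g$ion_sigma, cutoff = r0s + 4 * g$ion_sigma,
                    style = "gauss", r0 = r0s)
    sys <- set_labels(sys, ion = i_ion)
  }

  sys <- set_labels(sys, scissile = idx[["scissile"]],
                    fretA = idx[["fretA"]], fretC = idx[["fretC"]],
                    cat1 = idx[["cat1"]], cat2 = idx[["cat2"]],
                    fretB = idx[["fretB"]])
  sys <- set_groups(sys, scaffold = i_scaffold, mobile_domain = i_mobile)
  ion_arg <- if (ion_present) ion_pos else NULL
  sys$poses <- list(docked = pose_coords(h_d, ion_arg),
                    undocked = pose_coords(h_u, ion_arg))
  sys$design <- list(docked_metric = g$docked_metric,
                     undocked_metric = g$undocked_metric,
                     ion_depth = ion_depth, barrier = g$barrier,
                     anchor_heights = c(docked = h_d, undocked = h_u),
                     geometry = g, seed = as.integer(seed),
                     ion_present = ion_present)
  sys
}

#' Paper-scale targeted-MD steering setup on the docking fixture
#'
#' Prepares the physical-unit docking fixture and steering parameters for
#' the standard targeted-MD exercise: a start pose whose best-fit RMSD
#' from the docked target (measured over the mobile domain after a
#' scaffold fit) equals `initial_rmsd`, a per-atom spring constant
#' `k_per_atom` in kcal/mol/A^2, and a linear schedule from
#' `initial_rmsd` to `rmsd_final` over `duration` ns — i.e. a scheduled
#' RMSD decrease rate of `(initial_rmsd - rmsd_final)/duration` A/ns.
#' The fixture uses a low docking barrier (~1 kBT) and near-slack
#' linkers, since this exercise probes schedule tracking rather than
#' barrier hopping, and the engine friction default keeps the steered
#' collective coordinate's lag relaxation fast relative to the schedule
#' (slope estimates from a single run still wander by ~10%; production
#' use averages duplicate runs, as steering campaigns usually do).
#'
#' @param initial_rmsd starting mobile-domain RMSD from the target (A).
#' @param k_per_atom per-targeted-atom spring constant (kcal/mol/A^2).
#' @param duration schedule length (ns).
#' @param rmsd_final scheduled final RMSD (A).
#' @param temperature thermal energy (kcal/mol); default 310.15 K.
#' @param seed engine seed.
#' @return list with `system` (the fixture), `tmd` ([tmd_params()]),
#'   `engine` ([engine_params()]; dt 0.005 ns, friction 0.2/ns, one
#'   frame per 0.1 ns) and `initial` (the start pose).
#' @export
make_tmd_steering_setup <- function(initial_rmsd = 10, k_per_atom = 0.25,
                                    duration = 100, rmsd_final = 0,
                                    temperature = thermal_energy(310.15),
                                    seed = 1L) {
  stopifnot(initial_rmsd > 0, duration > 0)
  geom <- function(mu) {
    docking_geometry(undocked_metric = mu, barrier = 0.3,
                     ion_sigma = 0.3, linker_kappa = 0.002)
  }
  mobile <- 9:14
  scaffold <- 1:8
  gap_rmsd <- function(mu) {
    s <- make_domain_docking_model(geom(mu), mode = "physical")
    tp <- tmd_params(k_per_atom = k_per_atom, targeted_indices = mobile,
                     target_coords = s$poses$docked,
                     fit_indices = scaffold,
                     schedule = list(t_start = 0, t_end = 1,
                                     rmsd_initial = 1, rmsd_final = 0))
    tmd_energy_forces(s, s$poses$undocked, 0, tp)$rmsd - initial_rmsd
  }
  mu <- stats::uniroot(gap_rmsd, c(6.5, 20 + 2 * initial_rmsd),
                       tol = 1e-9)$root
  system <- make_domain_docking_model(geom(mu), mode = "physical")
  tmd <- tmd_params(k_per_atom = k_per_atom, targeted_indices = mobile,
                    target_coords = system$poses$docked,
                    fit_indices = scaffold, weights = "mass",
                    schedule = list(t_start = 0, t_end = duration,
                                    rmsd_initial = initial_rmsd,
                                    rmsd_final = rmsd_final))
  engine <- engine_params(dt = 0.005, temperature = temperature,
                          friction = 0.2,
                          n_steps = round(duration / 0.005),
                          save_interval = 20, seed = seed)
  list(system = system, tmd = tmd, engine = engine,
       initial = system$poses$undocked)
}
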