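#' Superpose every frame onto a reference using a fit selection
#'
#' Each frame is rigid-body transformed by the rotation/translation that
#' best fits the *fit selection* onto the reference; the rest of the
#' system (e.g. a mobile domain excluded from the fit) is carried along
#' by the same transform without further fitting. This is the standard
#' protocol for analysing a mobile domain's motion relative to a fixed
#' scaffold frame of reference.
#'
#' @param trajectory an `md_trajectory`.
#' @param reference reference coordinates (`n x 3` matrix or
#'   [md_frame()]); defaults to the first frame.
#' @param fit_selection group name or index vector used for the fit;
#'   `NULL` fits on all particles.
#' @param weights optional per-atom fit weights (defaults to uniform;
#'   `"mass"` uses the system masses).
#' @return the aligned `md_trajectory`.
#' @export
fit_superpose_series <- function(trajectory, reference = NULL,
                                 fit_selection = NULL, weights = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  system <- trajectory$system
  if (inherits(reference, "md_frame")) reference <- reference$coords
  if (is.null(reference)) reference <- trajectory$coords[, , 1]
  reference <- .as_coords(reference, dim(trajectory$coords)[1])
  sel <- if (is.null(system)) {
    if (is.null(fit_selection)) seq_len(nrow(reference)) else
      as.integer(fit_selection)
  } else {
    group_indices(system, fit_selection)
  }
  if (length(sel) < 3) stop("fit selection needs at least 3 particles",
                            call. = FALSE)
  w <- if (identical(weights, "mass")) {
    system$masses[sel]
  } else if (is.null(weights)) {
    NULL
  } else {
    as.numeric(weights)
  }
  out <- trajectory
  for (i in seq_len(n_frames(trajectory))) {
    X <- trajectory$coords[, , i]
    fit <- kabsch_superpose(reference[sel, , drop = FALSE],
                            X[sel, , drop = FALSE], weights = w)
    out$coords[, , i] <- sweep(X %*% t(fit$rotation), 2, fit$translation,
                               FUN = "+")
  }
  out
}

#' Distances between labelled site pairs over a trajectory
#'
#' @param trajectory an `md_trajectory` carrying its system.
#' @param pairs list of length-2 character vectors of site labels (e.g.
#'   FRET-analog label pairs).
#' @return tibble with `frame`, `time`, `pair` (`"a-b"`), `distance`; use
#'   [tidyr::pivot_wider()] for pair-vs-pair scatter exports.
#' @export
distance_pairs_series <- function(trajectory, pairs) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  system <- trajectory$system
  if (is.null(system)) stop("trajectory carries no system", call. = FALSE)
  pairs <- lapply(pairs, as.character)
  nf <- n_frames(trajectory)
  purrr::map_dfr(pairs, function(p) {
    i <- site_index(system, p[1]); j <- site_index(system, p[2])
    d <- sqrt(colSums((trajectory$coords[i, , ] -
                         trajectory$coords[j, , ])^2))
    tibble::tibble(frame = seq_len(nf), time = trajectory$times,
                   pair = paste(p, collapse = "-"), distance = d)
  })
}

#' Per-group RMSD series with global or per-group fitting
#'
#' `"global_fit"` superposes each frame on the designated fit selection
#' (default: all particles) and reports each group's RMSD from the
#' reference *without refitting* — so a rigidly displaced but internally
#' intact domain shows its full displacement. `"self_fit"` superposes
#' each group onto its own reference coordinates before computing its
#' RMSD — reporting only internal deformation.
#'
#' @param trajectory an `md_trajectory` carrying its system.
#' @param reference reference coordinates (default first frame).
#' @param groups character vector of group names (default all groups).
#' @param fit_mode `"global_fit"` or `"self_fit"`.
#' @param fit_selection fit selection for `"global_fit"` (default all
#'   particles).
#' @return tibble with `frame`, `time`, `group`, `rmsd`.
#' @export
groupwise_rmsd <- function(trajectory, reference = NULL, groups = NULL,
                           fit_mode = c("global_fit", "self_fit"),
                           fit_selection = NULL) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(inherits(trajectory, "md_trajectory"))
  system <- trajectory$system
  if (is.null(system)) stop("trajectory carries no system", call. = FALSE)
  if (inherits(reference, "md_frame")) reference <- reference$coords
  if (is.null(reference)) reference <- trajectory$coords[, , 1]
  reference <- .as_coords(reference, system$n_particles)
  groups <- groups %||% names(system$groups)
  if (!length(groups)) stop("no groups to report", call. = FALSE)
  idx <- lapply(groups, function(gn) group_indices(system, gn))
  nf <- n_frames(trajectory)
  aligned <- if (fit_mode == "global_fit") {
    fit_superpose_series(trajectory, reference, fit_selection)
  } else {
    trajectory
  }
  purrr::map_dfr(seq_along(groups), function(gi) {
    sel <- idx[[gi]]
    r <- vapply(seq_len(nf), function(i) {
      X <- aligned$coords[sel, , i]
      if (fit_mode == "self_fit") {
        kabsch_superpose(X, reference[sel, , drop = FALSE])$rmsd
      } else {
        rmsd_nofit(X, reference[sel, , drop = FALSE])
      }
    }, numeric(1))
    tibble::tibble(frame = seq_len(nf), time = aligned$times,
                   group = groups[gi], rmsd = r)
  })
}

#' Cluster frames on pairwise best-fit RMSD and pick a representative
#'
#' Builds the pairwise best-fit RMSD matrix over the selection,
#' average-linkage clusters it, cuts the tree at an RMSD threshold, and
#' returns the medoid (minimum summed RMSD to its cluster mates) of the
#' largest cluster. All ties resolve to the earliest frame.
#'
#' @param trajectory an `md_trajectory`.
#' @param selection group name or indices over which the RMSD is
#'   computed (`NULL` = all particles).
#' @param threshold RMSD cut height for the tree (same units as
#'   coordinates).
#' @return list with `representative` (frame index), `cluster_sizes`,
#'   `assignment` (per-frame cluster id), `rmsd_matrix`.
#' @export
cluster_representative <- function(trajectory, selection = NULL,
                                   threshold = 1) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  nf <- n_frames(trajectory)
  if (nf == 0) stop("empty trajectory", call. = FALSE)
  sel <- if (is.null(trajectory$system)) {
    if (is.null(selection)) seq_len(dim(trajectory$coords)[1]) else
      as.integer(selection)
  } else {
    group_indices(trajectory$system, selection)
  }
  if (nf == 1) {
    return(list(representative = 1L, cluster_sizes = 1L,
                assignment = 1L, rmsd_matrix = matrix(0, 1, 1)))
  }
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    Xi <- trajectory$coords[sel, , i]
    for (j in (i + 1):nf) {
      D[i, j] <- D[j, i] <-
        kabsch_superpose(Xi, trajectory$coords[sel, , j])$rmsd
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  assignment <- stats::cutree(hc, h = threshold)
  sizes <- tabulate(assignment)
  big <- which(sizes == max(sizes))
  if (length(big) > 1) { # tie: cluster containing the earliest frame
    first_member <- vapply(big, function(cl) min(which(assignment == cl)),
                           integer(1))
    big <- big[which.min(first_member)]
  }
  members <- which(assignment == big)
  sums <- rowSums(D[members, members, drop = FALSE])
  rep_frame <- members[which.min(sums)] # which.min takes the earliest tie
  list(representative = rep_frame, cluster_sizes = sizes,
       assignment = assignment, rmsd_matrix = D)
}

#' Metal-coordination geometry around a labelled center
#'
#' Finds the candidate ligand sites within `cutoff` of the center and
#' checks for octahedral geometry: exactly six ligands whose
#' center-vertex angles split into twelve cis angles near 90 degrees and
#' three trans angles near 180 degrees (within the tolerances).
#'
#' @param coords `n x 3` coordinates or an [md_frame()].
#' @param system the [particle_system()] resolving the labels.
#' @param center_label label of the coordination center (e.g. `"ion"`).
#' @param candidate_labels labels of candidate ligand sites.
#' @param cutoff inclusion distance (> 0).
#' @param angle_tolerance maximal deviation (degrees) of cis angles from
#'   90 and trans angles from 180 for `is_octahedral`.
#' @return object of class `coordination_report`: `ligand_count`,
#'   `ligands` (tibble with label and distance), `cis_deviation`,
#'   `trans_deviation`, `octahedral_deviation` (the larger of the two),
#'   `is_octahedral`.
#' @export
coordination_geometry <- function(coords, system, center_label,
                                  candidate_labels, cutoff,
                                  angle_tolerance = 15) {
  if (inherits(coords, "md_frame")) coords <- coords$coords
  coords <- .as_coords(coords, system$n_particles)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  ci <- site_index(system, center_label)
  cand <- vapply(candidate_labels, function(l) site_index(system, l),
                 integer(1))
  d <- sqrt(rowSums((coords[cand, , drop = FALSE] -
                       matrix(coords[ci, ], length(cand), 3,
                              byrow = TRUE))^2))
  keep <- d <= cutoff
  lig <- cand[keep]
  ligands <- tibble::tibble(label = candidate_labels[keep],
                            distance = d[keep])
  count <- length(lig)
  cis_dev <- trans_dev <- NA_real_
  is_oct <- FALSE
  if (count >= 2) {
    V <- sweep(coords[lig, , drop = FALSE], 2, coords[ci, ])
    V <- V / sqrt(rowSums(V^2))
    pairs <- utils::combn(count, 2)
    ang <- vapply(seq_len(ncol(pairs)), function(k) {
      cosv <- sum(V[pairs[1, k], ] * V[pairs[2, k], ])
      acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
    }, numeric(1))
    trans <- ang >= 135
    cis_dev <- if (any(!trans)) max(abs(ang[!trans] - 90)) else 0
    trans_dev <- if (any(trans)) max(abs(ang[trans] - 180)) else NA_real_
    is_oct <- count == 6 && sum(trans) == 3 && !is.na(trans_dev) &&
      cis_dev <= angle_tolerance && trans_dev <= angle_tolerance
  }
  structure(list(ligand_count = count, ligands = ligands,
                 cis_deviation = cis_dev, trans_deviation = trans_dev,
                 octahedral_deviation = suppressWarnings(
                   max(cis_dev, trans_dev, na.rm = TRUE)),
                 is_octahedral = is_oct),
            class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  cat("<coordination_report> ", x$ligand_count, " ligand(s); ",
      if (isTRUE(x$is_octahedral)) "octahedral" else "not octahedral",
      "\n", sep = "")
  if (is.finite(x$octahedral_deviation)) {
    cat(sprintf("  max angular deviation: %.2f deg (cis %.2f, trans %s)\n",
                x$octahedral_deviation, x$cis_deviation,
                ifelse(is.na(x$trans_deviation), "-",
                       sprintf("%.2f", x$trans_deviation))))
  }
  invisible(x)
}

#' Cross-group non-bonded interaction energy decomposition
#'
#' Sums the pair potential terms whose endpoints straddle the two
#' (disjoint) groups, and splits each pair energy evenly between its two
#' endpoints, so the per-particle contributions sum exactly to the total
#' cross-group energy. A toy analog of per-residue interaction-energy
#' decomposition at a binding interface.
#'
#' @param system a [particle_system()].
#' @param coords `n x 3` coordinates or an [md_frame()].
#' @param group_a,group_b group names or index vectors (disjoint).
#' @return list with `total` and `per_particle` (tibble: `particle`,
#'   `group`, `energy`).
#' @export
interaction_decomposition <- function(system, coords, group_a, group_b) {
  if (inherits(coords, "md_frame")) coords <- coords$coords
  coords <- .as_coords(coords, system$n_particles)
  ia <- group_indices(system, group_a)
  ib <- group_indices(system, group_b)
  if (length(intersect(ia, ib))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  contrib <- numeric(system$n_particles)
  total <- 0
  for (t in system$terms) {
    if (t$kind != "pair") next
    cross <- (t$i %in% ia && t$j %in% ib) || (t$i %in% ib && t$j %in% ia)
    if (!cross) next
    r <- sqrt(sum((coords[t$i, ] - coords[t$j, ])^2))
    e <- .pair_energy_scalar(t, r)
    total <- total + e
    contrib[t$i] <- contrib[t$i] + e / 2
    contrib[t$j] <- contrib[t$j] + e / 2
  }
  involved <- sort(unique(c(ia, ib)))
  list(total = total,
       per_particle = tibble::tibble(
         particle = involved,
         group = ifelse(involved %in% ia,
                        if (is.character(group_a)) group_a else "group_a",
                        if (is.character(group_b)) group_b else "group_b"),
         energy = contrib[involved]))
}

.pair_energy_scalar <- function(t, r) {
  if (r >= t$cutoff) return(0)
  if (t$style == "lj") {
    s6 <- (t$sigma / r)^6
    s6c <- (t$sigma / t$cutoff)^6
    4 * t$eps * (s6^2 - s6) - 4 * t$eps * (s6c^2 - s6c)
  } else {
    z <- (r - t$r0) / t$sigma
    zc <- (t$cutoff - t$r0) / t$sigma
    -t$eps * (exp(-0.5 * z^2) - exp(-0.5 * zc^2))
  }
}
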