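docking_frames <- function(sys, poses, times = seq_along(poses)) {
  md_trajectory(lapply(seq_along(poses), function(i) {
    md_frame(times[i], poses[[i]], potential_energy = 0)
  }), system = sys)
}

test_that("fit superposition removes rigid whole-body motion", {
  sys <- make_domain_docking_model()
  ref <- sys$poses$docked
  set.seed(20)
  poses <- lapply(1:4, function(i) {
    sweep(ref %*% t(random_rotation()), 2, rnorm(3), FUN = "+")
  })
  traj <- docking_frames(sys, poses)
  aligned <- fit_superpose_series(traj, ref, fit_selection = "scaffold")
  for (i in 1:4) {
    expect_lt(max(abs(aligned$coords[, , i] - ref)), 1e-8)
  }
  # idempotence: refitting an aligned trajectory changes nothing
  again <- fit_superpose_series(aligned, ref, fit_selection = "scaffold")
  expect_equal(again$coords, aligned$coords, tolerance = 1e-10)
})

test_that("the mobile selection is carried along, not refit", {
  sys <- make_domain_docking_model()
  ref <- sys$poses$docked
  moved <- ref
  mobile <- group_indices(sys, "mobile_domain")
  moved[mobile, 3] <- moved[mobile, 3] + 2 # displace the domain only
  Q <- random_rotation()
  traj <- docking_frames(sys, list(sweep(moved %*% t(Q), 2, c(1, -2, 0.5),
                                         FUN = "+")))
  aligned <- fit_superpose_series(traj, ref, fit_selection = "scaffold")
  scaf <- group_indices(sys, "scaffold")
  expect_lt(rmsd_nofit(aligned$coords[scaf, , 1], ref[scaf, ]), 1e-8)
  expect_equal(rmsd_nofit(aligned$coords[mobile, , 1], ref[mobile, ]), 2,
               tolerance = 1e-8)
})

test_that("PCA recovers a known covariance and keeps exact bookkeeping", {
  sys <- particle_system(1)
  set.seed(21)
  nf <- 4000
  xs <- rnorm(nf, sd = 2)  # variance 4
  ys <- rnorm(nf, sd = 1)  # variance 1
  traj <- md_trajectory(lapply(seq_len(nf), function(i) {
    md_frame(i, matrix(c(xs[i], ys[i], 0), 1, 3), potential_energy = 0)
  }), system = sys)
  pca <- pca_modes(traj)
  expect_equal(pca$eigenvalues[1], 4, tolerance = 0.3)
  expect_equal(pca$eigenvalues[2], 1, tolerance = 0.15)
  expect_equal(pca$eigenvalues[3], 0, tolerance = 1e-12)
  expect_equal(sum(pca$fractions), 1, tolerance = 1e-9)
  expect_equal(crossprod(pca$modes), diag(3), tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  # projection variance equals the eigenvalue; mean projects to zero
  proj <- project_trajectory(traj, pca, n_modes = 2)
  expect_equal(var(proj$pc1), pca$eigenvalues[1], tolerance = 1e-9)
  expect_equal(var(proj$pc2), pca$eigenvalues[2], tolerance = 1e-9)
  expect_equal(colMeans(proj[, c("pc1", "pc2")]), c(pc1 = 0, pc2 = 0),
               tolerance = 1e-9)
  g <- glance(pca)
  expect_equal(g$total_variance, sum(pca$eigenvalues))
  td <- tidy(pca)
  expect_equal(td$cumulative_fraction[3], 1, tolerance = 1e-9)
})

test_that("identical frames give zero variance, one frame warns", {
  sys <- particle_system(2)
  f <- md_frame(1, matrix(1:6, 2, 3), potential_energy = 0)
  f2 <- md_frame(2, matrix(1:6, 2, 3), potential_energy = 0)
  pca <- pca_modes(md_trajectory(list(f, f2), system = sys))
  expect_true(all(pca$eigenvalues == 0))
  expect_warning(pca_modes(md_trajectory(list(f), system = sys)),
                 "single frame")
})

test_that("full-rank projection reconstructs the centred data exactly", {
  sys <- particle_system(2)
  set.seed(22)
  nf <- 12
  frames <- lapply(seq_len(nf), function(i) {
    md_frame(i, matrix(rnorm(6), 2, 3), potential_energy = 0)
  })
  traj <- md_trajectory(frames, system = sys)
  pca <- pca_modes(traj)
  proj <- project_trajectory(traj, pca, n_modes = 6)
  scores <- as.matrix(proj[, paste0("pc", 1:6)])
  recon <- scores %*% t(pca$modes) # back to centred coordinates
  M <- t(matrix(traj$coords, 6, nf))
  Mc <- sweep(M, 2, as.vector(pca$mean_coords))
  expect_lt(max(abs(recon - Mc)), 1e-9)
  expect_error(project_trajectory(traj, pca, n_modes = 7), "exceeds")
})

test_that("trajectories from the two basins separate in the PCA plane", {
  sys <- make_domain_docking_model()
  set.seed(23)
  noise <- function(base) base + matrix(rnorm(length(base), sd = 0.15),
                                        nrow(base), 3)
  poses <- c(lapply(1:10, function(i) noise(sys$poses$docked)),
             lapply(1:10, function(i) noise(sys$poses$undocked)))
  traj <- docking_frames(sys, poses)
  aligned <- fit_superpose_series(traj, sys$poses$docked,
                                  fit_selection = "scaffold")
  pca <- pca_modes(aligned, selection = "mobile_domain")
  proj <- project_trajectory(aligned, pca, n_modes = 1)
  a <- proj$pc1[1:10]; b <- proj$pc1[11:20]
  # silhouette-style separation: gap between clusters dwarfs their spread
  expect_gt(abs(mean(a) - mean(b)), 3 * (sd(a) + sd(b)))
})

test_that("distance series report labelled pairs per frame", {
  sys <- particle_system(2)
  sys <- set_labels(sys, a = 1, b = 2)
  f <- md_frame(1, rbind(c(0, 0, 0), c(3, 4, 0)), potential_energy = 0)
  f2 <- md_frame(2, rbind(c(0, 0, 0), c(3, 4, 0)), potential_energy = 0)
  traj <- md_trajectory(list(f, f2), system = sys)
  ds <- distance_pairs_series(traj, list(c("a", "b")))
  expect_equal(ds$distance, c(5, 5)) # static trajectory: constant series
  expect_error(distance_pairs_series(traj, list(c("a", "zz"))),
               "unknown site")
})

test_that("FRET-analog pair distances separate the designed poses", {
  sys <- make_domain_docking_model()
  traj <- docking_frames(sys, list(sys$poses$undocked, sys$poses$docked))
  ds <- distance_pairs_series(traj, list(c("fretA", "fretB"),
                                         c("fretB", "fretC")))
  wide <- tidyr::pivot_wider(ds, id_cols = "frame", names_from = "pair",
                             values_from = "distance")
  # the docked pose shortens both label distances, by the designed
  # displacement projected on the pair directions
  iA <- site_index(sys, "fretA"); iB <- site_index(sys, "fretB")
  dz <- sys$design$anchor_heights[["undocked"]] -
    sys$design$anchor_heights[["docked"]]
  expect_equal(wide[["fretA-fretB"]][1] - wide[["fretA-fretB"]][2],
               sqrt(sum((sys$poses$undocked[iA, ] -
                           sys$poses$undocked[iB, ])^2)) -
                 sqrt(sum((sys$poses$docked[iA, ] -
                             sys$poses$docked[iB, ])^2)))
  expect_gt(wide[["fretA-fretB"]][1], wide[["fretA-fretB"]][2])
})

test_that("groupwise RMSD distinguishes global and self fitting", {
  sys <- make_domain_docking_model()
  ref <- sys$poses$docked
  self_traj <- docking_frames(sys, list(ref))
  r0 <- groupwise_rmsd(self_traj, ref, fit_mode = "global_fit",
                       fit_selection = "scaffold")
  expect_true(all(r0$rmsd < 1e-9))
  r0s <- groupwise_rmsd(self_traj, ref, fit_mode = "self_fit")
  expect_true(all(r0s$rmsd < 1e-9))
  # rigidly rotated whole structure: global fit removes everything
  Q <- random_rotation()
  rot_traj <- docking_frames(sys, list(sweep(ref %*% t(Q), 2, c(2, 0, -1),
                                             FUN = "+")))
  rg <- groupwise_rmsd(rot_traj, ref, fit_mode = "global_fit",
                       fit_selection = NULL)
  expect_true(all(rg$rmsd < 1e-8))
  # internally rigid but displaced domain: self-fit ~ 0, global fit = shift
  moved <- ref
  mobile <- group_indices(sys, "mobile_domain")
  moved[mobile, 3] <- moved[mobile, 3] + 2.5
  mv_traj <- docking_frames(sys, list(moved))
  rs <- groupwise_rmsd(mv_traj, ref, groups = "mobile_domain",
                       fit_mode = "self_fit")
  expect_lt(rs$rmsd, 1e-9)
  rgl <- groupwise_rmsd(mv_traj, ref, groups = "mobile_domain",
                        fit_mode = "global_fit",
                        fit_selection = "scaffold")
  expect_equal(rgl$rmsd, 2.5, tolerance = 1e-8)
})

test_that("cluster representatives are medoids of the largest cluster", {
  sys <- particle_system(4)
  set.seed(24)
  base_a <- matrix(rnorm(12), 4, 3)
  base_b <- base_a * 3 # scaled shape: no rigid transform can match it
  frames <- c(lapply(1:8, function(i) base_a + rnorm(12, sd = 0.05)),
              lapply(1:2, function(i) base_b + rnorm(12, sd = 0.05)))
  traj <- md_trajectory(lapply(seq_along(frames), function(i) {
    md_frame(i, frames[[i]], potential_energy = 0)
  }), system = sys)
  cl <- cluster_representative(traj, threshold = 2)
  expect_equal(sort(cl$cluster_sizes, decreasing = TRUE), c(8, 2))
  expect_lte(cl$representative, 8) # from the big cluster
  # exhaustive medoid oracle on the same RMSD matrix
  big <- which(cl$assignment == cl$assignment[cl$representative])
  sums <- rowSums(cl$rmsd_matrix[big, big])
  expect_equal(cl$representative, big[which.min(sums)])
  # degenerate cases
  same <- md_trajectory(lapply(1:5, function(i) {
    md_frame(i, base_a, potential_energy = 0)
  }), system = sys)
  cls <- cluster_representative(same, threshold = 1)
  expect_equal(cls$representative, 1L)
  expect_equal(max(cls$assignment), 1L)
  one <- md_trajectory(list(md_frame(1, base_a, potential_energy = 0)),
                       system = sys)
  expect_equal(cluster_representative(one)$representative, 1L)
})

test_that("octahedral coordination is recognised and perturbation-tolerant", {
  sys <- particle_system(8)
  sys <- set_labels(sys, center = 1, l1 = 2, l2 = 3, l3 = 4, l4 = 5,
                    l5 = 6, l6 = 7, far = 8)
  octa <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1), c(5, 5, 5))
  ligs <- paste0("l", 1:6)
  rep_ok <- coordination_geometry(octa, sys, "center", c(ligs, "far"),
                                  cutoff = 1.5)
  expect_equal(rep_ok$ligand_count, 6)
  expect_true(rep_ok$is_octahedral)
  expect_equal(rep_ok$octahedral_deviation, 0, tolerance = 1e-9)
  # one vertex removed
  rep_5 <- coordination_geometry(octa, sys, "center", ligs[1:5],
                                 cutoff = 1.5)
  expect_equal(rep_5$ligand_count, 5)
  expect_false(rep_5$is_octahedral)
  # Gaussian perturbation sigma = 0.02: angular errors stay within a
  # 3-sigma-derived bound (~ 3 * sqrt(2) * sigma / r radians)
  set.seed(25)
  bound_deg <- 3 * sqrt(2) * 0.02 * 180 / pi * 1.5
  for (rep in 1:10) {
    pert <- octa
    pert[2:7, ] <- pert[2:7, ] + matrix(rnorm(18, sd = 0.02), 6, 3)
    rp <- coordination_geometry(pert, sys, "center", ligs, cutoff = 1.5)
    expect_true(rp$is_octahedral)
    expect_lt(rp$octahedral_deviation, bound_deg)
  }
  expect_error(coordination_geometry(octa, sys, "nope", ligs, 1.5),
               "unknown site")
})

test_that("interaction decomposition sums pair terms across groups", {
  sys <- particle_system(5)
  sys <- add_pair(sys, 1, 3, eps = 2, sigma = 0.5, cutoff = 5,
                  style = "gauss", r0 = 1.5)
  sys <- add_pair(sys, 2, 4, eps = 1, sigma = 1, cutoff = 4, style = "lj")
  sys <- add_pair(sys, 1, 2, eps = 3, sigma = 0.3, cutoff = 3,
                  style = "gauss", r0 = 1) # intra-group: excluded
  sys <- set_groups(sys, left = 1:2, right = 3:5)
  coords <- rbind(c(0, 0, 0), c(0, 1, 0), c(1.5, 0, 0), c(0, 2.2, 0),
                  c(9, 9, 9))
  dec <- interaction_decomposition(sys, coords, "left", "right")
  # analytic values of the two cross terms
  e13 <- -2 * (exp(0) - exp(-0.5 * ((5 - 1.5) / 0.5)^2))
  r24 <- 1.2
  e24 <- 4 * 1 * ((1 / r24)^12 - (1 / r24)^6) - 4 * ((1 / 4)^12 - (1 / 4)^6)
  expect_equal(dec$total, e13 + e24, tolerance = 1e-12)
  expect_equal(sum(dec$per_particle$energy), dec$total, tolerance = 1e-12)
  # no terms in range
  far <- coords; far[3:4, ] <- far[3:4, ] + 100
  expect_equal(interaction_decomposition(sys, far, "left", "right")$total,
               0)
  expect_error(interaction_decomposition(sys, coords, 1:3, 3:5),
               "disjoint")
})
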