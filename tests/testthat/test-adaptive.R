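make_metric_frames <- function(metrics, t0 = 0) {
  # frames of a 2-bead system whose single-pair metric equals `metrics`
  lapply(seq_along(metrics), function(i) {
    md_frame(t0 + i, rbind(c(0, 0, 0), c(metrics[i], 0, 0)),
             potential_energy = 0)
  })
}

two_bead_system <- function() {
  set_labels(particle_system(2), scissile = 1, cat1 = 2)
}

test_that("the progress metric is the geometric mean of pair distances", {
  sys <- particle_system(3)
  sys <- set_labels(sys, scissile = 1, cat1 = 2, cat2 = 3)
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 9, 0))
  expect_equal(progress_metric(coords, sys), 6) # sqrt(4 * 9)
  coords2 <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  expect_equal(progress_metric(coords2, sys), 6)
  # symmetric in pair order
  spec_rev <- progress_metric_spec(list(c("cat1", "scissile"),
                                        c("cat2", "scissile")))
  expect_equal(progress_metric(coords, sys, spec_rev), 6)
  coords2[2, ] <- 0
  expect_error(progress_metric(coords2, sys), "coincident")
})

test_that("the docking fixture realises its designed metric values", {
  sys <- make_domain_docking_model()
  expect_equal(progress_metric(sys$poses$docked, sys),
               sys$design$docked_metric, tolerance = 1e-9)
  expect_equal(progress_metric(sys$poses$undocked, sys),
               sys$design$undocked_metric, tolerance = 1e-9)
  expect_gt(progress_metric(sys$poses$undocked, sys),
            progress_metric(sys$poses$docked, sys))
})

test_that("seed selection minimises the metric with deterministic ties", {
  sys <- two_bead_system()
  spec <- single_pair_spec()
  single <- md_trajectory(make_metric_frames(8.8), system = sys)
  sel <- select_seed(single, spec)
  expect_equal(sel$metric, 8.8)
  expect_equal(sel$frame_index, 1)

  tied <- md_trajectory(make_metric_frames(c(8.1, 7.2, 7.2, 9.0)),
                        system = sys)
  sel2 <- select_seed(tied, spec)
  expect_equal(sel2$metric, 7.2)
  expect_equal(sel2$frame_index, 2) # earlier frame wins the tie

  # ties across replicas and cycles resolve to earlier cycle, lower replica
  cycles <- list(
    list(md_trajectory(make_metric_frames(c(9, 7.2)), system = sys),
         md_trajectory(make_metric_frames(c(7.2, 8)), system = sys)),
    list(md_trajectory(make_metric_frames(c(7.2, 7.5)), system = sys))
  )
  sel3 <- select_seed(cycles, spec)
  expect_equal(c(sel3$cycle, sel3$replica, sel3$frame_index), c(1, 1, 2))
  expect_error(select_seed(list(list()), spec), "no trajectories")
})

test_that("selection agrees with an exhaustive scan oracle", {
  sys <- two_bead_system()
  spec <- single_pair_spec()
  set.seed(15)
  vals <- lapply(1:4, function(r) 8 + cumsum(rnorm(30, sd = 0.1)))
  vals[[3]][17] <- 5.5 # replica 3 transiently reaches the lowest metric
  trajs <- lapply(vals, function(v)
    md_trajectory(make_metric_frames(v), system = sys))
  sel <- select_seed(trajs, spec)
  flat <- unlist(vals)
  expect_equal(sel$metric, min(flat))
  expect_equal(sel$replica, 3)
  expect_equal(sel$frame_index, 17)
})

test_that("a zero-cycle campaign returns the initial frame unchanged", {
  sys <- make_domain_docking_model()
  eng <- engine_params(dt = 0.01, n_steps = 1, seed = 1)
  camp <- run_stepwise_campaign(sys, eng, campaign_spec(n_cycles = 0),
                                initial = sys$poses$undocked)
  expect_equal(camp$seed_frame$coords, sys$poses$undocked)
  expect_equal(nrow(camp$series), 0)
  expect_false(camp$converged)
})

test_that("one cycle with one replica reduces to a plain MD run", {
  sys <- make_domain_docking_model()
  eng <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                       n_steps = 1, save_interval = 10, seed = 99)
  spec <- campaign_spec(n_cycles = 1, n_replicas = 1, run_length = 300,
                        master_seed = 5)
  camp <- run_stepwise_campaign(sys, eng, spec,
                                initial = sys$poses$undocked)
  p <- eng
  p$n_steps <- 300L
  p$seed <- stepmd:::derive_seed(5, 1, 1)
  direct <- run_md(sys, p, initial = md_frame(0, sys$poses$undocked))
  expect_identical(camp$trajectories[[1]][[1]]$coords, direct$coords)
  ms <- metric_series(direct)
  expect_equal(camp$series$min_metric[1], min(ms$metric))
})

test_that("a deterministic zero-temperature campaign descends to the minimum", {
  # a single mobile bead on a sloped well: T = 0 dynamics is gradient
  # descent, so the campaign must end at the designed minimum distance
  sys <- particle_system(2)
  sys <- add_tether(sys, 1, kappa = 100, ref = c(0, 0, 0))
  sys <- add_tether(sys, 2, kappa = 2, ref = c(3, 0, 0))
  sys <- set_labels(sys, scissile = 1, cat1 = 2)
  eng <- engine_params(dt = 0.02, temperature = 0, friction = 5,
                       n_steps = 1, save_interval = 10, seed = 1)
  spec <- campaign_spec(n_cycles = 4, n_replicas = 2, run_length = 2000,
                        master_seed = 2,
                        convergence = list(window = 1,
                                           relative_tolerance = 1e-4))
  init <- rbind(c(0, 0, 0), c(9, 0, 0))
  camp <- run_stepwise_campaign(sys, eng, spec, single_pair_spec(),
                                initial = init)
  expect_equal(tail(camp$series$min_metric, 1), 3, tolerance = 1e-3)
})

test_that("best-so-far campaigns have a non-increasing minimum series", {
  sys <- make_domain_docking_model()
  eng <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                       n_steps = 1, save_interval = 20, seed = 1)
  spec <- campaign_spec(n_cycles = 3, n_replicas = 3, run_length = 1500,
                        selection_scope = "best_so_far", master_seed = 8)
  camp <- run_stepwise_campaign(sys, eng, spec,
                                initial = sys$poses$undocked)
  expect_true(all(diff(camp$series$min_metric) <= 1e-12))
  # the manifest records every run
  expect_equal(nrow(camp$manifest), nrow(camp$series))
  expect_true(all(camp$manifest$n_runs == 3))
  expect_equal(unique(camp$manifest$method), "cMDens")
})

test_that("campaigns fail loudly when every replica fails", {
  sys <- add_bond(particle_system(2), 1, 2, kappa = 5000, r0 = 1)
  sys <- set_labels(sys, scissile = 1, cat1 = 2)
  eng <- engine_params(dt = 2, temperature = 1, friction = 0,
                       n_steps = 1, save_interval = 10, seed = 1,
                       explode_bound = 1e4)
  spec <- campaign_spec(n_cycles = 1, n_replicas = 2, run_length = 500,
                        master_seed = 3)
  init <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  expect_error(
    run_stepwise_campaign(sys, eng, spec, single_pair_spec(),
                          initial = init),
    "all replicas failed")
})

test_that("adaptive reseeding beats equal-budget single-seed ensembles", {
  # paired comparison of aggregate steps to first reach a docking
  # threshold; the stepwise protocol must win the majority of pairs
  sys <- make_domain_docking_model()
  threshold <- 7
  eng <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                       n_steps = 1, save_interval = 25, seed = 1)
  steps_to_threshold <- function(camp_traj, run_length) {
    total <- 0
    for (cyc in camp_traj) {
      for (tr in cyc) {
        ms <- metric_series(tr)
        hit <- which(ms$metric <= threshold)
        if (length(hit)) {
          return(total + (hit[1] - 1) * 25)
        }
        total <- total + run_length
      }
    }
    Inf
  }
  wins <- 0
  n_pairs <- 5
  for (pair in seq_len(n_pairs)) {
    spec <- campaign_spec(n_cycles = 4, n_replicas = 4, run_length = 1500,
                          selection_scope = "best_so_far",
                          master_seed = 100 + pair)
    camp <- run_stepwise_campaign(sys, eng, spec,
                                  initial = sys$poses$undocked)
    adaptive_cost <- steps_to_threshold(camp$trajectories, 1500)
    # same budget, all runs seeded from the initial undocked frame
    flat <- list()
    k <- 0
    for (cyc in 1:4) for (r in 1:4) {
      k <- k + 1
      p <- eng
      p$n_steps <- 1500L
      p$seed <- stepmd:::derive_seed(900 + pair, cyc, r)
      flat[[k]] <- run_md(sys, p, initial = md_frame(0, sys$poses$undocked))
    }
    single_cost <- steps_to_threshold(list(flat), 1500)
    if (adaptive_cost < single_cost) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("removing the ion from a docked seed destabilises docking", {
  with_ion <- make_domain_docking_model(ion_present = TRUE)
  without <- make_domain_docking_model(ion_present = FALSE)
  p <- engine_params(dt = 0.01, temperature = 1, friction = 1,
                     n_steps = 8000, save_interval = 20, seed = 6)
  m_with <- mean(metric_series(
    run_md(with_ion, p, initial = with_ion$poses$docked))$metric)
  m_without <- mean(metric_series(
    run_md(without, p, initial = without$poses$docked[1:14, ]))$metric)
  expect_gt(m_without, m_with)
})
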