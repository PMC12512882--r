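test_that("the myopic policy coincides with planning at gamma zero", {
  cat_ <- tiny_catalog(n_prep = 4, n_clusters = 2, n_pers = 1)
  mods <- hand_models(cat_, features = "belief_1", effort_value = 0.6)
  mods$effort$mean_scaled[2, ] <- 0.8
  full0 <- make_policy("full", mods$effort, mods$transition, cat_, gamma = 0)
  myo <- make_policy("myopic", mods$effort, mods$transition, cat_)
  expect_equal(full0$Q, myo$Q)
})

test_that("the random policy proposes preparatory activities uniformly", {
  cat_ <- fixture_activity_catalog(seed = 2)
  mods <- hand_models(cat_)
  pol <- make_policy("random", mods$effort, mods$transition, cat_)
  sim <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                         uniform_init(), n_people = 10000, horizon = 1,
                         seed = 13)
  counts <- table(factor(sim$actions[, 1], levels = cat_$id))
  expect_equal(sum(counts), 10000)
  expect_true(all(counts[as.character(45:53)] == 0))  # never persuasive
  chi <- suppressWarnings(chisq.test(counts[1:44]))
  expect_gt(chi$p.value, 0.001)
})

test_that("the effort-greedy cluster policy stays within preparatory clusters", {
  cat_ <- fixture_activity_catalog(seed = 2)
  mods <- hand_models(cat_)
  # cluster 3 has the clearly highest expected effort everywhere
  mods$effort$mean_scaled[, 3] <- 0.95
  pol <- make_policy("uf_only", mods$effort, mods$transition, cat_)
  sim <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                         uniform_init(), n_people = 200, horizon = 5, seed = 3)
  expect_true(all(cat_$kind[match(as.vector(sim$actions), cat_$id)] == "preparatory"))
  # first proposals come from the highest-effort cluster
  first_clusters <- cat_$cluster[match(sim$actions[, 1], cat_$id)]
  expect_true(all(first_clusters == 3))
})

test_that("degenerate environments give the expected curve endpoints", {
  # all-zero contributions: nothing can be built
  zero_cat <- tiny_catalog(n_prep = 6, n_clusters = 2,
                           cont = matrix(0, 6, 6))
  mods <- hand_models(zero_cat, features = "belief_1")
  pol <- make_policy("random", mods$effort, mods$transition, zero_cat)
  sim <- simulate_cohort(pol, mods$effort, mods$transition, zero_cat,
                         uniform_init(1), n_people = 50, horizon = 3, seed = 1)
  expect_equal(sim$fraction_built, rep(0, 4))

  # one all-ones activity at unit effort saturates in a single step
  one_cat <- tiny_catalog(n_prep = 1, n_clusters = 1,
                          cont = matrix(1, 1, 6))
  mods1 <- hand_models(one_cat, features = "belief_1", effort_value = 1)
  pol1 <- make_policy("myopic", mods1$effort, mods1$transition, one_cat)
  sim1 <- simulate_cohort(pol1, mods1$effort, mods1$transition, one_cat,
                          uniform_init(1), n_people = 20, horizon = 1, seed = 1)
  expect_equal(sim1$fraction_built, c(0, 1))
})

test_that("step fractions match hand arithmetic in a two-activity world", {
  # two activities, effort fixed at 0.5 everywhere, so each person follows
  # the same deterministic competency path under the greedy no-repeat rule
  cont <- rbind(c(0.8, 0.8, 0, 0, 0, 0),
                c(0, 0, 0.8, 0, 0, 0))
  cat_ <- tiny_catalog(n_prep = 2, n_clusters = 2, cont = cont)
  mods <- hand_models(cat_, features = "belief_1", effort_value = 0.5)
  pol <- make_policy("myopic", mods$effort, mods$transition, cat_)
  sim <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                         uniform_init(1), n_people = 10, horizon = 2, seed = 4)
  # step 1: activity 1 (reward 2/3 beats 1/3); levels (1/3, 1/3, 0, ...)
  lv1 <- update_competencies(rep(0, 6), 0.5, cont[1, ])
  # step 2: only activity 2 remains; levels add snap(0.4) on competency 3
  lv2 <- update_competencies(lv1, 0.5, cont[2, ])
  expect_equal(sim$fraction_built,
               c(0, sum(lv1) / 6, sum(lv2) / 6))
  expect_equal(sim$mc_se, rep(0, 3))  # identical trajectories
})

test_that("identical seeds reproduce the simulation bit for bit", {
  cat_ <- fixture_activity_catalog(seed = 2)
  mods <- hand_models(cat_, effort_value = 0.55, trans_p = 0.4)
  mods$effort$mean_scaled[5:8, ] <- 0.85  # uf-dependent efforts
  pol <- make_policy("myopic", mods$effort, mods$transition, cat_)
  s1 <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                        uniform_init(), n_people = 100, horizon = 5, seed = 77)
  s2 <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                        uniform_init(), n_people = 100, horizon = 5, seed = 77)
  expect_identical(s1$per_person, s2$per_person)
  expect_identical(s1$actions, s2$actions)
  s3 <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                        uniform_init(), n_people = 100, horizon = 5, seed = 78)
  expect_false(identical(s1$per_person, s3$per_person))
})

test_that("curves are non-decreasing, bounded, and start at zero", {
  cat_ <- fixture_activity_catalog(seed = 2)
  mods <- hand_models(cat_, effort_value = 0.6, trans_p = 0.5)
  for (v in c("full", "random", "uf_only")) {
    pol <- make_policy(v, mods$effort, mods$transition, cat_)
    sim <- simulate_cohort(pol, mods$effort, mods$transition, cat_,
                           uniform_init(), n_people = 100, horizon = 5,
                           seed = 5)
    expect_equal(sim$fraction_built[1], 0)
    expect_true(all(diff(sim$fraction_built) >= 0))
    expect_true(all(sim$fraction_built <= 1))
  }
})

test_that("resampling at keep fraction one reproduces the baseline", {
  cat_ <- fixture_activity_catalog(seed = 2)
  truth <- generate_ground_truth(synthetic_config(n_people = 200), seed = 6)
  log <- generate_mrt_log(truth, cat_, seed = 7)
  spec <- binarization_spec(log)
  samples <- interaction_samples(log, quiet = TRUE)
  feats <- c("belief_1", "belief_7", "energy")
  init <- estimate_initial_uf(log, spec, feats)
  reps <- robustness_resample(samples, cat_, spec, feats, init,
                              keep_fraction = 1, n_reps = 2, seeds = c(3, 3),
                              n_people = 50, horizon = 3)
  expect_length(reps, 2)
  expect_identical(reps[[1]]$fraction_built, reps[[2]]$fraction_built)
  eff <- fit_effort_model(samples, cat_, feats, spec)
  trans <- fit_transition_model(samples, cat_, feats, spec)
  pol <- make_policy("full", eff, trans, cat_)
  base <- simulate_cohort(pol, eff, trans, cat_, init, n_people = 50,
                          horizon = 3, seed = 3)
  expect_equal(reps[[1]]$fraction_built, base$fraction_built)
})

test_that("a discount sweep at gamma zero reproduces the myopic curve", {
  cat_ <- fixture_activity_catalog(seed = 2)
  mods <- hand_models(cat_, effort_value = 0.6)
  mods$effort$mean_scaled[5:8, ] <- 0.75
  sweep <- gamma_sweep(c(0, 0.85), mods$effort, mods$transition, cat_,
                       uniform_init(), n_people = 80, horizon = 5, seed = 9)
  expect_named(sweep, c("0", "0.85"))
  myo <- make_policy("myopic", mods$effort, mods$transition, cat_)
  sim_myo <- simulate_cohort(myo, mods$effort, mods$transition, cat_,
                             uniform_init(), n_people = 80, horizon = 5,
                             seed = 9)
  expect_equal(sweep[["0"]]$fraction_built, sim_myo$fraction_built)
  expect_error(gamma_sweep(c(0.5, 1), mods$effort, mods$transition, cat_,
                           uniform_init()), "gamma")
})
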