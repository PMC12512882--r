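test_that("binarization thresholds at the sample mean, inclusive", {
  log <- data.frame(person_id = 1:4, session = 1L)
  for (f in feature_columns()) log[[f]] <- c(1, 2, 3, 6)  # mean 3
  spec <- binarization_spec(log)
  bits <- binarize_features(log, spec)
  expect_equal(unname(bits[, "belief_1"]), c(0L, 0L, 1L, 1L))  # raw = mean -> 1
  # constant column: every value equals the mean, so all bits are 1
  log2 <- log
  log2$energy <- 5
  bits2 <- binarize_features(log2, binarization_spec(log2))
  expect_equal(unname(bits2[, "energy"]), rep(1L, 4))
})

test_that("session pairing yields one sample per consecutive attended pair", {
  fc <- feature_columns()
  log <- data.frame(person_id = c(1, 1, 1, 2, 2, 3),
                    session = c(1, 2, 3, 1, 3, 1))
  for (f in fc) log[[f]] <- seq_len(6)
  log$action_id <- 1:6
  log$raw_effort <- c(5, 6, NA, 7, NA, NA)
  s <- interaction_samples(log, quiet = TRUE)
  # person 1: (1,2) and (2,3); person 2's sessions 1,3 are not consecutive;
  # person 3 has a single session
  expect_equal(nrow(s), 2)
  expect_equal(s$person_id, c(1, 1))
  expect_equal(s$cur_belief_1, c(1, 2))
  expect_equal(s$nxt_belief_1, c(2, 3))
})

test_that("k-means recovers planted activity clusters", {
  set.seed(11)
  blob <- rbind(matrix(rnorm(10 * 3, mean = 0), 10, 3),
                matrix(rnorm(10 * 3, mean = 8), 10, 3))
  cl <- cluster_preparatory_activities(blob, k = 2, seed = 3)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[11])
  # duplicated rows always co-cluster
  dup <- blob[c(1, 1, 15, 15), ]
  cl2 <- cluster_preparatory_activities(dup, k = 2, seed = 3)
  expect_equal(cl2[1], cl2[2])
  expect_equal(cl2[3], cl2[4])
  # k = n gives singletons
  expect_equal(sort(cluster_preparatory_activities(blob, k = 20, seed = 1)), 1:20)
  expect_error(cluster_preparatory_activities(blob, k = 0), "positive")
})

test_that("effort model averages scaled efforts per configuration and group", {
  cat_ <- tiny_catalog(n_prep = 2, n_clusters = 2)
  feats <- c("belief_1")
  # one sample in cell (bit1, group1): its scaled effort is the cell mean
  s <- hand_samples(action_id = c(1, 2, 2),
                    raw_effort = c(10, 4, 6),
                    cur = list(belief_1 = c(5, -5, -5)))
  spec <- hand_spec()
  em <- fit_effort_model(s, cat_, feats, spec)
  pop <- mean(c(10, 4, 6))
  expect_equal(em$population_mean_raw, pop)
  expect_equal(unname(em$mean_scaled[2, 1]), 1.0)  # raw 10 -> scaled 1
  expect_equal(unname(em$mean_scaled[1, 2]),
               mean(scale_effort(c(4, 6), pop)))
  # empty cell falls back to the group mean
  expect_true(em$fallback[1, 1])
  expect_equal(unname(em$mean_scaled[1, 1]), 1.0)  # group 1's only sample
  expect_error(fit_effort_model(s[0, ], cat_, feats, spec), "empty")
})

test_that("transition model counts per-feature next-bit fractions", {
  cat_ <- tiny_catalog(n_prep = 2, n_clusters = 2)
  feats <- c("belief_1")
  # 4 transitions from bit 1 under group 1: three end at 1 -> 0.75
  s <- hand_samples(action_id = rep(1, 4), raw_effort = rep(5, 4),
                    cur = list(belief_1 = rep(5, 4)),
                    nxt = list(belief_1 = c(5, 5, 5, -5)))
  spec <- hand_spec()
  tm <- fit_transition_model(s, cat_, feats, spec)
  expect_equal(tm$prob["belief_1", "bit1", 1], 0.75)
  # unseen cells use the documented 0.5 fallback
  expect_equal(tm$prob["belief_1", "bit0", 2], 0.5)
  expect_true(tm$fallback["belief_1", "bit0", 2])
  # a feature constant at bit 1 self-transitions with probability 1
  s2 <- hand_samples(action_id = rep(1, 3), raw_effort = rep(5, 3),
                     cur = list(belief_2 = rep(5, 3)),
                     nxt = list(belief_2 = rep(5, 3)))
  tm2 <- fit_transition_model(s2, cat_, "belief_2", spec)
  expect_equal(tm2$prob["belief_2", "bit1", 1], 1)
})

test_that("estimation is invariant to sample order and person relabeling", {
  cat_ <- tiny_catalog(n_prep = 4, n_clusters = 2, n_pers = 1)
  set.seed(21)
  n <- 400
  s <- hand_samples(action_id = sample(1:5, n, replace = TRUE),
                    raw_effort = sample(0:10, n, replace = TRUE),
                    cur = list(belief_1 = sample(c(-5, 5), n, TRUE),
                               energy = sample(c(2, 8), n, TRUE)),
                    nxt = list(belief_1 = sample(c(-5, 5), n, TRUE)))
  spec <- hand_spec(list(energy = 5))
  feats <- c("belief_1", "energy")
  perm <- sample(n)
  s_perm <- s[perm, ]
  s_perm$person_id <- paste0("P", s_perm$person_id)
  em1 <- fit_effort_model(s, cat_, feats, spec)
  em2 <- fit_effort_model(s_perm, cat_, feats, spec)
  expect_equal(em1$mean_scaled, em2$mean_scaled)
  tm1 <- fit_transition_model(s, cat_, feats, spec)
  tm2 <- fit_transition_model(s_perm, cat_, feats, spec)
  expect_equal(tm1$prob, tm2$prob)
})

test_that("fitted dynamics serialize to JSON losslessly", {
  cat_ <- tiny_catalog(n_prep = 2, n_clusters = 2, n_pers = 1)
  s <- hand_samples(action_id = c(1, 2, 3, 1), raw_effort = c(2, 8, 5, 7),
                    cur = list(belief_1 = c(5, -5, 5, -5)),
                    nxt = list(belief_1 = c(5, 5, -5, -5)))
  spec <- hand_spec()
  em <- fit_effort_model(s, cat_, "belief_1", spec)
  tm <- fit_transition_model(s, cat_, "belief_1", spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_dynamics_models(em, tm, path)
  back <- read_dynamics_models(path)
  expect_equal(back$effort$mean_scaled, em$mean_scaled)
  expect_equal(back$effort$population_mean_raw, em$population_mean_raw)
  expect_equal(back$transition$prob, tm$prob)
  expect_equal(back$transition$features, tm$features)
})
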