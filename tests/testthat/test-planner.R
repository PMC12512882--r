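test_that("state enumeration is a bijection of the documented size", {
  sp <- state_space()
  expect_equal(sp$n_states, 32768L)
  expect_equal(sp$n_uf, 8L)
  expect_equal(sp$n_ec, 4096L)
  expect_equal(state_space(1, 1, 2)$n_states, 4L)
  # round-trip index -> state -> index on random states
  set.seed(5)
  idx <- sample.int(sp$n_states, 100)
  dec <- decode_state(sp, idx)
  expect_equal(encode_state(sp, dec$uf_bits, dec$ec_digits), idx)
  expect_error(state_space(10, 10, 10), "too large")
})

test_that("the assembled MDP has the documented factored structure", {
  cat_ <- tiny_catalog(n_prep = 3, n_clusters = 2, n_pers = 1)
  mods <- hand_models(cat_, features = "belief_1", effort_value = 0.5,
                      trans_p = 0.5)
  # hand-set asymmetric transitions for the single feature
  mods$transition$prob["belief_1", "bit0", ] <- 0.2
  mods$transition$prob["belief_1", "bit1", ] <- 0.9
  mdp <- build_mdp(mods$effort, mods$transition, cat_, gamma = 0.85)
  sp <- mdp$space
  expect_equal(sp$n_states, 2L * 4096L)

  # persuasive action: reward 0 and unchanged competencies in every state
  pers_col <- which(cat_$kind == "persuasive")
  expect_true(all(mdp$R[, pers_col] == 0))
  some_states <- c(1L, 500L, 4096L, 4097L, 8192L)
  expect_equal(mdp$ecnext[some_states, pers_col],
               (some_states - 1L) %% sp$n_ec)

  # all competencies built: no reward for any action
  full_ec <- encode_state(sp, 0L, rep(3L, 6))
  expect_true(all(mdp$R[full_ec, ] == 0))

  # successor uf distribution is the product of per-feature Bernoullis
  expect_equal(mdp$uf_next_prob[1, 1, ], c(0.8, 0.2))  # current bit 0
  expect_equal(mdp$uf_next_prob[2, 1, ], c(0.1, 0.9))  # current bit 1

  # reward in the all-zero state equals the direct arithmetic
  s0 <- encode_state(sp, 0L, rep(0L, 6))
  a1 <- 1L
  expect_equal(mdp$R[s0, a1],
               compute_reward(contributions(cat_)[a1, ], 0.5, rep(0, 6)))
})

test_that("factored next-uf marginals reproduce the transition model cells", {
  cat_ <- tiny_catalog(n_prep = 4, n_clusters = 2, n_pers = 2)
  mods <- hand_models(cat_, features = c("belief_1", "belief_7", "energy"))
  set.seed(8)
  mods$transition$prob[] <- runif(length(mods$transition$prob), 0.1, 0.9)
  mdp <- build_mdp(mods$effort, mods$transition, cat_)
  sp <- mdp$space
  bits <- sp$uf_bits
  for (u in seq_len(sp$n_uf)) {
    for (g in seq_len(dim(mods$transition$prob)[3])) {
      marg <- vapply(1:3, function(f) {
        sum(mdp$uf_next_prob[u, g, bits[, f] == 1L])
      }, numeric(1))
      want <- vapply(1:3, function(f) {
        mods$transition$prob[f, bits[u, f] + 1L, g]
      }, numeric(1))
      expect_equal(marg, want)
    }
  }
})

test_that("Gauss-Seidel VI matches a brute-force synchronous oracle", {
  # sup-norm stopping bounds the value error; the span default must agree
  # on the greedy policy
  for (seed in 1:6) {
    S <- sample(c(20, 50, 120), 1)
    mdp <- random_tabular_mdp(S = S, A = 4, gamma = 0.9, seed = seed)
    vstar <- oracle_sync_vi(mdp$P, mdp$R, mdp$gamma)
    b_sup <- gauss_seidel_vi(mdp, epsilon = 1e-3, criterion = "supnorm")
    expect_lt(max(abs(b_sup$V - vstar)), 1e-3)
    b_span <- gauss_seidel_vi(mdp, epsilon = 1e-3)
    expect_equal(apply(b_span$Q, 1, which.max), apply(b_sup$Q, 1, which.max))
  }
})

test_that("VI limits: myopic at gamma 0 and geometric series for one action", {
  mdp0 <- random_tabular_mdp(S = 30, A = 3, gamma = 0, seed = 7)
  b0 <- gauss_seidel_vi(mdp0)
  expect_equal(b0$Q, mdp0$R)
  # single action, constant reward r: V = r / (1 - gamma)
  r <- 0.7; gamma <- 0.85
  P <- list(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  mdp1 <- tabular_mdp(P, matrix(r, 2, 1), gamma)
  b1 <- gauss_seidel_vi(mdp1, epsilon = 1e-6, criterion = "supnorm")
  expect_equal(b1$V, rep(r / (1 - gamma), 2), tolerance = 1e-4)
  # invalid transition rows are rejected before iterating
  expect_error(tabular_mdp(list(matrix(c(0.5, 0.4, 0.2, 0.8), 2, 2)),
                           matrix(0, 2, 1), 0.9), "sum to 1")
})

test_that("factored and generic kernels agree on a small factored MDP", {
  cat_ <- tiny_catalog(n_prep = 3, n_clusters = 2, n_pers = 1)
  mods <- hand_models(cat_, features = "belief_1")
  mods$transition$prob["belief_1", "bit0", ] <- 0.3
  mods$transition$prob["belief_1", "bit1", ] <- 0.8
  mods$effort$mean_scaled[1, ] <- 0.4
  mods$effort$mean_scaled[2, ] <- 0.7
  mdp <- build_mdp(mods$effort, mods$transition, cat_, gamma = 0.8)
  sp <- mdp$space
  # expand the factored successors into the generic ragged-sparse layout
  A <- nrow(cat_)
  n_pairs <- sp$n_states * A
  succ <- integer(n_pairs * sp$n_uf)
  prob <- numeric(n_pairs * sp$n_uf)
  k <- 0L
  for (s in seq_len(sp$n_states)) {
    u <- (s - 1L) %/% sp$n_ec + 1L
    for (a in seq_len(A)) {
      for (un in seq_len(sp$n_uf)) {
        k <- k + 1L
        succ[k] <- (un - 1L) * sp$n_ec + mdp$ecnext[s, a]     # 0-based
        prob[k] <- mdp$uf_next_prob[u, mdp$group[a], un]
      }
    }
  }
  offset <- as.integer(seq(0L, n_pairs * sp$n_uf, by = sp$n_uf))
  generic <- quitprep:::gs_vi_sparse_cpp(mdp$R, succ, prob, offset, mdp$gamma,
                                         1e-4, 10000L, FALSE)
  bf <- gauss_seidel_vi(mdp, epsilon = 1e-4, criterion = "supnorm")
  expect_equal(bf$V, generic$V, tolerance = 1e-6)
  expect_equal(bf$Q, generic$Q, tolerance = 1e-6)
})

test_that("the no-repeat advisor walks down the Q ranking", {
  Q <- matrix(c(5, 9, 7, 1,
                2, 2, 8, 3), 2, 4, byrow = TRUE)
  bundle <- structure(list(Q = Q, action_ids = c(10L, 20L, 30L, 40L)),
                      class = "policy_bundle")
  expect_equal(next_best_action(bundle, 1), 20L)
  expect_equal(next_best_action(bundle, 1, history = 20L), 30L)
  # sequential proposals are distinct and exhaust the catalog
  hist <- integer(0)
  for (i in 1:4) hist <- c(hist, next_best_action(bundle, 2, hist))
  expect_equal(sort(hist), c(10L, 20L, 30L, 40L))
  expect_equal(hist[1], 30L)
  # ties resolve to the lowest action id
  expect_equal(next_best_action(bundle, 2, history = 30L), 40L)
  bundle$Q[2, ] <- c(4, 4, 4, 4)
  expect_equal(next_best_action(bundle, 2), 10L)
  expect_error(next_best_action(bundle, 1, history = c(10L, 20L, 30L, 40L)),
               "exhausts")
})
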