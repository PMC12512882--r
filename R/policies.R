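#' Build one of the six ablation policies
#'
#' The ablation removes increasingly more model components:
#' \describe{
#'   \item{`full`}{value iteration on the complete factored MDP.}
#'   \item{`no_next_uf`}{value iteration with the learned next
#'     user-feature transitions replaced by a uniform distribution
#'     (every feature moves to 0 or 1 with probability 0.5).}
#'   \item{`myopic`}{a contextual bandit on the full state: argmax of the
#'     immediate reward, no future terms.}
#'   \item{`ec_only`}{a bandit that sees only the competency levels: the
#'     effort is marginalized over the user-feature configurations with
#'     the observed population weights.}
#'   \item{`uf_only`}{a bandit that sees only the user features: one of
#'     the activities in the preparatory cluster with the highest expected
#'     effort is picked at random.}
#'   \item{`random`}{uniform over the preparatory activities.}
#' }
#'
#' @param variant One of the labels above.
#' @param effort An `effort_model`.
#' @param transition A `transition_model`.
#' @param catalog An `activity_catalog`.
#' @param gamma Discount factor for the planning variants (default 0.85).
#' @param epsilon Value-iteration tolerance (default 0.001).
#' @param ties Grid snapping midpoint rule.
#' @return Object of class `policy_variant`.
#' @export
make_policy <- function(variant = c("full", "no_next_uf", "myopic", "ec_only",
                                    "uf_only", "random"),
                        effort, transition, catalog, gamma = 0.85,
                        epsilon = 0.001, ties = "up") {
  variant <- match.arg(variant)
  ag <- action_groups(catalog)
  base <- list(label = variant, action_ids = catalog$id,
               preparatory = catalog$kind == "preparatory")
  out <- switch(variant,
    full = {
      mdp <- build_mdp(effort, transition, catalog, gamma = gamma, ties = ties)
      b <- gauss_seidel_vi(mdp, epsilon = epsilon, variant = variant)
      c(base, list(kind = "q", Q = b$Q, bundle_meta = b[c("iterations", "converged")]))
    },
    no_next_uf = {
      uni <- transition
      uni$prob[] <- 0.5
      mdp <- build_mdp(effort, uni, catalog, gamma = gamma, ties = ties)
      b <- gauss_seidel_vi(mdp, epsilon = epsilon, variant = variant)
      c(base, list(kind = "q", Q = b$Q, bundle_meta = b[c("iterations", "converged")]))
    },
    myopic = {
      mdp <- build_mdp(effort, transition, catalog, gamma = gamma, ties = ties)
      c(base, list(kind = "q", Q = mdp$R))
    },
    ec_only = {
      w <- rowSums(effort$counts)
      w <- if (sum(w) > 0) w / sum(w) else rep(1 / nrow(effort$mean_scaled), nrow(effort$mean_scaled))
      marg <- effort
      marg$mean_scaled[] <- rep(colSums(effort$mean_scaled * w), each = nrow(effort$mean_scaled))
      mdp <- build_mdp(marg, transition, catalog, gamma = gamma, ties = ties)
      c(base, list(kind = "q", Q = mdp$R))
    },
    uf_only = {
      prep_groups <- which(ag$preparatory)
      c(base, list(kind = "cluster_effort", effort_matrix = effort$mean_scaled,
                   prep_groups = prep_groups, group = ag$group))
    },
    random = c(base, list(kind = "uniform_prep")))
  structure(out, class = "policy_variant")
}

#' Initial user-feature distribution
#'
#' The simulated cohort starts with all competencies at level 0 and
#' user-feature configurations distributed as observed in the first
#' session of the training log.
#'
#' @param log Interaction log data frame.
#' @param spec A [binarization_spec()].
#' @param features Selected feature names (order fixes the configuration
#'   index).
#' @return Object of class `initial_uf`: probability vector over the
#'   2^m configurations.
#' @export
estimate_initial_uf <- function(log, spec, features) {
  first <- log[log$session == 1L, , drop = FALSE]
  if (nrow(first) == 0L) stop("log has no session-1 rows")
  cfg <- uf_config_index(binarize_features(first, spec, features))
  n_cfg <- 2L^length(features)
  p <- tabulate(cfg, nbins = n_cfg) / nrow(first)
  structure(p, class = "initial_uf", features = features)
}

#' Simulate a cohort under one policy
#'
#' Each simulated person starts with all competencies at 0 and a
#' user-feature configuration drawn from `init`. At each step the policy
#' proposes an activity not yet proposed to that person (no-repeat rule;
#' the random variants sample without replacement), the person spends the
#' environment's mean unit effort for their configuration and the
#' activity's group, competencies update deterministically, and the next
#' user-feature configuration is drawn from the learned transition model.
#' The environment (effort + transitions) is the full learned model for
#' every policy variant, and the random streams are pre-drawn per
#' person/step so that identical action choices imply identical
#' user-feature trajectories across variants.
#'
#' @param policy A [make_policy()] `policy_variant`.
#' @param effort Environment `effort_model`.
#' @param transition Environment `transition_model`.
#' @param catalog An `activity_catalog`.
#' @param init An [estimate_initial_uf()] distribution.
#' @param n_people Cohort size (default 1000).
#' @param horizon Number of proposed activities per person (default 5).
#' @param seed Integer seed.
#' @param effort_mode `"mean"` (default; deterministic mean effort) or
#'   `"sampled"` (truncated-normal draw around the cell mean, sensitivity
#'   mode).
#' @param effort_sd Unit-scale standard deviation for `"sampled"` mode.
#' @param normalize `"ceiling"` (default): fraction of the six-competency
#'   ceiling; `"reachable"`: fraction of the best total achievable within
#'   `horizon` unit-effort activities (greedy bound).
#' @return Object of class `simulation_result`: list with `fraction_built`
#'   (steps 0..horizon), `mc_se`, `per_person` (people x steps matrix of
#'   fractions), `actions` (people x horizon matrix of proposed activity
#'   ids), `variant`, `n_people`, `horizon`, `seed`, `normalize`.
#' @export
simulate_cohort <- function(policy, effort, transition, catalog, init,
                            n_people = 1000, horizon = 5, seed = 1,
                            effort_mode = c("mean", "sampled"),
                            effort_sd = 0.15,
                            normalize = c("ceiling", "reachable")) {
  effort_mode <- match.arg(effort_mode)
  normalize <- match.arg(normalize)
  if (horizon < 1) stop("horizon must be at least 1")
  ag <- action_groups(catalog)
  n_prep <- sum(catalog$kind == "preparatory")
  max_actions <- if (policy$kind %in% c("uniform_prep", "cluster_effort")) n_prep else nrow(catalog)
  if (horizon > max_actions) stop("horizon exceeds the number of distinct proposable activities")
  m <- length(effort$features)
  space <- state_space(n_uf_bits = m)
  cont <- contributions(catalog)
  n_levels <- space$n_levels
  radix <- n_levels^(seq_len(space$n_competencies) - 1L)

  set.seed(seed)
  u_init <- runif(n_people)
  u_action <- matrix(runif(n_people * horizon), n_people, horizon)
  u_trans <- array(runif(n_people * horizon * m), c(n_people, horizon, m))
  z_effort <- if (effort_mode == "sampled") {
    matrix(rnorm(n_people * horizon), n_people, horizon)
  } else NULL

  cum_init <- cumsum(init)
  frac <- matrix(0, n_people, horizon + 1L)
  actions <- matrix(NA_integer_, n_people, horizon)
  for (p in seq_len(n_people)) {
    uf <- findInterval(u_init[p], cum_init, left.open = TRUE) + 1L
    digits <- integer(space$n_competencies)
    history <- integer(0)
    for (t in seq_len(horizon)) {
      a <- choose_action(policy, uf, digits, history, space, radix, u_action[p, t])
      g <- ag$group[a]
      e <- effort$mean_scaled[uf, g]
      if (effort_mode == "sampled") {
        e <- min(max(e + effort_sd * z_effort[p, t], 0), 1)
      }
      lut_levels <- snap_to_level_grid(pmin(digits / (n_levels - 1) + e * cont[a, ], 1))
      digits <- as.integer(round(lut_levels * (n_levels - 1)))
      history <- c(history, a)
      actions[p, t] <- catalog$id[a]
      frac[p, t + 1L] <- sum(digits) / ((n_levels - 1) * space$n_competencies)
      bits <- space$uf_bits[uf, ]
      p1 <- vapply(seq_len(m), function(f) transition$prob[f, bits[f] + 1L, g], numeric(1))
      bits <- as.integer(u_trans[p, t, ] < p1)
      uf <- uf_config_index(matrix(bits, nrow = 1))
    }
  }
  denom <- if (normalize == "reachable") max_reachable_fraction(catalog, horizon) else 1
  frac <- frac / denom
  structure(list(fraction_built = colMeans(frac),
                 mc_se = apply(frac, 2, sd) / sqrt(n_people),
                 per_person = frac, actions = actions,
                 variant = policy$label, n_people = n_people,
                 horizon = horizon, seed = seed, normalize = normalize),
            class = "simulation_result")
}

choose_action <- function(policy, uf, digits, history, space, radix, u) {
  idx <- seq_along(policy$action_ids)
  allowed <- idx[!(idx %in% history)]
  if (policy$kind == "q") {
    s <- (uf - 1L) * space$n_ec + as.integer(digits %*% radix) + 1L
    return(allowed[which.max(policy$Q[s, allowed])])
  }
  if (policy$kind == "uniform_prep") {
    pool <- allowed[policy$preparatory[allowed]]
    return(pool[floor(u * length(pool)) + 1L])
  }
  if (policy$kind == "cluster_effort") {
    ord <- policy$prep_groups[order(policy$effort_matrix[uf, policy$prep_groups],
                                    decreasing = TRUE)]
    for (g in ord) {
      pool <- allowed[policy$group[allowed] == g]
      if (length(pool)) return(pool[floor(u * length(pool)) + 1L])
    }
    stop("no preparatory activity left to propose")
  }
  stop("unknown policy kind")
}

# Best total competency mass achievable within `horizon` unit-effort
# activities, found greedily; used for the alternative curve normalization.
max_reachable_fraction <- function(catalog, horizon) {
  cont <- contributions(catalog)
  levels <- rep(0, ncol(cont))
  used <- integer(0)
  for (t in seq_len(horizon)) {
    gains <- vapply(seq_len(nrow(cont)), function(a) {
      if (a %in% used) return(-Inf)
      compute_reward(cont[a, ], 1, levels)
    }, numeric(1))
    a <- which.max(gains)
    levels <- update_competencies(levels, 1, cont[a, ])
    used <- c(used, a)
  }
  max(sum(levels) / ncol(cont), .Machine$double.eps)
}

#' Robustness of the simulation to training-data subsets
#'
#' Refits the dynamics on stratified subsamples (per action) of the
#' interaction samples, re-plans the chosen policy variant, and re-runs the
#' cohort simulation once per replicate.
#'
#' @param samples An [interaction_samples()] table.
#' @param catalog An `activity_catalog`.
#' @param spec A [binarization_spec()].
#' @param features Selected feature names.
#' @param init An `initial_uf` distribution.
#' @param keep_fraction Fraction of samples kept per action (default 0.95).
#' @param n_reps Number of replicates (default 3).
#' @param seeds Integer vector of length `n_reps` (default `1:n_reps`).
#' @param variant Policy variant to re-plan (default `"full"`).
#' @param gamma,epsilon,n_people,horizon Passed through to planning and
#'   simulation.
#' @return List of `simulation_result`, one per replicate.
#' @export
robustness_resample <- function(samples, catalog, spec, features, init,
                                keep_fraction = 0.95, n_reps = 3,
                                seeds = seq_len(n_reps), variant = "full",
                                gamma = 0.85, epsilon = 0.001,
                                n_people = 1000, horizon = 5) {
  if (keep_fraction <= 0 || keep_fraction > 1) stop("keep_fraction must lie in (0, 1]")
  stopifnot(length(seeds) == n_reps)
  lapply(seq_len(n_reps), function(r) {
    set.seed(seeds[r])
    keep <- unlist(lapply(split(seq_len(nrow(samples)), samples$action_id), function(ix) {
      n_keep <- max(1L, round(keep_fraction * length(ix)))
      if (n_keep == length(ix)) ix else sample(ix, n_keep)
    }))
    sub <- samples[sort(keep), , drop = FALSE]
    eff <- fit_effort_model(sub, catalog, features, spec)
    trans <- fit_transition_model(sub, catalog, features, spec)
    pol <- make_policy(variant, eff, trans, catalog, gamma = gamma, epsilon = epsilon)
    simulate_cohort(pol, eff, trans, catalog, init,
                    n_people = n_people, horizon = horizon, seed = seeds[r])
  })
}

#' Discount-factor sensitivity sweep
#'
#' Re-plans the full policy for each discount factor and re-simulates the
#' cohort in the fixed learned environment.
#'
#' @param gammas Numeric vector of discount factors in \[0, 1).
#' @inheritParams simulate_cohort
#' @param epsilon Value-iteration tolerance.
#' @return Named list of `simulation_result`, one per gamma.
#' @export
gamma_sweep <- function(gammas, effort, transition, catalog, init,
                        epsilon = 0.001, n_people = 1000, horizon = 5,
                        seed = 1) {
  if (any(gammas < 0) || any(gammas >= 1)) stop("each gamma must lie in [0, 1)")
  res <- lapply(gammas, function(g) {
    pol <- make_policy("full", effort, transition, catalog,
                       gamma = g, epsilon = epsilon)
    simulate_cohort(pol, effort, transition, catalog, init,
                    n_people = n_people, horizon = horizon, seed = seed)
  })
  names(res) <- as.character(gammas)
  res
}
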