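#' Configuration for the synthetic interaction-log generator
#'
#' Defaults emulate the training study: 542 people with at least one
#' usable session pair, up to five sessions, and attrition calibrated so
#' that roughly 64% of them complete session 5 (continuation probability
#' 0.86 per session from session 3 on), which lands the sample count near
#' the study's 1710 state-action-effort-next-state tuples. Target raw
#' effort moments are mean 5.58, SD 2.86 on the 0--10 scale.
#'
#' @param n_people Number of people contributing to the log (default 542).
#' @param max_sessions Maximum sessions per person (default 5).
#' @param continuation Probability of attending each session after the
#'   second (default 0.86; set to 1 for no dropout).
#' @param null_effects If `TRUE`, all effort cells share one mean and no
#'   feature carries an effect (for null-calibration tests).
#' @param effort_mean_target,effort_sd_target Raw-scale effort moments.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_people = 542, max_sessions = 5,
                             continuation = 0.86, null_effects = FALSE,
                             effort_mean_target = 5.58,
                             effort_sd_target = 2.86) {
  stopifnot(n_people >= 1, max_sessions >= 1,
            continuation > 0, continuation <= 1)
  structure(list(n_people = as.integer(n_people),
                 max_sessions = as.integer(max_sessions),
                 continuation = continuation, null_effects = null_effects,
                 effort_mean_target = effort_mean_target,
                 effort_sd_target = effort_sd_target),
            class = "synthetic_config")
}

# Features given a real effect on effort in the synthetic ground truth,
# mirroring the three features the study model conditions on.
informative_features <- function() c("belief_1", "belief_7", "energy")

#' Draw a synthetic ground truth
#'
#' Generates the population parameters the estimation stage is supposed to
#' recover: per-cell raw effort means (additive in three informative
#' binary features, with a dominant first feature), a shared within-cell
#' effort SD calibrated to the target population SD, per-feature binary
#' transition probabilities with persistence, initial feature
#' probabilities, and raw belief-drift magnitudes for the nine persuasive
#' activities. Action groups follow the fixture catalog convention: groups
#' 1--5 are the preparatory clusters and groups 5 + b (b = 1..9) are the
#' persuasive activities targeting belief b.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: list with `effort_cell_mean`
#'   (8 x 14, rows = configurations of the informative features),
#'   `effort_sd`, `feature_deltas`, `trans_prob` (11 features x 2 bits x
#'   14 groups), `init_p`, `belief_drift` (9), `informative`, `config`.
#' @export
generate_ground_truth <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  n_groups <- 14L
  feats <- feature_columns()
  deltas <- setNames(rep(0, length(feats)), feats)
  if (config$null_effects) {
    base <- rep(config$effort_mean_target, n_groups)
  } else {
    deltas[informative_features()] <- c(2.5, 1.0, 0.7)
    # base chosen so that the half-on average of the deltas recentres the
    # population mean on the target
    centre <- config$effort_mean_target - sum(deltas) / 2
    base <- runif(n_groups, centre - 0.3, centre + 0.3)
  }
  bits <- uf_config_bits(3L)
  cell_mean <- outer(rep(1, 8L), base) +
    matrix(bits %*% deltas[informative_features()], 8L, n_groups)
  effort_sd <- calibrate_effort_sd(cell_mean, config$effort_sd_target)
  # recentre for the mean shift the 0..10 truncation induces
  for (i in 1:3) {
    realized <- mean(vapply(as.vector(cell_mean), function(mu) {
      sum(0:10 * effort_pmf(mu, effort_sd))
    }, numeric(1)))
    cell_mean <- pmin(pmax(cell_mean + (config$effort_mean_target - realized), 0), 10)
  }

  trans_prob <- array(NA_real_, c(length(feats), 2L, n_groups),
                      dimnames = list(feats, c("bit0", "bit1"), NULL))
  trans_prob[, 1, ] <- runif(length(feats) * n_groups, 0.25, 0.45)
  trans_prob[, 2, ] <- runif(length(feats) * n_groups, 0.55, 0.75)
  belief_drift <- runif(9, 1, 3)
  if (config$null_effects) belief_drift[] <- 0
  for (b in 1:9) {
    g <- 5L + b
    trans_prob[paste0("belief_", b), 1, g] <- runif(1, 0.45, 0.60)
    trans_prob[paste0("belief_", b), 2, g] <- runif(1, 0.75, 0.90)
  }
  init_p <- setNames(runif(length(feats), 0.45, 0.55), feats)
  structure(list(effort_cell_mean = cell_mean, effort_sd = effort_sd,
                 feature_deltas = deltas, trans_prob = trans_prob,
                 init_p = init_p, belief_drift = belief_drift,
                 informative = informative_features(), config = config),
            class = "ground_truth")
}

# discretized truncated normal pmf on the integers 0..10
effort_pmf <- function(mean, sd) {
  r <- 0:10
  w <- pnorm(r + 0.5, mean, sd) - pnorm(r - 0.5, mean, sd)
  w / sum(w)
}

# within-cell SD chosen so that the realized population SD of the
# discretized, truncated effort distribution (which sheds tail variance)
# matches the target; deterministic, no sampling involved
calibrate_effort_sd <- function(cell_means, target_sd) {
  m <- as.vector(cell_means)
  excess <- function(s) {
    mus <- vapply(m, function(mu) sum(0:10 * effort_pmf(mu, s)), numeric(1))
    wvar <- vapply(seq_along(m), function(i) {
      sum((0:10 - mus[i])^2 * effort_pmf(m[i], s))
    }, numeric(1))
    mean(wvar) + mean((mus - mean(mus))^2) - target_sd^2
  }
  if (excess(6) < 0) return(6)
  stats::uniroot(excess, c(0.3, 6), tol = 1e-4)$root
}

#' Exact cell-level expectations implied by a ground truth
#'
#' Returns, for each (configuration, group) cell, the expectation of the
#' unit-scaled effort under the generator's discretized effort
#' distribution, using the ground truth's implied population mean raw
#' effort as the scaling anchor. This is the quantity
#' [fit_effort_model()] estimates.
#'
#' @param truth A `ground_truth`.
#' @return List with `mean_scaled` (8 x 14) and `population_mean_raw`.
#' @export
true_mean_scaled_effort <- function(truth) {
  cm <- truth$effort_cell_mean
  raw_means <- matrix(vapply(seq_along(cm), function(i) {
    sum(0:10 * effort_pmf(cm[i], truth$effort_sd))
  }, numeric(1)), nrow(cm), ncol(cm))
  pop_mean <- mean(raw_means)
  scaled <- matrix(vapply(seq_along(cm), function(i) {
    sum(effort_pmf(cm[i], truth$effort_sd) * scale_effort(0:10, pop_mean))
  }, numeric(1)), nrow(cm), ncol(cm))
  list(mean_scaled = scaled, population_mean_raw = pop_mean)
}

# raw integer value consistent with a bit: beliefs live in -10..-1 / 1..10,
# energy and time in 0..4 / 6..10. The gap at the threshold keeps the
# sample-mean binarization faithful to the generative bits.
raw_from_bits <- function(bits, feature, shift = 0) {
  n <- length(bits)
  if (grepl("^belief_", feature)) {
    raw <- ifelse(bits == 1L, sample(1:10, n, replace = TRUE),
                  sample(-10:-1, n, replace = TRUE))
    raw <- raw + round(shift)
    ifelse(bits == 1L, pmin(raw, 10L), pmin(raw, -1L))
  } else {
    raw <- ifelse(bits == 1L, sample(6:10, n, replace = TRUE),
                  sample(0:4, n, replace = TRUE))
    ifelse(bits == 1L, pmin(raw, 10L), pmin(raw, 4L))
  }
}

#' Generate a synthetic micro-randomized interaction log
#'
#' Emulates the training study: in every attended session the coach
#' records the person's eleven user-inquired features, picks uniformly at
#' random one of the 14 action groups (5 preparatory clusters, 9
#' persuasive activities) and, within a cluster, uniformly one of its
#' activities. Raw effort for the proposed activity is drawn from the
#' ground truth's discretized cell distribution and reported in the next
#' session; binary features transition per the ground truth, and a
#' persuasive activity additionally drifts its targeted belief's raw value
#' upward. People always attend the first two sessions and continue with
#' the configured probability afterwards.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param catalog An `activity_catalog` following the fixture convention
#'   (see [fixture_activity_catalog()]).
#' @param seed Integer seed.
#' @return Interaction log data frame: `person_id`, `session`, the
#'   [feature_columns()], `action_id`, `raw_effort` (`NA` in a person's
#'   final attended session, where the report is never collected).
#' @export
generate_mrt_log <- function(truth, catalog, seed = 1) {
  config <- truth$config
  set.seed(seed)
  n <- config$n_people
  S <- config$max_sessions
  feats <- feature_columns()
  ag <- action_groups(catalog)
  group_members <- split(seq_len(nrow(catalog)), ag$group)
  pers_target <- setNames(catalog$target_belief[catalog$kind == "persuasive"],
                          catalog$id[catalog$kind == "persuasive"])
  inf_idx <- match(truth$informative, feats)

  attend <- matrix(FALSE, n, S)
  attend[, seq_len(min(2L, S))] <- TRUE
  if (S >= 3L) for (t in 3:S) {
    attend[, t] <- attend[, t - 1L] & (runif(n) < config$continuation)
  }
  bits <- vapply(feats, function(f) rbinom(n, 1L, truth$init_p[[f]]), integer(n))
  pending_shift <- matrix(0, n, 9)

  rows <- vector("list", S)
  effort_store <- matrix(NA_real_, n, S)   # effort on the session-t activity
  action_store <- matrix(NA_integer_, n, S)
  for (t in seq_len(S)) {
    alive <- which(attend[, t])
    if (!length(alive)) break
    raw <- matrix(NA_integer_, length(alive), length(feats),
                  dimnames = list(NULL, feats))
    for (f in seq_along(feats)) {
      b_idx <- if (grepl("^belief_", feats[f])) as.integer(sub("belief_", "", feats[f])) else NA
      shift <- if (!is.na(b_idx)) pending_shift[alive, b_idx] else 0
      raw[, f] <- raw_from_bits(bits[alive, f], feats[f], shift)
    }
    pending_shift[alive, ] <- 0
    grp <- sample.int(14L, length(alive), replace = TRUE)
    act <- vapply(grp, function(g) {
      mem <- group_members[[g]]
      mem[sample.int(length(mem), 1L)]
    }, integer(1))
    action_store[alive, t] <- act
    cfg <- uf_config_index(bits[alive, inf_idx, drop = FALSE])
    for (cell in unique(cfg * 100L + grp)) {
      in_cell <- which(cfg * 100L + grp == cell)
      u <- (cell %/% 100L); g <- cell %% 100L
      pmf <- effort_pmf(truth$effort_cell_mean[u, g], truth$effort_sd)
      effort_store[alive[in_cell], t] <- sample(0:10, length(in_cell),
                                                replace = TRUE, prob = pmf)
    }
    rows[[t]] <- data.frame(person_id = alive, session = t, raw,
                            action_id = catalog$id[act],
                            raw_effort = NA_real_)
    # feature transitions toward session t + 1
    for (f in seq_along(feats)) {
      p1 <- truth$trans_prob[f, bits[alive, f] + 1L, ]
      p1 <- p1[cbind(seq_along(alive), grp)]
      bits[alive, f] <- as.integer(runif(length(alive)) < p1)
    }
    is_pers <- catalog$kind[act] == "persuasive"
    if (any(is_pers)) {
      tgt <- pers_target[as.character(catalog$id[act[is_pers]])]
      pend_rows <- alive[is_pers]
      pending_shift[cbind(pend_rows, tgt)] <-
        truth$belief_drift[match(catalog$id[act[is_pers]],
                                 catalog$id[catalog$kind == "persuasive"])]
    }
  }
  log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  # effort spent on session t's activity is reported in session t + 1
  for (t in seq_len(S - 1L)) {
    reported <- attend[, t] & attend[, t + 1L]
    sel <- log$session == t & log$person_id %in% which(reported)
    log$raw_effort[sel] <- effort_store[log$person_id[sel], t]
  }
  log <- log[order(log$person_id, log$session), ]
  rownames(log) <- NULL
  log
}

#' Synthetic activity catalog fixture
#'
#' A synthetic stand-in for the study's 53-activity catalog: 44
#' preparatory activities in 5 clusters with sparse contribution profiles
#' (every competency is reachable with contribution > 0.5, and two
#' competencies are reachable through a single cluster only), plus 9
#' persuasive activities targeting beliefs 1..9 with all-zero
#' contributions. Contribution values are generated, not the study's
#' expert-derived ones.
#'
#' @param seed Integer seed for the contribution jitter.
#' @return An `activity_catalog`.
#' @export
fixture_activity_catalog <- function(seed = 1) {
  set.seed(seed)
  sizes <- c(10, 9, 9, 8, 8)
  profile <- rbind(c(0.9, 0.0, 0.3, 0.0, 0.2, 0.0),
                   c(0.0, 0.9, 0.0, 0.3, 0.0, 0.0),
                   c(0.3, 0.0, 0.8, 0.0, 0.0, 0.3),
                   c(0.0, 0.0, 0.0, 0.8, 0.6, 0.0),
                   c(0.2, 0.0, 0.0, 0.0, 0.0, 0.9))
  cluster <- rep(1:5, sizes)
  cont <- profile[cluster, ] * matrix(runif(44 * 6, 0.85, 1.15), 44, 6)
  cont <- pmin(pmax(cont, 0), 1)
  prep <- data.frame(id = 1:44,
                     name = sprintf("synthetic preparatory activity %02d", 1:44),
                     kind = "preparatory", cluster = cluster)
  prep[contribution_columns()] <- round(cont, 4)
  prep$target_belief <- NA_integer_
  pers <- data.frame(id = 45:53,
                     name = sprintf("synthetic persuasive activity (belief %d)", 1:9),
                     kind = "persuasive", cluster = NA_integer_)
  pers[contribution_columns()] <- 0
  pers$target_belief <- 1:9
  activity_catalog(rbind(prep, pers))
}

#' Synthetic smoker-rating matrix for the preparatory activities
#'
#' Ratings of how much each preparatory activity contributes to the nine
#' smoker-identified competencies, generated around well-separated cluster
#' centroids so that k-means can recover the catalog's clusters.
#'
#' @param catalog A [fixture_activity_catalog()].
#' @param seed Integer seed.
#' @param noise_sd Rating noise SD (default 0.5 on the -10..10 scale).
#' @return Numeric matrix, preparatory activities x 9, rownames = ids.
#' @export
fixture_activity_ratings <- function(catalog, seed = 1, noise_sd = 0.5) {
  set.seed(seed)
  prep <- catalog[catalog$kind == "preparatory", ]
  centroids <- matrix(0, 5, 9)
  for (c_ in 1:5) centroids[c_, ((c_ - 1) %% 9) + c(1, 3, 5)] <- c(8, 6, -6)
  ratings <- centroids[prep$cluster, ] + matrix(rnorm(nrow(prep) * 9, 0, noise_sd),
                                                nrow(prep), 9)
  ratings <- pmin(pmax(ratings, -10), 10)
  rownames(ratings) <- prep$id
  ratings
}
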