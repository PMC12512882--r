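# Small in-code fixtures shared across tests.

# minimal catalog: n_prep preparatory activities split over n_clusters,
# plus optional persuasive activities targeting beliefs 1..n_pers
tiny_catalog <- function(n_prep = 4, n_clusters = 2, n_pers = 0,
                         cont = NULL) {
  cluster <- rep(seq_len(n_clusters), length.out = n_prep)
  if (is.null(cont)) {
    cont <- matrix(0, n_prep, 6)
    cont[, 1] <- 0.8
    cont[cbind(seq_len(n_prep), 1 + (seq_len(n_prep) %% 5))] <- 0.6
  }
  prep <- data.frame(id = seq_len(n_prep),
                     name = paste("prep", seq_len(n_prep)),
                     kind = "preparatory", cluster = cluster)
  prep[paste0("cont_", 1:6)] <- cont
  prep$target_belief <- NA_integer_
  if (n_pers > 0) {
    pers <- data.frame(id = n_prep + seq_len(n_pers),
                       name = paste("pers", seq_len(n_pers)),
                       kind = "persuasive", cluster = NA_integer_)
    pers[paste0("cont_", 1:6)] <- 0
    pers$target_belief <- seq_len(n_pers)
    prep <- rbind(prep, pers)
  }
  activity_catalog(prep)
}

# hand-built interaction-sample table: one row per sample with chosen
# feature raw values (all other features constant), action ids and efforts
hand_samples <- function(action_id, raw_effort, cur = list(), nxt = list(),
                         person_id = NULL) {
  n <- length(action_id)
  fc <- feature_columns()
  out <- data.frame(person_id = if (is.null(person_id)) seq_len(n) else person_id,
                    session = 1L, action_id = action_id,
                    raw_effort = raw_effort)
  for (f in fc) {
    out[[paste0("cur_", f)]] <- if (!is.null(cur[[f]])) cur[[f]] else rep(0, n)
    out[[paste0("nxt_", f)]] <- if (!is.null(nxt[[f]])) nxt[[f]] else rep(0, n)
  }
  structure(out, class = c("interaction_samples", "data.frame"))
}

# binarization spec with explicit thresholds (defaults: 0 everywhere)
hand_spec <- function(means = NULL) {
  fc <- feature_columns()
  m <- setNames(rep(0, length(fc)), fc)
  if (!is.null(means)) m[names(means)] <- unlist(means)
  structure(m, class = "binarization_spec")
}

# a small fitted environment for simulation tests: uniform effort model and
# symmetric transitions over a tiny catalog
hand_models <- function(catalog, features = c("belief_1", "belief_7", "energy"),
                        effort_value = 0.5, trans_p = 0.5) {
  ag <- action_groups(catalog)
  n_cfg <- 2L^length(features)
  eff <- structure(list(
    mean_scaled = matrix(effort_value, n_cfg, ag$n_groups,
                         dimnames = list(NULL, ag$labels)),
    counts = matrix(1L, n_cfg, ag$n_groups),
    fallback = matrix(FALSE, n_cfg, ag$n_groups),
    population_mean_raw = 5, features = features,
    group_labels = ag$labels), class = "effort_model")
  m <- length(features)
  prob <- array(trans_p, c(m, 2L, ag$n_groups),
                dimnames = list(features, c("bit0", "bit1"), ag$labels))
  trans <- structure(list(prob = prob,
                          counts = array(1L, dim(prob)),
                          fallback = array(FALSE, dim(prob)),
                          features = features, group_labels = ag$labels),
                     class = "transition_model")
  list(effort = eff, transition = trans)
}

uniform_init <- function(m = 3) {
  structure(rep(1 / 2^m, 2^m), class = "initial_uf")
}
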