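#' User-inquired feature columns of an interaction log
#'
#' Eleven candidate state features are recorded in each session: the nine
#' usefulness-belief ratings on -10..10 and energy and available time on
#' 0..10.
#'
#' @return Character vector of column names.
#' @export
feature_columns <- function() c(paste0("belief_", 1:9), "energy", "time_available")

feature_bounds <- function() {
  lo <- c(rep(-10, 9), 0, 0)
  hi <- c(rep(10, 9), 10, 10)
  data.frame(feature = feature_columns(), lower = lo, upper = hi)
}

#' Binarization thresholds for user-inquired features
#'
#' Raw features are reduced to binary by thresholding at the sample mean:
#' a value greater than or equal to the mean maps to 1, below it to 0. The
#' spec records the means so the reduction is reproducible.
#'
#' @param log Interaction log data frame (one row per attended session).
#' @return Object of class `binarization_spec`: named numeric vector of
#'   per-feature sample means.
#' @export
binarization_spec <- function(log) {
  cols <- feature_columns()
  missing <- setdiff(cols, names(log))
  if (length(missing)) stop("log is missing feature columns: ", paste(missing, collapse = ", "))
  means <- colMeans(log[, cols, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(means))) stop("binarization thresholds must be finite")
  structure(means, class = "binarization_spec")
}

#' Binarize user-inquired features
#'
#' @param df Data frame containing (a subset of) the columns named in
#'   `spec`; typically an interaction log or sample table.
#' @param spec A [binarization_spec()].
#' @param features Which features to binarize (default: all in `spec`).
#' @return Integer matrix of 0/1 bits, one column per requested feature.
#' @export
binarize_features <- function(df, spec, features = names(spec)) {
  stopifnot(inherits(spec, "binarization_spec"))
  missing <- setdiff(features, names(df))
  if (length(missing)) stop("data is missing columns: ", paste(missing, collapse = ", "))
  bits <- vapply(features,
                 function(f) as.integer(df[[f]] >= spec[[f]]),
                 integer(nrow(df)))
  bits <- matrix(bits, nrow = nrow(df),
                 dimnames = list(NULL, features))
  bits
}

#' Pair consecutive sessions into interaction samples
#'
#' Each training sample is a (state, action, effort, next state) tuple: the
#' state and assigned activity of one session together with the state of
#' the person's next session, in which the effort spent on the activity was
#' reported. Final attended sessions (no successor) and rows with missing
#' effort are dropped.
#'
#' @param log Interaction log data frame with columns `person_id`,
#'   `session`, the [feature_columns()], `action_id`, and `raw_effort`.
#' @param quiet Suppress the message about dropped rows.
#' @return Data frame of class `interaction_samples` with `person_id`,
#'   `session`, `action_id`, `raw_effort`, and the current/next features
#'   prefixed `cur_` / `nxt_`.
#' @export
interaction_samples <- function(log, quiet = FALSE) {
  log <- log[order(log$person_id, log$session), , drop = FALSE]
  n <- nrow(log)
  if (n < 2L) return(empty_samples())
  cur <- seq_len(n - 1L)
  nxt <- cur + 1L
  paired <- log$person_id[cur] == log$person_id[nxt] &
    log$session[cur] + 1L == log$session[nxt]
  cur <- cur[paired]
  nxt <- nxt[paired]
  keep <- !is.na(log$raw_effort[cur]) & !is.na(log$action_id[cur])
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet) {
    message(dropped, " session pair(s) dropped for missing effort or action")
  }
  cur <- cur[keep]
  nxt <- nxt[keep]
  fc <- feature_columns()
  out <- data.frame(person_id = log$person_id[cur],
                    session = log$session[cur],
                    action_id = log$action_id[cur],
                    raw_effort = log$raw_effort[cur])
  out[paste0("cur_", fc)] <- log[cur, fc]
  out[paste0("nxt_", fc)] <- log[nxt, fc]
  structure(out, class = c("interaction_samples", "data.frame"))
}

empty_samples <- function() {
  fc <- feature_columns()
  out <- data.frame(person_id = character(0), session = integer(0),
                    action_id = integer(0), raw_effort = numeric(0))
  out[paste0("cur_", fc)] <- numeric(0)
  out[paste0("nxt_", fc)] <- numeric(0)
  structure(out, class = c("interaction_samples", "data.frame"))
}

strip_prefix_spec <- function(spec, prefix) {
  # reuse a binarization_spec on cur_/nxt_ prefixed columns
  structure(setNames(as.numeric(spec), paste0(prefix, names(spec))),
            class = "binarization_spec")
}

#' Cluster preparatory activities by smoker rating profiles
#'
#' Preparatory activities perceived by smokers as contributing similarly to
#' the smoker-identified competencies are grouped with k-means so that
#' effort and feature transitions can be estimated per cluster rather than
#' per activity.
#'
#' @param ratings Numeric matrix, activities x rating dimensions, no
#'   missing values.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for reproducible restarts.
#' @param nstart Number of k-means restarts.
#' @return Integer vector of cluster assignments in `1..k`.
#' @export
cluster_preparatory_activities <- function(ratings, k = 5, seed = 1, nstart = 25) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  if (!is.numeric(k) || length(k) != 1L || k <= 0) stop("k must be a positive integer")
  if (k > nrow(ratings)) stop("k cannot exceed the number of activities")
  set.seed(seed)
  if (k == nrow(ratings)) return(seq_len(nrow(ratings)))
  km <- kmeans(ratings, centers = k, nstart = nstart, iter.max = 100)
  as.integer(km$cluster)
}

uf_config_index <- function(bits) {
  # bits: matrix n x m, first column most significant; returns 1-based index
  m <- ncol(bits)
  as.integer(bits %*% 2^((m - 1):0)) + 1L
}

uf_config_bits <- function(n_features) {
  # enumeration matching uf_config_index: row u holds the bits of config u,
  # first column most significant
  idx <- 0:(2^n_features - 1)
  vapply((n_features - 1):0,
         function(p) as.integer((idx %/% 2^p) %% 2),
         integer(length(idx)))
}

#' Fit the population-level effort model
#'
#' Estimates, for every combination of the selected binary user features
#' (2^m configurations) and every action group, the mean unit-scaled effort
#' spent on proposed activities. Cells without observations fall back to
#' the group-level mean (and to the overall mean for empty groups).
#'
#' @param samples An [interaction_samples()] table.
#' @param catalog An `activity_catalog`.
#' @param features Character vector of selected feature names (the order
#'   fixes the configuration indexing, first feature most significant).
#' @param spec A [binarization_spec()] computed from the same log.
#' @return Object of class `effort_model`: list with `mean_scaled`
#'   (configurations x groups), `counts`, `fallback` (logical matrix),
#'   `population_mean_raw`, `features`, and `group_labels`.
#' @export
fit_effort_model <- function(samples, catalog, features, spec) {
  if (nrow(samples) == 0L) stop("cannot estimate an effort model from an empty log")
  ag <- action_groups(catalog)
  grp <- ag$group[match(samples$action_id, catalog$id)]
  if (anyNA(grp)) stop("samples contain action ids absent from the catalog")
  bits <- binarize_features(samples, strip_prefix_spec(spec, "cur_"),
                            paste0("cur_", features))
  cfg <- uf_config_index(bits)
  pop_mean <- mean(samples$raw_effort)
  scaled <- scale_effort(samples$raw_effort, pop_mean)
  n_cfg <- 2L^length(features)
  sums <- matrix(0, n_cfg, ag$n_groups)
  counts <- matrix(0L, n_cfg, ag$n_groups)
  for (i in seq_along(scaled)) {
    sums[cfg[i], grp[i]] <- sums[cfg[i], grp[i]] + scaled[i]
    counts[cfg[i], grp[i]] <- counts[cfg[i], grp[i]] + 1L
  }
  mean_scaled <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  group_mean <- colSums(sums) / pmax(colSums(counts), 1L)
  group_mean[colSums(counts) == 0] <- mean(scaled)
  fallback <- counts == 0L
  for (g in seq_len(ag$n_groups)) {
    mean_scaled[fallback[, g], g] <- group_mean[g]
  }
  dimnames(mean_scaled) <- dimnames(counts) <- list(NULL, ag$labels)
  structure(list(mean_scaled = mean_scaled, counts = counts, fallback = fallback,
                 population_mean_raw = pop_mean, features = features,
                 group_labels = ag$labels),
            class = "effort_model")
}

#' Fit the user-feature transition model
#'
#' For each selected feature, current bit value, and action group, the
#' probability that the feature is 1 in the next session is the empirical
#' fraction among observed transitions. Transitions of one feature are
#' modelled independently of the values of the other features. Unseen
#' cells fall back to probability 0.5.
#'
#' @inheritParams fit_effort_model
#' @return Object of class `transition_model`: list with `prob` (array
#'   features x 2 x groups, second dimension = current bit 0/1), `counts`,
#'   `fallback`, `features`, `group_labels`.
#' @export
fit_transition_model <- function(samples, catalog, features, spec) {
  if (nrow(samples) == 0L) stop("cannot estimate a transition model from an empty log")
  ag <- action_groups(catalog)
  grp <- ag$group[match(samples$action_id, catalog$id)]
  if (anyNA(grp)) stop("samples contain action ids absent from the catalog")
  cur_bits <- binarize_features(samples, strip_prefix_spec(spec, "cur_"),
                                paste0("cur_", features))
  nxt_bits <- binarize_features(samples, strip_prefix_spec(spec, "nxt_"),
                                paste0("nxt_", features))
  m <- length(features)
  prob <- array(NA_real_, c(m, 2L, ag$n_groups),
                dimnames = list(features, c("bit0", "bit1"), ag$labels))
  counts <- array(0L, dim(prob), dimnames = dimnames(prob))
  for (f in seq_len(m)) {
    for (b in 0:1) {
      sel <- cur_bits[, f] == b
      if (!any(sel)) next
      tab <- tapply(nxt_bits[sel, f], grp[sel], function(v) c(sum(v), length(v)))
      for (g in names(tab)) {
        gi <- as.integer(g)
        counts[f, b + 1L, gi] <- tab[[g]][2]
        prob[f, b + 1L, gi] <- tab[[g]][1] / tab[[g]][2]
      }
    }
  }
  fallback <- is.na(prob)
  prob[fallback] <- 0.5
  structure(list(prob = prob, counts = counts, fallback = fallback,
                 features = features, group_labels = ag$labels),
            class = "transition_model")
}

#' Serialize fitted dynamics models to JSON
#'
#' Both models are small enumerable tables (2^m x groups effort cells and
#' m x 2 x groups transition cells) and round-trip losslessly.
#'
#' @param effort An `effort_model`.
#' @param transition A `transition_model`.
#' @param path Output JSON file.
#' @export
write_dynamics_models <- function(effort, transition, path) {
  payload <- list(
    schema = "quitprep-dynamics-1",
    effort = list(mean_scaled = effort$mean_scaled,
                  counts = effort$counts,
                  fallback = effort$fallback,
                  population_mean_raw = effort$population_mean_raw,
                  features = effort$features,
                  group_labels = effort$group_labels),
    transition = list(prob = transition$prob,
                      counts = transition$counts,
                      fallback = transition$fallback,
                      features = transition$features,
                      group_labels = transition$group_labels))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dynamics_models
#' @return `read_dynamics_models()` returns `list(effort =, transition =)`.
#' @export
read_dynamics_models <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "quitprep-dynamics-1")) stop("unrecognised dynamics schema")
  eff <- p$effort
  m <- length(eff$features)
  effort <- structure(list(
    mean_scaled = matrix(unlist(eff$mean_scaled), ncol = length(eff$group_labels),
                         dimnames = list(NULL, eff$group_labels)),
    counts = matrix(as.integer(unlist(eff$counts)), ncol = length(eff$group_labels)),
    fallback = matrix(as.logical(unlist(eff$fallback)), ncol = length(eff$group_labels)),
    population_mean_raw = eff$population_mean_raw,
    features = eff$features, group_labels = eff$group_labels),
    class = "effort_model")
  tr <- p$transition
  dimn <- list(tr$features, c("bit0", "bit1"), tr$group_labels)
  transition <- structure(list(
    prob = array(unlist(tr$prob), c(m, 2L, length(tr$group_labels)), dimnames = dimn),
    counts = array(as.integer(unlist(tr$counts)), c(m, 2L, length(tr$group_labels)), dimnames = dimn),
    fallback = array(as.logical(unlist(tr$fallback)), c(m, 2L, length(tr$group_labels)), dimnames = dimn),
    features = tr$features, group_labels = tr$group_labels),
    class = "transition_model")
  list(effort = effort, transition = transition)
}
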