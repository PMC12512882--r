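#' Score how strongly a feature modulates effort
#'
#' In the spirit of the G-algorithm, a candidate binary feature is scored
#' by how different the effort-based Q-values (here: immediate mean
#' unit-scaled effort per action group) are between candidate = 0 and
#' candidate = 1. Samples are stratified by the configurations of the
#' already-selected features crossed with the action group; within each
#' stratum that has observations on both sides, the absolute difference of
#' mean scaled efforts is taken, and the score is the stratum-size-weighted
#' mean of these differences.
#'
#' @param samples An [interaction_samples()] table.
#' @param candidate Feature name to score (see [feature_columns()]).
#' @param already_selected Character vector of previously selected features
#'   (possibly empty).
#' @param catalog An `activity_catalog`.
#' @param spec A [binarization_spec()].
#' @return List with `score` (non-negative scalar) and `detail` (per-stratum
#'   data frame with both-side means, difference, and weight).
#' @export
score_feature_split <- function(samples, candidate, already_selected, catalog, spec) {
  if (candidate %in% already_selected) stop("candidate is already selected")
  ag <- action_groups(catalog)
  grp <- ag$group[match(samples$action_id, catalog$id)]
  cur_spec <- strip_prefix_spec(spec, "cur_")
  cand_bit <- binarize_features(samples, cur_spec, paste0("cur_", candidate))[, 1]
  if (length(unique(cand_bit)) < 2L) {
    warning("candidate feature '", candidate, "' never varies; score 0")
    return(list(score = 0, detail = data.frame()))
  }
  if (length(already_selected)) {
    sel_bits <- binarize_features(samples, cur_spec, paste0("cur_", already_selected))
    parts <- lapply(seq_len(ncol(sel_bits)), function(j) sel_bits[, j])
    stratum <- do.call(interaction, c(parts, list(grp, drop = TRUE)))
  } else {
    stratum <- factor(grp)
  }
  scaled <- scale_effort(samples$raw_effort, mean(samples$raw_effort))
  detail <- do.call(rbind, lapply(levels(stratum), function(st) {
    in_st <- stratum == st
    b <- cand_bit[in_st]
    if (length(unique(b)) < 2L) return(NULL)
    e <- scaled[in_st]
    m0 <- mean(e[b == 0]); m1 <- mean(e[b == 1])
    data.frame(stratum = st, n = sum(in_st),
               mean_bit0 = m0, mean_bit1 = m1, abs_diff = abs(m1 - m0))
  }))
  if (is.null(detail) || nrow(detail) == 0L) {
    return(list(score = 0, detail = data.frame()))
  }
  list(score = weighted.mean(detail$abs_diff, detail$n), detail = detail)
}

#' Greedy selection of the most effort-relevant features
#'
#' Runs `m` rounds of [score_feature_split()], each round adding the
#' highest-scoring remaining candidate to the selected set. Ties are broken
#' by the lowest position in `candidates`.
#'
#' @inheritParams score_feature_split
#' @param m Number of features to select (default 3).
#' @param candidates Candidate pool, default all 11 user-inquired features.
#' @return Data frame with columns `round`, `feature`, `score`, in
#'   selection order; the selected set is `$feature`.
#' @export
select_features <- function(samples, m = 3, catalog, spec,
                            candidates = feature_columns()) {
  if (!is.numeric(m) || length(m) != 1L || m <= 0) stop("m must be a positive integer")
  if (m > length(candidates)) stop("m cannot exceed the number of candidates")
  selected <- character(0)
  out <- data.frame(round = integer(0), feature = character(0), score = numeric(0))
  for (r in seq_len(m)) {
    pool <- setdiff(candidates, selected)
    scores <- vapply(pool, function(f) {
      suppressWarnings(score_feature_split(samples, f, selected, catalog, spec)$score)
    }, numeric(1))
    best <- pool[which.max(scores)]  # which.max: first max, i.e. lowest index
    selected <- c(selected, best)
    out <- rbind(out, data.frame(round = r, feature = best,
                                 score = scores[[best]]))
  }
  out
}
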