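#' Construct and validate an activity catalog
#'
#' A catalog holds the coach's actions: preparatory activities, which carry
#' a cluster membership and a six-value contribution profile toward the
#' expert-identified competencies, and persuasive activities, which target
#' one of the nine usefulness beliefs and contribute nothing directly
#' (contributions all zero).
#'
#' @param df Data frame with columns `id` (unique integer), `name`,
#'   `kind` (`"preparatory"` or `"persuasive"`), `cluster` (integer for
#'   preparatory rows, `NA` otherwise), `cont_1` .. `cont_6` in \[0, 1\],
#'   and `target_belief` (1--9 for persuasive rows, `NA` otherwise).
#' @return The validated data frame with class `activity_catalog`.
#' @export
activity_catalog <- function(df) {
  needed <- c("id", "name", "kind", "cluster", contribution_columns(), "target_belief")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[, needed]
  if (anyDuplicated(df$id)) stop("activity ids must be unique")
  if (!all(df$kind %in% c("preparatory", "persuasive"))) {
    stop("kind must be 'preparatory' or 'persuasive'")
  }
  cont <- as.matrix(df[, contribution_columns()])
  if (any(cont < 0) || any(cont > 1)) stop("contributions must lie in [0, 1]")
  prep <- df$kind == "preparatory"
  if (any(is.na(df$cluster[prep]))) stop("preparatory activities need a cluster")
  if (any(rowSums(cont[!prep, , drop = FALSE]) > 0)) {
    stop("persuasive activities must have all-zero contributions")
  }
  if (any(is.na(df$target_belief[!prep])) ||
      any(df$target_belief[!prep] < 1) || any(df$target_belief[!prep] > 9)) {
    stop("persuasive activities need target_belief in 1..9")
  }
  structure(df, class = c("activity_catalog", "data.frame"))
}

contribution_columns <- function() paste0("cont_", 1:6)

#' Contribution matrix of a catalog
#' @param catalog An `activity_catalog`.
#' @return Numeric matrix, activities x 6.
#' @export
contributions <- function(catalog) {
  m <- as.matrix(catalog[, contribution_columns()])
  rownames(m) <- catalog$id
  m
}

#' Action groups of a catalog
#'
#' Dynamics (effort and user-feature transitions) are estimated per action
#' group: one group per preparatory cluster and one singleton group per
#' persuasive activity (5 + 9 = 14 groups in the study catalog).
#'
#' @param catalog An `activity_catalog`.
#' @return List with `group` (integer group id per catalog row), `labels`
#'   (one per group), `preparatory` (logical per group), and `n_groups`.
#' @export
action_groups <- function(catalog) {
  prep <- catalog$kind == "preparatory"
  clusters <- sort(unique(catalog$cluster[prep]))
  if (length(clusters) && any(tabulate(match(catalog$cluster[prep], clusters)) == 0)) {
    stop("every preparatory cluster must be non-empty")
  }
  group <- integer(nrow(catalog))
  group[prep] <- match(catalog$cluster[prep], clusters)
  pers_idx <- which(!prep)
  group[pers_idx] <- length(clusters) + seq_along(pers_idx)
  labels <- c(paste0("cluster_", clusters),
              paste0("persuasive_", catalog$id[pers_idx]))
  list(group = group,
       labels = labels,
       preparatory = c(rep(TRUE, length(clusters)), rep(FALSE, length(pers_idx))),
       n_groups = length(labels))
}

#' Read / write an activity catalog CSV
#'
#' @param path CSV file with a header row and the columns documented in
#'   [activity_catalog()].
#' @return `read_activity_catalog()` returns an `activity_catalog`.
#' @export
read_activity_catalog <- function(path) {
  activity_catalog(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_activity_catalog
#' @param catalog An `activity_catalog`.
#' @export
write_activity_catalog <- function(catalog, path) {
  write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}
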