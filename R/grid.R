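#' Competency level grid
#'
#' The admissible values for an expert-identified competency. Exact thirds
#' are used internally; 0.33/0.67 in printed tables are display roundings.
#'
#' @return Numeric vector `c(0, 1/3, 2/3, 1)`.
#' @export
level_grid <- function() c(0, 1 / 3, 2 / 3, 1)

#' Snap a raw competency value to the level grid
#'
#' Raw competency updates are capped at 1 and mapped to the nearest grid
#' point in \{0, 1/3, 2/3, 1\}. Midpoints (1/6, 1/2, 5/6) are resolved
#' upward by default, which keeps updates consistent with the cap-at-one
#' rule and never penalises reward; downward resolution is available for
#' sensitivity analysis.
#'
#' @param x Numeric vector, each element >= 0.
#' @param ties `"up"` (default) or `"down"`: direction in which exact
#'   midpoints between grid points are resolved.
#' @return Numeric vector of grid values, same length as `x`.
#' @examples
#' snap_to_level_grid(c(0, 0.4, 0.5, 0.9))
#' @export
snap_to_level_grid <- function(x, ties = c("up", "down")) {
  ties <- match.arg(ties)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("snap_to_level_grid() requires finite non-negative input")
  }
  x <- pmin(x, 1)
  cuts <- c(1 / 6, 1 / 2, 5 / 6)
  idx <- findInterval(x, cuts, left.open = (ties == "down"))
  level_grid()[idx + 1L]
}

#' Scale raw effort to the unit interval
#'
#' Self-reported effort on a 0--10 scale is mapped piecewise-linearly to
#' \[0, 1\] so that the population-level mean effort lands at 0.5 and
#' efforts below and above the mean are each equally spaced.
#'
#' @param raw Numeric vector of raw efforts in \[0, 10\].
#' @param population_mean Population-level mean raw effort, strictly
#'   inside (0, 10).
#' @return Numeric vector of unit efforts in \[0, 1\].
#' @examples
#' scale_effort(c(0, 2.79, 5.58, 10), population_mean = 5.58)
#' @export
scale_effort <- function(raw, population_mean) {
  if (!is.numeric(population_mean) || length(population_mean) != 1L ||
      !is.finite(population_mean) ||
      population_mean <= 0 || population_mean >= 10) {
    stop("population_mean must be a single value strictly inside (0, 10)")
  }
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > 10)) {
    stop("raw effort must lie in [0, 10]")
  }
  ifelse(raw <= population_mean,
         0.5 * raw / population_mean,
         0.5 + 0.5 * (raw - population_mean) / (10 - population_mean))
}

#' Scale bipolar factor loadings to contribution values
#'
#' Each bipolar factor from the expert repertory-grid analysis defines two
#' competencies: the positive and the negative pole. Positive loadings
#' populate the positive-pole column, absolute negative loadings the
#' negative-pole column, and each resulting column is min-max scaled to
#' \[0, 1\] across activities. A column that is identically zero is left
#' zero with a warning.
#'
#' @param loadings Numeric matrix, activities x factors.
#' @return Numeric matrix, activities x (2 * factors), values in \[0, 1\].
#'   Column `2f - 1` is the positive pole of factor `f`, column `2f` the
#'   negative pole.
#' @export
scale_loadings_to_contributions <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  n_fac <- ncol(loadings)
  out <- matrix(0, nrow(loadings), 2L * n_fac)
  for (f in seq_len(n_fac)) {
    poles <- list(pmax(loadings[, f], 0), pmax(-loadings[, f], 0))
    for (p in 1:2) {
      col <- poles[[p]]
      rng <- range(col)
      if (rng[2] == rng[1]) {
        if (rng[2] == 0) {
          warning(sprintf("factor %d pole %d has all-zero loadings; column left 0", f, p))
        } else {
          warning(sprintf("factor %d pole %d is constant; column set to 1", f, p))
          col[] <- 1
        }
      } else {
        col <- (col - rng[1]) / (rng[2] - rng[1])
      }
      out[, 2L * (f - 1L) + p] <- col
    }
  }
  rownames(out) <- rownames(loadings)
  out
}

check_competency_levels <- function(levels) {
  if (!is.numeric(levels) || any(!is.finite(levels))) {
    stop("competency levels must be finite numerics")
  }
  on_grid <- vapply(levels, function(v) any(abs(v - level_grid()) < 1e-12), logical(1))
  if (!all(on_grid)) stop("competency levels must lie on the grid {0, 1/3, 2/3, 1}")
  invisible(levels)
}

#' Reward of proposing an activity
#'
#' The reward is the actual increase in expert-identified competencies:
#' for each competency `j`, the possible contribution
#' `pc_j = snap(cont_j * effort)` is credited only up to the remaining
#' headroom `1 - comp_j`, and credits are summed over the six
#' competencies, giving a value in \[0, 6\].
#'
#' @param contributions Numeric vector of activity contributions in
#'   \[0, 1\] (length 6 in the study model).
#' @param effort Unit effort in \[0, 1\].
#' @param current Current competency levels, each on the level grid.
#' @param ties Midpoint rule passed to [snap_to_level_grid()].
#' @return Single numeric reward.
#' @export
compute_reward <- function(contributions, effort, current, ties = "up") {
  if (length(current) != length(contributions)) {
    stop("contributions and current levels must have equal length")
  }
  if (any(contributions < 0) || any(contributions > 1)) {
    stop("contributions must lie in [0, 1]")
  }
  if (length(effort) != 1L || effort < 0 || effort > 1) {
    stop("effort must be a single value in [0, 1]")
  }
  check_competency_levels(current)
  pc <- snap_to_level_grid(contributions * effort, ties = ties)
  sum(pmin(pc, 1 - current))
}

#' Deterministic competency-level update
#'
#' Each competency is raised by `effort * cont_j`, capped at the maximum
#' level 1, then snapped to the nearest grid point. The update never
#' decreases a level.
#'
#' @inheritParams compute_reward
#' @return Numeric vector of next levels on the grid.
#' @export
update_competencies <- function(current, effort, contributions, ties = "up") {
  if (length(current) != length(contributions)) {
    stop("contributions and current levels must have equal length")
  }
  check_competency_levels(current)
  if (length(effort) != 1L || effort < 0 || effort > 1) {
    stop("effort must be a single value in [0, 1]")
  }
  snap_to_level_grid(pmin(current + effort * contributions, 1), ties = ties)
}
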