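#' Enumerate the factored state space
#'
#' States combine `n_uf_bits` binary user features with `n_competencies`
#' competency levels on an `n_levels`-point grid. The index is mixed-radix
#' with the user-feature bits high-order (first bit most significant) and
#' the competency digits low-order (first competency least significant):
#' `state = (uf_index - 1) * n_levels^n_competencies + ec_index`, both
#' parts 1-based. The study model has 2^3 * 4^6 = 32768 states.
#'
#' @param n_uf_bits Number of binary user features (default 3).
#' @param n_competencies Number of competencies (default 6).
#' @param n_levels Number of grid levels per competency (default 4).
#' @return Object of class `state_space`: list with `n_states`, `n_uf`,
#'   `n_ec`, `uf_bits` (n_uf x n_uf_bits matrix), `ec_digits` (n_ec x
#'   n_competencies matrix of 0-based digits), and the dimension parameters.
#' @export
state_space <- function(n_uf_bits = 3, n_competencies = 6, n_levels = 4) {
  stopifnot(n_uf_bits >= 1, n_competencies >= 1, n_levels >= 2)
  n_uf <- 2^n_uf_bits
  n_ec <- n_levels^n_competencies
  if (n_uf * n_ec > 5e7) stop("state space too large to enumerate (", n_uf * n_ec, " states)")
  ec_idx <- 0:(n_ec - 1)
  ec_digits <- vapply(seq_len(n_competencies) - 1L,
                      function(j) (ec_idx %/% n_levels^j) %% n_levels,
                      numeric(n_ec))
  structure(list(n_states = as.integer(n_uf * n_ec),
                 n_uf = as.integer(n_uf), n_ec = as.integer(n_ec),
                 n_uf_bits = as.integer(n_uf_bits),
                 n_competencies = as.integer(n_competencies),
                 n_levels = as.integer(n_levels),
                 uf_bits = uf_config_bits(n_uf_bits),
                 ec_digits = ec_digits),
            class = "state_space")
}

#' Encode / decode factored states
#'
#' @param space A [state_space()].
#' @param uf_bits Integer vector (or matrix, one row per state) of user
#'   feature bits, first bit most significant.
#' @param ec_digits Integer vector (or matrix) of 0-based competency
#'   digits, first competency least significant.
#' @return `encode_state()` returns 1-based state indices;
#'   `decode_state()` a list with `uf_bits` and `ec_digits` matrices.
#' @export
encode_state <- function(space, uf_bits, ec_digits) {
  if (is.vector(uf_bits)) uf_bits <- matrix(uf_bits, nrow = 1)
  if (is.vector(ec_digits)) ec_digits <- matrix(ec_digits, nrow = 1)
  uf_idx <- uf_config_index(uf_bits)
  ec_idx <- as.integer(ec_digits %*% space$n_levels^(seq_len(space$n_competencies) - 1L)) + 1L
  as.integer((uf_idx - 1L) * space$n_ec + ec_idx)
}

#' @rdname encode_state
#' @param state Integer vector of 1-based state indices.
#' @export
decode_state <- function(space, state) {
  stopifnot(all(state >= 1), all(state <= space$n_states))
  uf_idx <- (state - 1L) %/% space$n_ec + 1L
  ec_idx <- (state - 1L) %% space$n_ec + 1L
  list(uf_bits = space$uf_bits[uf_idx, , drop = FALSE],
       ec_digits = space$ec_digits[ec_idx, , drop = FALSE])
}

#' Assemble the factored MDP
#'
#' For every state `(uf, ec)` and activity `a`, the model assigns the mean
#' unit effort `e = effort$mean_scaled[uf, group(a)]`, the reward
#' `R(s, a) = compute_reward(cont_a, e, levels(ec))`, the deterministic
#' next competency configuration from [update_competencies()], and a
#' distribution over next user-feature configurations obtained as the
#' product of the per-feature transition probabilities.
#'
#' @param effort An `effort_model`.
#' @param transition A `transition_model` fitted with the same features.
#' @param catalog An `activity_catalog`.
#' @param gamma Discount factor in \[0, 1), default 0.85 (early competency
#'   gains are worth more than late ones).
#' @param ties Midpoint rule for grid snapping.
#' @return Object of class `factored_mdp`: list with `R` (states x
#'   actions), `ecnext` (0-based next competency index per state-action),
#'   `uf_next_prob` (n_uf x groups x n_uf array of P(uf' | uf, group)),
#'   `group`, `space`, `catalog`, `gamma`, `effort_matrix`.
#' @export
build_mdp <- function(effort, transition, catalog, gamma = 0.85, ties = "up") {
  stopifnot(inherits(effort, "effort_model"), inherits(transition, "transition_model"))
  if (!identical(effort$features, transition$features)) {
    stop("effort and transition models must use the same selected features")
  }
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  m <- length(effort$features)
  space <- state_space(n_uf_bits = m)
  ag <- action_groups(catalog)
  if (ag$n_groups != ncol(effort$mean_scaled)) stop("effort model does not match catalog groups")
  cont <- contributions(catalog)
  A <- nrow(catalog)
  n_uf <- space$n_uf; n_ec <- space$n_ec
  levels_mat <- space$ec_digits / (space$n_levels - 1)   # n_ec x 6 in {0,1/3,2/3,1}
  radix <- space$n_levels^(seq_len(space$n_competencies) - 1L)

  R <- matrix(0, space$n_states, A)
  ecnext <- matrix(0L, space$n_states, A)
  headroom <- 1 - levels_mat                             # n_ec x 6
  for (u in seq_len(n_uf)) {
    rows <- (u - 1L) * n_ec + seq_len(n_ec)
    for (a in seq_len(A)) {
      e <- effort$mean_scaled[u, ag$group[a]]
      ca <- cont[a, ]
      pc <- snap_to_level_grid(ca * e, ties = ties)
      pc_mat <- matrix(pc, n_ec, space$n_competencies, byrow = TRUE)
      R[rows, a] <- rowSums(pmin(pc_mat, headroom))
      # next digits: per competency a 4-entry lookup applied to the digit column
      nxt_digits <- vapply(seq_len(space$n_competencies), function(j) {
        lut <- as.integer(round(snap_to_level_grid(
          pmin((0:(space$n_levels - 1)) / (space$n_levels - 1) + e * ca[j], 1),
          ties = ties) * (space$n_levels - 1)))
        lut[space$ec_digits[, j] + 1L]
      }, integer(n_ec))
      ecnext[rows, a] <- as.integer(nxt_digits %*% radix)
    }
  }

  uf_next_prob <- uf_transition_array(transition, space)
  structure(list(R = R, ecnext = ecnext, uf_next_prob = uf_next_prob,
                 group = ag$group, space = space, catalog = catalog,
                 gamma = gamma, effort_matrix = effort$mean_scaled,
                 ties = ties),
            class = "factored_mdp")
}

# P(uf' | uf, group) as the product of independent per-feature Bernoullis
uf_transition_array <- function(transition, space) {
  m <- space$n_uf_bits
  n_uf <- space$n_uf
  n_groups <- dim(transition$prob)[3]
  bits <- space$uf_bits
  arr <- array(NA_real_, c(n_uf, n_groups, n_uf))
  for (g in seq_len(n_groups)) {
    for (u in seq_len(n_uf)) {
      p1 <- vapply(seq_len(m), function(f) transition$prob[f, bits[u, f] + 1L, g],
                   numeric(1))
      probs <- rep(1, n_uf)
      for (f in seq_len(m)) {
        probs <- probs * ifelse(bits[, f] == 1L, p1[f], 1 - p1[f])
      }
      arr[u, g, ] <- probs
    }
  }
  if (any(abs(apply(arr, c(1, 2), sum) - 1) > 1e-9)) {
    stop("next user-feature distributions do not sum to 1")
  }
  arr
}

#' Construct a tabular MDP
#'
#' Dense representation used for small models and for cross-checking the
#' factored planner: one transition matrix per action.
#'
#' @param P List of `S x S` row-stochastic matrices, one per action.
#' @param R `S x A` reward matrix.
#' @param gamma Discount factor in \[0, 1).
#' @return Object of class `tabular_mdp`.
#' @export
tabular_mdp <- function(P, R, gamma) {
  R <- as.matrix(R)
  if (length(P) != ncol(R)) stop("need one transition matrix per action")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  for (a in seq_along(P)) {
    Pa <- P[[a]]
    if (nrow(Pa) != nrow(R) || ncol(Pa) != nrow(R)) stop("transition matrices must be S x S")
    if (any(Pa < 0) || any(abs(rowSums(Pa) - 1) > 1e-9)) {
      stop("transition rows must be non-negative and sum to 1 (action ", a, ")")
    }
  }
  structure(list(P = P, R = R, gamma = gamma), class = "tabular_mdp")
}

#' Gauss-Seidel value iteration
#'
#' Computes an epsilon-optimal value function and Q-values by asynchronous
#' (in-place) sweeps over the states in enumeration order, starting from
#' V = 0. By default the sweep stops when the span seminorm of the value
#' change falls below `epsilon * (1 - gamma) / gamma`; a plain sup-norm
#' criterion is available.
#'
#' @param mdp A [build_mdp()] `factored_mdp` or a [tabular_mdp()].
#' @param epsilon Optimality tolerance (default 0.001).
#' @param max_iter Sweep cap.
#' @param criterion `"span"` (default) or `"supnorm"`.
#' @param variant Optional label stored in the result.
#' @return Object of class `policy_bundle`: list with `Q` (states x
#'   actions), `V`, `iterations`, `converged`, `epsilon`, `gamma`,
#'   `criterion`, `action_ids`, `variant`.
#' @export
gauss_seidel_vi <- function(mdp, epsilon = 0.001, max_iter = 10000L,
                            criterion = c("span", "supnorm"), variant = NULL) {
  criterion <- match.arg(criterion)
  if (epsilon <= 0) stop("epsilon must be positive")
  if (inherits(mdp, "factored_mdp")) {
    res <- gs_vi_factored_cpp(mdp$R, mdp$ecnext, mdp$uf_next_prob,
                              mdp$group - 1L, mdp$space$n_ec, mdp$gamma,
                              epsilon, as.integer(max_iter),
                              criterion == "span")
    ids <- mdp$catalog$id
  } else if (inherits(mdp, "tabular_mdp")) {
    sp <- dense_to_sparse(mdp$P)
    res <- gs_vi_sparse_cpp(mdp$R, sp$succ, sp$prob, sp$offset, mdp$gamma,
                            epsilon, as.integer(max_iter), criterion == "span")
    ids <- seq_len(ncol(mdp$R))
  } else {
    stop("mdp must be a factored_mdp or tabular_mdp")
  }
  if (!res$converged) warning("value iteration hit max_iter before the stopping criterion")
  structure(list(Q = res$Q, V = res$V, iterations = res$iterations,
                 converged = res$converged, epsilon = epsilon,
                 gamma = mdp$gamma, criterion = criterion,
                 action_ids = ids, variant = variant),
            class = "policy_bundle")
}

dense_to_sparse <- function(P) {
  S <- nrow(P[[1]]); A <- length(P)
  succ <- vector("list", S * A)
  prob <- vector("list", S * A)
  for (s in seq_len(S)) {
    for (a in seq_len(A)) {
      k <- (s - 1L) * A + a
      nz <- which(P[[a]][s, ] > 0)
      succ[[k]] <- nz - 1L
      prob[[k]] <- P[[a]][s, nz]
    }
  }
  lens <- lengths(succ)
  list(succ = as.integer(unlist(succ)), prob = as.numeric(unlist(prob)),
       offset = as.integer(c(0, cumsum(lens))))
}

#' Highest-Q action not yet proposed
#'
#' Implements the coach's no-repeat rule: if the optimal activity for the
#' person's state has already been proposed, the activity with the next
#' highest Q-value is proposed instead. Q ties resolve to the lowest
#' action id.
#'
#' @param bundle A `policy_bundle`.
#' @param state 1-based state index.
#' @param history Vector of already-proposed action ids (possibly empty).
#' @return A single action id.
#' @export
next_best_action <- function(bundle, state, history = integer(0)) {
  ids <- bundle$action_ids
  allowed <- which(!(ids %in% history))
  if (!length(allowed)) stop("history exhausts all actions")
  q <- bundle$Q[state, allowed]
  ids[allowed[which.max(q)]]
}
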