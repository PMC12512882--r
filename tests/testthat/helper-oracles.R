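# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# nearest grid point by explicit distance table; ties resolved upward
oracle_snap <- function(x) {
  grid <- c(0, 1 / 3, 2 / 3, 1)
  vapply(pmin(x, 1), function(v) {
    d <- abs(grid - v)
    candidates <- grid[d < min(d) + 1e-12]
    max(candidates)
  }, numeric(1))
}

# brute-force synchronous value iteration on a dense tabular MDP,
# iterated to a tiny sup-norm change
oracle_sync_vi <- function(P, R, gamma, tol = 1e-10, max_iter = 100000) {
  S <- nrow(R); A <- ncol(R)
  V <- rep(0, S)
  for (i in seq_len(max_iter)) {
    Q <- vapply(seq_len(A), function(a) R[, a] + gamma * P[[a]] %*% V, numeric(S))
    Vn <- apply(matrix(Q, S, A), 1, max)
    if (max(abs(Vn - V)) < tol) return(Vn)
    V <- Vn
  }
  V
}

# seeded random dense MDP with row-stochastic transitions
random_tabular_mdp <- function(S, A, gamma, seed) {
  set.seed(seed)
  P <- lapply(seq_len(A), function(a) {
    M <- matrix(rexp(S * S), S, S)
    M / rowSums(M)
  })
  R <- matrix(runif(S * A), S, A)
  tabular_mdp(P, R, gamma)
}
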