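#' Highest-density interval of posterior draws
#'
#' Narrowest interval containing the requested posterior mass, found by
#' sliding a fixed-mass window over the sorted draws.
#'
#' @param draws Numeric vector of posterior draws (>= 1 for point masses;
#'   >= 1000 recommended for stable bounds).
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass > 1) {
    stop("mass must lie in (0, 1]")
  }
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n == 0L) stop("no finite draws")
  k <- ceiling(mass * n)
  if (k >= n) return(c(draws[1], draws[n]))
  widths <- draws[(k + 1):n] - draws[1:(n - k)]
  i <- which.min(widths)
  c(draws[i], draws[i + k])
}

#' Paired Bayesian t-test (BEST model) on belief differences
#'
#' Fits Kruschke's BEST model to paired differences: a Student-t likelihood
#' with location `mu`, scale `sigma`, and normality `nu`, with the broad
#' data-scaled priors popularised by the Bayesian First Aid package
#' (`mu ~ Normal(mean(x), (1000 sd(x))^2)`, `sigma ~ Uniform(sd(x)/1000,
#' 1000 sd(x))`, `nu - 1 ~ Exponential(1/29)`). Sampling is done with JAGS.
#'
#' @param pairs Either a numeric vector of differences (post - pre) or a
#'   data frame with columns `pre` and `post`.
#' @param mcmc_config List with `chains`, `draws` (per chain, after
#'   warm-up), and `warmup`; defaults 4 chains x 5000 draws after 1000
#'   warm-up iterations.
#' @param seed Integer seed (per-chain RNGs are derived from it).
#' @param mass HDI mass (default 0.95).
#' @return Object of class `posterior_summary`: list with `mean`, `sd`,
#'   `hdi_low`, `hdi_high`, `p_positive`, `n_pairs`, `draws` (mu draws),
#'   and `diagnostics` (split-chain potential scale reduction for mu).
#' @export
paired_best_test <- function(pairs, mcmc_config = list(), seed = 1, mass = 0.95) {
  diffs <- if (is.data.frame(pairs)) {
    stopifnot(all(c("pre", "post") %in% names(pairs)))
    pairs$post - pairs$pre
  } else as.numeric(pairs)
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2L) stop("need at least 2 complete pairs")
  if (sd(diffs) == 0) {
    stop("all differences are identical; the BEST scale prior is undefined. ",
         "Report the constant difference ", diffs[1], " directly instead.")
  }
  cfg <- utils::modifyList(list(chains = 4L, draws = 5000L, warmup = 1000L),
                           mcmc_config)
  model_string <- "
    model {
      for (i in 1:n) { x[i] ~ dt(mu, tau, nu) }
      mu ~ dnorm(mean_x, 1 / pow(sd_x * 1000, 2))
      sigma ~ dunif(sd_x / 1000, sd_x * 1000)
      tau <- 1 / pow(sigma, 2)
      nu <- nuMinusOne + 1
      nuMinusOne ~ dexp(1 / 29)
    }"
  data <- list(x = diffs, n = length(diffs),
               mean_x = mean(diffs), sd_x = sd(diffs))
  inits <- lapply(seq_len(cfg$chains), function(ch) {
    list(mu = mean(diffs), sigma = sd(diffs), nuMinusOne = 28,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = cfg$chains, quiet = TRUE)
  stats::update(jm, n.iter = cfg$warmup, progress.bar = "none")
  post <- rjags::coda.samples(jm, variable.names = c("mu", "sigma", "nu"),
                              n.iter = cfg$draws, progress.bar = "none")
  mu <- unlist(lapply(post, function(ch) as.numeric(ch[, "mu"])))
  hd <- hdi(mu, mass)
  psrf <- if (cfg$chains > 1) {
    as.numeric(coda::gelman.diag(post[, "mu"], autoburnin = FALSE)$psrf[1, 1])
  } else NA_real_
  structure(list(mean = mean(mu), sd = sd(mu),
                 hdi_low = hd[1], hdi_high = hd[2],
                 p_positive = mean(mu > 0),
                 n_pairs = length(diffs), draws = mu,
                 diagnostics = list(psrf_mu = psrf, chains = cfg$chains,
                                    draws_per_chain = cfg$draws)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior of mean difference: %.2f (SD %.2f), 95%% HDI [%.2f, %.2f], P(>0) = %.3f (n = %d)\n",
              x$mean, x$sd, x$hdi_low, x$hdi_high, x$p_positive, x$n_pairs))
  invisible(x)
}

#' Cohen's d for paired differences
#'
#' @param diffs Numeric vector of paired differences.
#' @return `mean(diffs) / sd(diffs)` with the sample (n - 1) SD.
#' @export
cohens_d_paired <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2L) stop("need at least 2 differences")
  s <- sd(diffs)
  if (s == 0) stop("zero standard deviation; Cohen's d is undefined")
  mean(diffs) / s
}

#' Cohen's h for two proportions
#'
#' Arcsine-transformed difference `2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @return Single numeric effect size.
#' @export
cohens_h <- function(p1, p2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) stop("proportions must lie in [0, 1]")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Extract pre/post belief pairs around persuasive activities
#'
#' For every session pair in which a persuasive activity was assigned, the
#' targeted usefulness belief is recorded before (assignment session) and
#' after (next session).
#'
#' @param log Interaction log data frame.
#' @param catalog An `activity_catalog`.
#' @return Data frame with `person_id`, `activity_id`, `belief_index`,
#'   `pre`, `post`, `diff`.
#' @export
extract_belief_pairs <- function(log, catalog) {
  samples <- interaction_samples(log, quiet = TRUE)
  pers <- catalog[catalog$kind == "persuasive", ]
  hit <- match(samples$action_id, pers$id)
  keep <- which(!is.na(hit))
  out <- do.call(rbind, lapply(keep, function(i) {
    b <- pers$target_belief[hit[i]]
    col <- paste0("belief_", b)
    data.frame(person_id = samples$person_id[i],
               activity_id = samples$action_id[i],
               belief_index = b,
               pre = samples[[paste0("cur_", col)]][i],
               post = samples[[paste0("nxt_", col)]][i])
  }))
  if (is.null(out)) {
    out <- data.frame(person_id = character(0), activity_id = integer(0),
                      belief_index = integer(0), pre = numeric(0), post = numeric(0))
  }
  out$diff <- out$post - out$pre
  out
}

#' Belief-change table for all persuasive activities
#'
#' Runs one paired BEST test per persuasive activity and tabulates the
#' posterior summaries plus Cohen's d, in the shape of a per-competency
#' results table.
#'
#' @param pairs Output of [extract_belief_pairs()].
#' @param catalog An `activity_catalog`.
#' @param mcmc_config,seed Passed to [paired_best_test()].
#' @return Data frame with one row per persuasive activity: `activity_id`,
#'   `belief_index`, `n_pairs`, `mean`, `sd`, `hdi_low`, `hdi_high`,
#'   `p_positive`, `cohens_d`.
#' @export
belief_change_table <- function(pairs, catalog, mcmc_config = list(), seed = 1) {
  pers <- catalog[catalog$kind == "persuasive", ]
  rows <- lapply(seq_len(nrow(pers)), function(k) {
    d <- pairs$diff[pairs$activity_id == pers$id[k]]
    if (length(d) < 2L || sd(d) == 0) {
      return(data.frame(activity_id = pers$id[k], belief_index = pers$target_belief[k],
                        n_pairs = length(d), mean = NA_real_, sd = NA_real_,
                        hdi_low = NA_real_, hdi_high = NA_real_,
                        p_positive = NA_real_, cohens_d = NA_real_))
    }
    fit <- paired_best_test(d, mcmc_config = mcmc_config, seed = seed + k)
    data.frame(activity_id = pers$id[k], belief_index = pers$target_belief[k],
               n_pairs = fit$n_pairs, mean = fit$mean, sd = fit$sd,
               hdi_low = fit$hdi_low, hdi_high = fit$hdi_high,
               p_positive = fit$p_positive, cohens_d = cohens_d_paired(d))
  })
  do.call(rbind, rows)
}
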