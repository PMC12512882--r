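#' Read an interaction log CSV
#'
#' Expects a header row with `person_id`, `session`, the eleven
#' [feature_columns()], `action_id`, and `raw_effort`. Rows violating the
#' scale bounds (beliefs in -10..10, energy/time/effort in 0..10, session
#' >= 1) are rejected individually with line-numbered messages; the rest
#' are kept.
#'
#' @param path CSV file path.
#' @param quiet Suppress the accepted/rejected message.
#' @return Interaction log data frame.
#' @export
read_interaction_log <- function(path, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("person_id", "session", feature_columns(), "action_id", "raw_effort")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("interaction log is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, needed]
  if (nrow(df) == 0L) {
    warning("interaction log is empty")
    return(df)
  }
  bounds <- feature_bounds()
  bad <- rep(FALSE, nrow(df))
  reasons <- character(nrow(df))
  flag <- function(cond, why) {
    fresh <- cond & !bad
    reasons[fresh] <<- why
    bad <<- bad | cond
  }
  flag(is.na(df$session) | df$session < 1, "session out of range")
  for (i in seq_len(nrow(bounds))) {
    v <- df[[bounds$feature[i]]]
    flag(is.na(v) | v < bounds$lower[i] | v > bounds$upper[i],
         paste0(bounds$feature[i], " out of range"))
  }
  flag(!is.na(df$raw_effort) & (df$raw_effort < 0 | df$raw_effort > 10),
       "raw_effort out of range")
  if (any(bad) && !quiet) {
    for (i in which(bad)) {
      message("line ", i + 1L, " rejected: ", reasons[i])
    }
  }
  if (!quiet) {
    message(sum(!bad), " row(s) accepted, ", sum(bad), " rejected")
  }
  df[!bad, , drop = FALSE]
}

#' @rdname read_interaction_log
#' @param log Interaction log data frame.
#' @export
write_interaction_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation results to CSV or JSON
#'
#' A single `simulation_result` or a list of them is flattened into a
#' tidy table (variant, step, fraction built, Monte-Carlo standard error)
#' with deterministic field order; JSON output round-trips losslessly.
#'
#' @param results A `simulation_result` or list of them.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "simulation_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(variant = r$variant, step = 0:r$horizon,
               fraction_built = r$fraction_built, mc_se = r$mc_se,
               n_people = r$n_people, seed = r$seed)
  }))
  rownames(tab) <- NULL
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read and validate a run configuration
#'
#' YAML file with optional blocks: `paths` (`log`, `catalog`, `out_dir`),
#' `model` (`gamma`, `epsilon`, `n_features`, `k_clusters`), `simulate`
#' (`n_people`, `horizon`, `seed`, `variants`, `effort_mode`,
#' `normalize`), `generate` (`n_people`, `max_sessions`, `continuation`,
#' `seed` — used when no log path is given), and `beliefs` (`chains`,
#' `draws`, `warmup`). Missing values take the study defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    paths = list(log = NULL, catalog = NULL, out_dir = "quitprep-output"),
    model = list(gamma = 0.85, epsilon = 0.001, n_features = 3, k_clusters = 5),
    simulate = list(n_people = 1000, horizon = 5, seed = 1,
                    variants = c("full", "no_next_uf", "myopic", "ec_only",
                                 "uf_only", "random"),
                    effort_mode = "mean", normalize = "ceiling"),
    generate = list(n_people = 542, max_sessions = 5, continuation = 0.86,
                    seed = 1),
    beliefs = list(chains = 4, draws = 5000, warmup = 1000))
  cfg <- utils::modifyList(defaults, if (is.null(cfg)) list() else cfg)
  with(cfg$model, {
    if (gamma < 0 || gamma >= 1) stop("config: gamma must lie in [0, 1)")
    if (epsilon <= 0) stop("config: epsilon must be positive")
  })
  if (cfg$simulate$horizon < 1) stop("config: horizon must be at least 1")
  if (cfg$simulate$n_people < 1) stop("config: n_people must be at least 1")
  for (p in c("log", "catalog")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]])) {
      stop("config: ", p, " path does not exist: ", cfg$paths[[p]])
    }
  }
  cfg$config_path <- path
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes, in order: data loading (or synthetic generation when no log
#' path is configured), feature binarization and selection, dynamics
#' estimation, planning of the requested policy variants, the cohort
#' simulation, and the persuasive-activity belief analysis. All artifacts
#' (models, policies, curves, belief table, manifest with seeds and the
#' config hash) are written to the configured output directory.
#'
#' @param config A [read_run_config()] object or path to a YAML config.
#' @return Invisibly, a list with the fitted models, selection table,
#'   simulation results, and belief table.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  catalog <- stage("catalog", {
    if (is.null(config$paths$catalog)) fixture_activity_catalog(seed = config$generate$seed)
    else read_activity_catalog(config$paths$catalog)
  })
  log <- stage("log", {
    if (is.null(config$paths$log)) {
      gen <- config$generate
      truth <- generate_ground_truth(
        synthetic_config(n_people = gen$n_people, max_sessions = gen$max_sessions,
                         continuation = gen$continuation),
        seed = gen$seed)
      generate_mrt_log(truth, catalog, seed = gen$seed + 1L)
    } else {
      read_interaction_log(config$paths$log, quiet = TRUE)
    }
  })
  spec <- stage("binarize", binarization_spec(log))
  samples <- stage("samples", interaction_samples(log, quiet = TRUE))
  selection <- stage("select_features", {
    select_features(samples, m = config$model$n_features, catalog, spec)
  })
  features <- selection$feature
  eff <- stage("effort_model", fit_effort_model(samples, catalog, features, spec))
  trans <- stage("transition_model", fit_transition_model(samples, catalog, features, spec))
  write_dynamics_models(eff, trans, file.path(out_dir, "dynamics.json"))
  init <- stage("initial_state", estimate_initial_uf(log, spec, features))

  sims <- stage("simulate", {
    lapply(setNames(nm = config$simulate$variants), function(v) {
      pol <- make_policy(v, eff, trans, catalog,
                         gamma = config$model$gamma,
                         epsilon = config$model$epsilon)
      simulate_cohort(pol, eff, trans, catalog, init,
                      n_people = config$simulate$n_people,
                      horizon = config$simulate$horizon,
                      seed = config$simulate$seed,
                      effort_mode = config$simulate$effort_mode,
                      normalize = config$simulate$normalize)
    })
  })
  write_results(sims, file.path(out_dir, "curves.csv"), "csv")
  write_results(sims, file.path(out_dir, "curves.json"), "json")

  beliefs <- stage("beliefs", {
    pairs <- extract_belief_pairs(log, catalog)
    belief_change_table(pairs, catalog,
                        mcmc_config = config$beliefs,
                        seed = config$simulate$seed)
  })
  write.csv(beliefs, file.path(out_dir, "belief_changes.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("quitprep")),
    config_md5 = if (!is.null(config$config_path) && file.exists(config$config_path)) {
      as.character(tools::md5sum(config$config_path))
    } else NA_character_,
    seeds = list(generate = config$generate$seed, simulate = config$simulate$seed),
    gamma = config$model$gamma, epsilon = config$model$epsilon,
    selected_features = features,
    n_samples = nrow(samples),
    artifacts = c("dynamics.json", "curves.csv", "curves.json", "belief_changes.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(catalog = catalog, log = log, spec = spec, samples = samples,
                 selection = selection, effort = eff, transition = trans,
                 init = init, simulations = sims, beliefs = beliefs))
}
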