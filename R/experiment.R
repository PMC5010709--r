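#' Configuration of a replicated simulation experiment
#'
#' Bundles the generator settings with every pipeline knob: the stage-1
#' selection method, which bag rules to evaluate, bag parameters, fold
#' count, replicate count, bootstrap size and the master seed from which
#' every per-replicate seed is derived.
#'
#' @param sim a [sim_config()].
#' @param stage1_method `"adaptive_lasso"` (default) or `"lasso"`.
#' @param weight_scheme initial-estimator scheme for the adaptive weights,
#'   see [initial_weights()].
#' @param bag_rules subset of `c("B1", "B2", "B3")`.
#' @param q bag size for B1/B3.
#' @param threshold correlation cutoff for B2.
#' @param ranking correlation ranking mode for B1/B2.
#' @param k_folds cross-validation folds.
#' @param n_runs number of simulation replicates.
#' @param bootstrap_B bootstrap replicates for the PMSE-ratio interval; 0
#'   skips the interval (faster).
#' @param master_seed integer; replicate r uses seed `master_seed + r`.
#' @param m portion size of the first two data portions (default n/3).
#' @param restandardize re-standardize covariates within each portion after
#'   splitting (default); `FALSE` keeps the one global standardization.
#' @param refit_baseline refit the stage-1 variable set by OLS on the
#'   second portion before validation (default), so error ratios isolate
#'   the variable-set change; `FALSE` evaluates the stage-1 penalized
#'   coefficients directly (the "no-refit" comparison).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              stage1_method = c("adaptive_lasso", "lasso"),
                              weight_scheme = "lasso_ols",
                              bag_rules = c("B1", "B2", "B3"),
                              q = 20L, threshold = 0.25,
                              ranking = c("signed", "absolute"),
                              k_folds = 5L, n_runs = 100L,
                              bootstrap_B = 1000L, master_seed = 1L,
                              m = NULL, restandardize = TRUE,
                              refit_baseline = TRUE) {
  stage1_method <- match.arg(stage1_method)
  ranking <- match.arg(ranking)
  stopifnot(n_runs >= 1, all(bag_rules %in% c("B1", "B2", "B3")),
            k_folds >= 2)
  structure(list(
    sim = sim, stage1_method = stage1_method, weight_scheme = weight_scheme,
    bag_rules = bag_rules, q = as.integer(q), threshold = threshold,
    ranking = ranking, k_folds = as.integer(k_folds),
    n_runs = as.integer(n_runs), bootstrap_B = as.integer(bootstrap_B),
    master_seed = as.integer(master_seed),
    m = if (is.null(m)) sim$n %/% 3L else as.integer(m),
    restandardize = isTRUE(restandardize),
    refit_baseline = isTRUE(refit_baseline)
  ), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s + bags {%s}, q=%d thr=%.2f | %d runs, seed %d\n",
    x$stage1_method, paste(x$bag_rules, collapse = ","), x$q, x$threshold,
    x$n_runs, x$master_seed))
  invisible(x)
}

## deterministic sub-seeds per replicate, one stream per stage
sub_seed <- function(replicate_seed, offset) {
  as.integer((as.numeric(replicate_seed) * 7L + offset) %% 2147483629)
}

#' Run one simulation replicate of the full pipeline
#'
#' Simulate, split, select on the first portion, build bags and apply the
#' substitution rules with the simulation's relevance oracle, refit every
#' final variable set by OLS on the second portion, and evaluate prediction
#' and estimation error on the third.
#'
#' @param config an [experiment_config()].
#' @param replicate_seed integer seed identifying the replicate; every
#'   stage's randomness is derived from it deterministically.
#' @param Sigma optional precomputed [build_covariance()] matrix (saves
#'   rebuilding it for every replicate of the same design).
#' @return A tibble with one row per method (`baseline` plus each bag rule)
#'   and columns: counts of the stage-1 and final variable sets, relevant
#'   counts and percentages, PMSE, PRPMSE, bootstrap interval and favorable
#'   flag (when `bootstrap_B > 0`), and the integrated squared error.
#' @export
run_replicate <- function(config, replicate_seed, Sigma = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$sim
  sim$seed <- sub_seed(replicate_seed, 1L)
  if (is.null(Sigma)) Sigma <- build_covariance(sim)
  sd <- simulate_dataset(sim)
  split <- split_three_way(sd$data, m = config$m,
                           seed = sub_seed(replicate_seed, 2L),
                           restandardize = config$restandardize)
  sel <- stage1_select(split$d1, method = config$stage1_method,
                       k = config$k_folds,
                       seed = sub_seed(replicate_seed, 3L),
                       weight_scheme = config$weight_scheme)
  if (length(sel$selected) < 1) {
    stop("stage 1 selected no variables.", call. = FALSE)
  }
  if (length(sel$selected) >= config$m) {
    stop("stage-1 selection too large for the OLS refit.", call. = FALSE)
  }
  relevance <- sd$relevance
  base_fit <- if (isTRUE(config$refit_baseline) || is.null(config$refit_baseline)) {
    refit_ols(sel$selected, split$d2)
  } else {
    as_model(sel)
  }
  base_pmse <- pmse(base_fit, split$d3)
  base_comp <- selection_composition(sel$selected, relevance)
  base_mise <- mise(base_fit, sd$true_beta, Sigma)

  row_for <- function(method, final_vars, fit) {
    comp <- selection_composition(final_vars, relevance)
    p <- pmse(fit, split$d3)
    ci <- c(NA_real_, NA_real_); fav <- NA
    if (config$bootstrap_B > 0 && method != "baseline") {
      bs <- bootstrap_ratio_ci(fit, base_fit, split$d3,
                               B = config$bootstrap_B,
                               seed = sub_seed(replicate_seed, 4L))
      ci <- bs$ci; fav <- bs$favorable
    }
    tibble::tibble(
      replicate_seed = replicate_seed, method = method,
      n_stage1 = length(sel$selected),
      n_final = comp$n_selected, n_relevant = comp$n_relevant,
      pct_relevant = comp$pct_relevant,
      pmse = p, prpmse = 100 * p / base_pmse,
      ci_lo = ci[1], ci_hi = ci[2], favorable = fav,
      mise = mise(fit, sd$true_beta, Sigma))
  }

  out <- row_for("baseline", sel$selected, base_fit)
  for (rule in config$bag_rules) {
    bags <- switch(rule,
      B1 = bag_correlation_topq(sel, split$d1, q = config$q,
                                ranking = config$ranking),
      B2 = bag_correlation_threshold(sel, split$d1,
                                     threshold = config$threshold,
                                     ranking = config$ranking),
      B3 = bag_mse_topq(sel, split$d1, q = config$q))
    subres <- apply_substitutions(sel, bags, relevance)
    fit <- refit_ols(subres$final_variables, split$d2)
    out <- dplyr::bind_rows(out, row_for(rule, subres$final_variables, fit))
  }
  out
}

#' Run the replicated experiment and summarize it
#'
#' Executes [run_replicate()] for `n_runs` seeds derived from the master
#' seed and aggregates per method. Replicates that fail (e.g. an empty
#' stage-1 selection) are recorded and skipped; if more than 10 % fail the
#' experiment is marked invalid.
#'
#' @param config an [experiment_config()].
#' @param progress print a dot per replicate.
#' @return An object of class `bag_experiment` with elements `summary` (one
#'   row per method), `replicates` (per-replicate rows), `failures`
#'   (seed/message tibble), `valid`, and the `config`. The summary reports
#'   both the mean per-replicate percentage of relevant variables and the
#'   ratio-of-means percentage `100 * mean(n_relevant) / mean(n_stage1)`
#'   (`pct_relevant_of_stage1`), whose denominator is the stage-1 selection
#'   size for every method.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  Sigma <- build_covariance(config$sim)
  seeds <- config$master_seed + seq_len(config$n_runs)
  reps <- vector("list", config$n_runs)
  fails <- list()
  for (i in seq_along(seeds)) {
    res <- tryCatch(run_replicate(config, seeds[i], Sigma = Sigma),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(replicate_seed = seeds[i],
                       message = conditionMessage(res))
    } else {
      reps[[i]] <- res
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  replicates <- dplyr::bind_rows(reps)
  failures <- dplyr::bind_rows(fails)
  if (!nrow(replicates)) {
    warning("every replicate failed; experiment marked invalid.",
            call. = FALSE)
    return(structure(list(summary = tibble::tibble(), replicates = replicates,
                          failures = failures, valid = FALSE,
                          config = config),
                     class = "bag_experiment"))
  }
  n_ok <- config$n_runs - nrow(failures)
  valid <- nrow(failures) <= 0.1 * config$n_runs
  if (!valid) {
    warning(sprintf("%d of %d replicates failed; experiment marked invalid.",
                    nrow(failures), config$n_runs), call. = FALSE)
  }
  summary <- replicates |>
    dplyr::arrange(.data$replicate_seed) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_n_stage1 = mean(.data$n_stage1),
      mean_n_final = mean(.data$n_final),
      mean_n_relevant = mean(.data$n_relevant),
      pct_relevant_of_stage1 =
        100 * mean(.data$n_relevant) / mean(.data$n_stage1),
      mean_pct_relevant = mean(.data$pct_relevant),
      sd_pct_relevant = sd(.data$pct_relevant),
      mean_pmse = mean(.data$pmse),
      mean_prpmse = mean(.data$prpmse),
      sd_prpmse = sd(.data$prpmse),
      favorable_pct = 100 * mean(.data$favorable),
      mean_mise = mean(.data$mise),
      .groups = "drop") |>
    dplyr::arrange(factor(.data$method,
                          levels = c("baseline", "B1", "B2", "B3")))
  structure(list(summary = summary, replicates = replicates,
                 failures = failures, valid = valid, config = config),
            class = "bag_experiment")
}

#' @export
print.bag_experiment <- function(x, ...) {
  cat(sprintf("<bag_experiment> %d replicates (%d failed)%s\n",
              x$config$n_runs, nrow(x$failures),
              if (x$valid) "" else " [INVALID]"))
  print(x$summary)
  invisible(x)
}

#' Sensitivity sweep over bag size and correlation threshold
#'
#' Re-runs the experiment over a grid of bag sizes `q` (rules B1/B3) and
#' correlation thresholds (rule B2), reusing the same replicate seeds in
#' every cell so differences are attributable to the parameters alone.
#'
#' @param config an [experiment_config()] providing everything else.
#' @param q_values integer vector of bag sizes.
#' @param thresholds numeric vector of B2 cutoffs.
#' @param progress print progress per cell.
#' @return A tibble of class `bag_sweep`: the per-method summaries of every
#'   grid cell, keyed by columns `q` and `threshold`.
#' @export
sensitivity_sweep <- function(config, q_values, thresholds,
                              progress = FALSE) {
  stopifnot(length(q_values) >= 1, length(thresholds) >= 1)
  grid <- expand.grid(q = q_values, threshold = thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$q <- as.integer(grid$q[i])
    cfg$threshold <- grid$threshold[i]
    if (progress) {
      cat(sprintf("q = %d, threshold = %.2f\n", cfg$q, cfg$threshold))
    }
    exp <- run_experiment(cfg)
    dplyr::mutate(exp$summary, q = cfg$q, threshold = cfg$threshold,
                  .before = 1)
  })
  class(out) <- c("bag_sweep", class(out))
  out
}

## experiment serialization ----------------------------------------------

#' Write experiment outputs to a directory
#'
#' Writes `summary.csv`, `replicates.csv`, `replicates.jsonl` and
#' `config.lock.yaml`.
#'
#' @param x a `bag_experiment`.
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "bag_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$summary, file.path(dir, "summary.csv"))
  readr::write_csv(x$replicates, file.path(dir, "replicates.csv"))
  writeLines(
    vapply(seq_len(nrow(x$replicates)), function(i) {
      jsonlite::toJSON(as.list(x$replicates[i, ]), auto_unbox = TRUE,
                       digits = NA, na = "null")
    }, character(1)),
    file.path(dir, "replicates.jsonl"))
  cfg <- x$config
  yaml::write_yaml(list(
    stage1_method = cfg$stage1_method, weight_scheme = cfg$weight_scheme,
    bag_rules = cfg$bag_rules, q = cfg$q, threshold = cfg$threshold,
    ranking = cfg$ranking, k_folds = cfg$k_folds, n_runs = cfg$n_runs,
    bootstrap_B = cfg$bootstrap_B, master_seed = cfg$master_seed, m = cfg$m,
    sim = list(n = cfg$sim$n, P = cfg$sim$P, n_true = cfg$sim$n_true,
               n_relevant = cfg$sim$n_relevant,
               beta_value = cfg$sim$beta_value, snr = cfg$sim$snr)
  ), file.path(dir, "config.lock.yaml"))
  invisible(dir)
}
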