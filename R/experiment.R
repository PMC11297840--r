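## Monte-Carlo experiment driver: generate train/test pairs, tune, fit,
## evaluate, and summarize tree recovery.

#' Configuration for a Monte-Carlo experiment
#'
#' @param study `"study1"` or `"study2"`.
#' @param replications number of Monte-Carlo replications.
#' @param n training and test sample size per replication.
#' @param depth tree depth D.
#' @param lambda mixing weight (study 2 only).
#' @param quantile_levels time-grid quantile levels.
#' @param nu boosting step length.
#' @param mstop_candidates candidate root iteration numbers for CV tuning;
#'   a single value skips cross-validation.
#' @param n_perm permutation count for the split tests.
#' @param folds CV folds.
#' @param master_seed master seed; per-replication seeds are derived
#'   deterministically from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(study = c("study1", "study2"),
                              replications = 10L, n = 1000L, depth = 2L,
                              lambda = 0.5,
                              quantile_levels = c(.1, .3, .5, .7, .9),
                              nu = 0.01,
                              mstop_candidates = c(0, 50, 100, 250, 500, 1000, 2500),
                              n_perm = 999L, folds = 5L,
                              master_seed = 1L) {
  study <- match.arg(study)
  stopifnot(replications >= 1, n >= 10, depth >= 0, folds >= 2)
  structure(list(study = study, replications = as.integer(replications),
                 n = as.integer(n), depth = as.integer(depth),
                 lambda = lambda, quantile_levels = quantile_levels,
                 nu = nu, mstop_candidates = mstop_candidates,
                 n_perm = as.integer(n_perm), folds = as.integer(folds),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

## derived per-replication seed, kept inside 32-bit integer range
replication_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) * 1000 + r) %% .Machine$integer.max)
}

#' Run a Monte-Carlo experiment
#'
#' For each replication: simulate a training and a test dataset, build the
#' time grid from a pilot sample, tune `m_stop1` by cross-validation (when
#' more than one candidate is given), fit the pseudo-value regression tree,
#' and evaluate RMSE, bias, IPCW Brier score and truncated C-index on the
#' test data against the exact simulated truth.  A failing replication is
#' logged and skipped; the failure count is reported.
#'
#' @param config an [experiment_config()].
#' @param keep_models if `TRUE`, fitted models are returned alongside the
#'   results table (needed for [summarize_tree_recovery()]).
#' @param verbose print per-replication progress.
#' @return A list of class `experiment_result`: `results` (one row per
#'   successful replication), `models` (optional), `failures`, `config`.
#' @export
run_experiment <- function(config, keep_models = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", config$replications)
  models <- if (keep_models) vector("list", config$replications) else NULL
  failures <- 0L
  for (r in seq_len(config$replications)) {
    seed_r <- replication_seed(config$master_seed, r)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_one_replication(config, seed_r, keep_models),
      error = function(e) {
        warning(sprintf("replication %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { failures <- failures + 1L; next }
    res$row$replication <- r
    res$row$seed <- seed_r
    res$row$seconds <- proc.time()[["elapsed"]] - t0
    rows[[r]] <- res$row
    if (keep_models) models[[r]] <- res$model
    if (verbose)
      message(sprintf("replication %d: RMSE %.4f, m_stop1 %d (%.1fs)",
                      r, res$row$rmse, res$row$m_stop1, res$row$seconds))
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(results = results, models = models, failures = failures,
                 config = config),
            class = "experiment_result")
}

run_one_replication <- function(config, seed_r, keep_models) {
  set.seed(seed_r)
  spec <- if (config$study == "study1") study1_spec() else study2_spec()
  sim_fun <- function(n) {
    if (config$study == "study1") simulate_study1(n, spec)
    else simulate_study2(n, config$lambda, spec)
  }
  pilot <- sim_fun(1000L)
  grid <- choose_time_grid(pilot$data$time, config$quantile_levels)
  train <- sim_fun(config$n)
  test <- sim_fun(config$n)
  K <- length(grid)
  tc <- tree_control(maxdepth = config$depth, n_perm = config$n_perm,
                     min_node_size = 5L * K)
  bc <- boost_control(nu = config$nu)
  if (length(config$mstop_candidates) > 1L) {
    cv <- cross_validate_mstop(train$data, grid,
                               candidates = config$mstop_candidates,
                               folds = config$folds,
                               tree_control = tc, boost_control = bc)
    m1 <- cv$m_stop1
  } else {
    m1 <- as.integer(config$mstop_candidates[1L])
  }
  model <- fit_prt(train$data, grid, m_stop1 = m1,
                   tree_control = tc, boost_control = bc)
  pred <- predict(model, test$data$x)
  truth <- test$true_survival(grid)
  acc <- mse_survival(pred, truth)
  bias <- bias_survival(pred, truth)
  br <- brier_score(test$data, pred, grid)
  tau <- max(as.numeric(grid))
  ci <- c_index(test$data, risk = 1 - pred[, K], tau = tau)
  row <- data.frame(study = config$study, n = config$n, depth = config$depth,
                    lambda = if (config$study == "study2") config$lambda else NA,
                    m_stop1 = m1, mse = acc$mse, rmse = acc$rmse,
                    bias = bias$overall, brier = br$overall, c_index = ci)
  list(row = row, model = if (keep_models) model else NULL)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo experiment (%s): %d successful replication(s), %d failure(s)\n",
              x$config$study, nrow(x$results), x$failures))
  num <- x$results[, c("rmse", "bias", "brier", "c_index")]
  print(round(rbind(mean = colMeans(num),
                    q25 = apply(num, 2, stats::quantile, 0.25, na.rm = TRUE),
                    q75 = apply(num, 2, stats::quantile, 0.75, na.rm = TRUE)), 4))
  invisible(x)
}

#' Classify recovered tree structures against the study-1 truth
#'
#' A depth-2 fit recovers the study-1 generating tree exactly when the root
#' splits on x1, the left daughter on x2 and the right daughter on x3.
#' Trees using all three variables in a different arrangement are classed
#' `wrong_order`; trees with fewer than three split variables are classed
#' `fewer_variables`.
#'
#' @param models list of fitted `prt` models (or `pv_tree` objects).
#' @return A list with the three proportions (summing to 1) and the
#'   per-model class vector.
#' @export
summarize_tree_recovery <- function(models) {
  cls <- vapply(models, function(m) {
    tree <- if (inherits(m, "prt")) m$tree else m
    nodes <- tree$nodes
    split_name <- function(id) {
      nd <- nodes[[as.character(id)]]
      if (is.null(nd) || is.null(nd$split)) NA_character_ else nd$split$name
    }
    v_root <- split_name(1); v_l <- split_name(2); v_r <- split_name(3)
    used <- as.character(stats::na.omit(c(v_root, v_l, v_r)))
    if (identical(v_root, "x1") && identical(v_l, "x2") && identical(v_r, "x3")) {
      "exact"
    } else if (length(used) == 3L && setequal(used, c("x1", "x2", "x3"))) {
      "wrong_order"
    } else {
      "fewer_variables"
    }
  }, character(1))
  list(exact = mean(cls == "exact"),
       wrong_order = mean(cls == "wrong_order"),
       fewer_variables = mean(cls == "fewer_variables"),
       classes = cls)
}
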