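# Scenario-grid orchestration: replications, model fitting, aggregation,
# the SPAM coverage validation study, and model ranking.

#' Experiment configuration
#'
#' Defaults reproduce the full study design: the 10 x 10 grid of spatial
#' and temporal correlations 0.05, 0.15, ..., 0.95, panels of 54 units x
#' 20 time points, 1000 replications per scenario, all four models, the
#' full-scale chain profile. Scaled-down runs override \code{n_reps},
#' panel dimensions and \code{chain}.
#'
#' @param sp_grid,tm_grid correlation grids, values in (0, 1).
#' @param n_reps replications per scenario.
#' @param models subset of \code{st_models()}.
#' @param n_units,n_times panel dimensions.
#' @param chain a \code{\link{chain_config}}.
#' @param priors a \code{\link{prior_config}}.
#' @param base_seed integer base seed; per-replication seeds are derived
#'   from it with a stable hash of (sp, tm, rep).
#' @param train_fraction training share for validation runs (default 0.7).
#' @return list of class \code{experiment_config}.
#' @export
experiment_config <- function(sp_grid = seq(0.05, 0.95, by = 0.1),
                              tm_grid = seq(0.05, 0.95, by = 0.1),
                              n_reps = 1000, models = st_models(),
                              n_units = 54, n_times = 20,
                              chain = chain_config("full"),
                              priors = prior_config(),
                              base_seed = 1L, train_fraction = 0.7) {
  if (!length(sp_grid) || !length(tm_grid)) stop("correlation grids must be non-empty")
  if (any(sp_grid <= 0 | sp_grid >= 1) || any(tm_grid <= 0 | tm_grid >= 1))
    stop("grid values must lie strictly inside (0, 1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  models <- vapply(models, check_model, character(1), USE.NAMES = FALSE)
  structure(list(sp_grid = sp_grid, tm_grid = tm_grid,
                 n_reps = as.integer(n_reps), models = models,
                 n_units = as.integer(n_units), n_times = as.integer(n_times),
                 chain = chain, priors = priors,
                 base_seed = as.integer(base_seed),
                 train_fraction = train_fraction),
            class = "experiment_config")
}

#' Stable per-replication seed
#'
#' Deterministic integer hash of (sp, tm, rep) added to the base seed, so
#' every scenario/replication is independently reproducible.
#'
#' @param base_seed integer.
#' @param sp,tm scenario correlations.
#' @param rep replication number.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, sp, tm, rep) {
  h <- (round(sp * 1000) * 100003 + round(tm * 1000) * 1009 + rep * 7919) %% 1000003
  as.integer((base_seed + h) %% .Machine$integer.max)
}

#' Scenario grid
#'
#' Cartesian product of the configured spatial and temporal correlation
#' grids, spatial value varying slowest. The default configuration yields
#' 100 scenarios.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return data frame with columns \code{sp}, \code{tm}.
#' @export
scenario_grid <- function(config) {
  g <- expand.grid(tm = config$tm_grid, sp = config$sp_grid,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(sp = g$sp, tm = g$tm)
}

#' Run one replication of the model comparison
#'
#' Generates one synthetic panel for the scenario and fits each requested
#' model on it, computing WAIC, RMSE and MAE. A model whose chain fails is
#' flagged \code{status = "failed"}; the other models are unaffected.
#'
#' @param sp,tm scenario correlations.
#' @param rep replication number (feeds the derived seed).
#' @param config an \code{\link{experiment_config}}.
#' @return data frame with one row per model: \code{sp, tm, rep, model,
#'   waic, lpd, p_waic, rmse, mae, cp, status}.
#' @export
run_replication <- function(sp, tm, rep, config) {
  seed <- derive_seed(config$base_seed, sp, tm, rep)
  scen <- scenario(sp, tm, config$n_units, config$n_times, seed = seed)
  panel <- generate_panel(scen)
  pdata <- as_panel_data(panel)
  rows <- lapply(config$models, function(model) {
    row <- data.frame(sp = sp, tm = tm, rep = rep, model = model,
                      waic = NA_real_, lpd = NA_real_, p_waic = NA_real_,
                      rmse = NA_real_, mae = NA_real_, cp = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    out <- tryCatch({
      fit <- run_chain(model, pdata, config$priors, config$chain)
      w <- waic(fit)
      yhat <- point_predictions(fit, pdata)
      row$waic <- w$waic; row$lpd <- w$lpd; row$p_waic <- w$p_waic
      row$rmse <- rmse(pdata$y, yhat)
      row$mae <- mae(pdata$y, yhat)
      row
    }, error = function(e) {
      row$status <- paste("failed:", conditionMessage(e))
      row
    })
    out
  })
  do.call(rbind, rows)
}

aggregate_metrics <- function(metrics, value_cols = c("waic", "rmse", "mae", "cp")) {
  ok <- metrics[metrics$status == "ok", , drop = FALSE]
  keys <- c("sp", "tm", "model")
  split_idx <- interaction(ok$sp, ok$tm, ok$model, drop = TRUE)
  rows <- lapply(split(ok, split_idx), function(d) {
    out <- d[1, keys, drop = FALSE]
    for (v in value_cols) {
      out[[paste0("mean_", v)]] <- mean(d[[v]])
      out[[paste0("sd_", v)]] <- if (nrow(d) > 1) sd(d[[v]]) else NA_real_
    }
    out$n_reps <- nrow(d)
    out
  })
  agg <- do.call(rbind, rows)
  fail <- metrics[metrics$status != "ok", , drop = FALSE]
  attr(agg, "n_failed") <- nrow(fail)
  agg <- agg[order(agg$sp, agg$tm, agg$model), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

read_done_keys <- function(path) {
  if (is.null(path) || !file.exists(path)) return(character(0))
  old <- read.csv(path, stringsAsFactors = FALSE)
  paste(old$sp, old$tm, old$rep, old$model)
}

#' Run the full scenario grid
#'
#' Loops scenarios x replications x models, optionally writing each metric
#' row incrementally to \code{<out_dir>/metrics.csv}. A rerun with the same
#' \code{out_dir} resumes, skipping rows already on disk. Aggregates are
#' arithmetic means over the completed replications of each scenario/model;
#' failed fits are excluded and counted.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param out_dir optional output directory for incremental results.
#' @param verbose print progress.
#' @return list of class \code{scenario_results} with \code{metrics} (one
#'   row per scenario/rep/model) and \code{aggregate}.
#' @export
run_grid <- function(config, out_dir = NULL, verbose = FALSE) {
  grid <- scenario_grid(config)
  path <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, "metrics.csv")
  }
  done <- read_done_keys(path)
  all_rows <- if (length(done)) list(read.csv(path, stringsAsFactors = FALSE)) else list()
  for (i in seq_len(nrow(grid))) {
    for (rep in seq_len(config$n_reps)) {
      key <- paste(grid$sp[i], grid$tm[i], rep, config$models)
      if (all(key %in% done)) next
      rows <- run_replication(grid$sp[i], grid$tm[i], rep, config)
      rows <- rows[!(paste(rows$sp, rows$tm, rows$rep, rows$model) %in% done), , drop = FALSE]
      all_rows[[length(all_rows) + 1L]] <- rows
      if (!is.null(path))
        write.table(rows, path, sep = ",", append = file.exists(path),
                    col.names = !file.exists(path), row.names = FALSE)
      if (verbose)
        message(sprintf("scenario sp=%.2f tm=%.2f rep %d done", grid$sp[i], grid$tm[i], rep))
    }
  }
  metrics <- do.call(rbind, all_rows)
  ord <- order(metrics$sp, metrics$tm, metrics$rep, metrics$model)
  metrics <- metrics[ord, , drop = FALSE]
  rownames(metrics) <- NULL
  agg <- aggregate_metrics(metrics, value_cols = c("waic", "rmse", "mae"))
  if (!is.null(out_dir))
    write.csv(agg, file.path(out_dir, "aggregate.csv"), row.names = FALSE)
  structure(list(metrics = metrics, aggregate = agg, config = config),
            class = "scenario_results")
}

#' Coverage validation study for the SPAM model
#'
#' For each scenario and replication: generate a panel, hold out 30% of the
#' records, fit SPAM on the remaining 70%, and compute the coverage
#' percentage of the 95% posterior-predictive intervals on the held-out
#' records. Aggregates the mean coverage per scenario.
#'
#' @inheritParams run_grid
#' @param level predictive-interval level (default 0.95).
#' @return list of class \code{validation_results} with \code{metrics} and
#'   per-scenario \code{aggregate} (mean coverage).
#' @export
run_validation <- function(config, out_dir = NULL, level = 0.95, verbose = FALSE) {
  grid <- scenario_grid(config)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (rep in seq_len(config$n_reps)) {
      seed <- derive_seed(config$base_seed, grid$sp[i], grid$tm[i], rep)
      scen <- scenario(grid$sp[i], grid$tm[i], config$n_units, config$n_times,
                       seed = seed)
      panel <- generate_panel(scen)
      split <- train_test_split(panel, config$train_fraction)
      pdata <- as_panel_data(panel, split = split)
      row <- data.frame(sp = grid$sp[i], tm = grid$tm[i], rep = rep,
                        model = "SPAM", cp = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      row <- tryCatch({
        fit <- run_chain("SPAM", pdata, config$priors, config$chain)
        row$cp <- coverage(fit, pdata, split$test_index, level = level)$cp
        row
      }, error = function(e) {
        row$status <- paste("failed:", conditionMessage(e)); row
      })
      rows[[length(rows) + 1L]] <- row
      if (verbose)
        message(sprintf("validation sp=%.2f tm=%.2f rep %d: cp=%.1f",
                        grid$sp[i], grid$tm[i], rep, row$cp))
    }
  }
  metrics <- do.call(rbind, rows)
  agg <- aggregate_metrics(metrics, value_cols = "cp")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(out_dir, "validation_metrics.csv"), row.names = FALSE)
    write.csv(agg, file.path(out_dir, "validation_aggregate.csv"), row.names = FALSE)
  }
  structure(list(metrics = metrics, aggregate = agg, config = config),
            class = "validation_results")
}

#' Rank models by mean WAIC per scenario
#'
#' Orders the models within each scenario by ascending mean WAIC (ties
#' broken by mean RMSE, then model name) and counts, per model, the number
#' of scenarios in which it ranks first.
#'
#' @param results a \code{scenario_results} object or its aggregate data
#'   frame.
#' @return list with \code{ranking} (data frame: sp, tm, rank, model,
#'   mean_waic) and \code{wins} (named integer vector).
#' @export
rank_models <- function(results) {
  agg <- if (inherits(results, "scenario_results")) results$aggregate else results
  if (length(unique(agg$model)) < 2) stop("need at least two models to rank")
  rows <- lapply(split(agg, interaction(agg$sp, agg$tm, drop = TRUE)), function(d) {
    d <- d[order(d$mean_waic, d$mean_rmse, d$model), , drop = FALSE]
    data.frame(sp = d$sp, tm = d$tm, rank = seq_len(nrow(d)),
               model = d$model, mean_waic = d$mean_waic,
               stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  rownames(ranking) <- NULL
  winners <- ranking$model[ranking$rank == 1]
  wins <- table(factor(winners, levels = sort(unique(agg$model))))
  list(ranking = ranking, wins = c(wins))
}

#' Export a scenario-grid aggregate as a correlation matrix layout
#'
#' Reshapes one metric for one model into a matrix with spatial correlation
#' on the rows and temporal correlation on the columns (the layout of the
#' study's comparison tables).
#'
#' @param agg aggregate data frame from \code{\link{run_grid}} or
#'   \code{\link{run_validation}}.
#' @param metric aggregate column, e.g. \code{"mean_waic"}.
#' @param model model name present in \code{agg}.
#' @return numeric matrix with dimnames sp x tm.
#' @export
metric_matrix <- function(agg, metric = "mean_waic", model = "SPAM") {
  d <- agg[agg$model == model, , drop = FALSE]
  sps <- sort(unique(d$sp)); tms <- sort(unique(d$tm))
  M <- matrix(NA_real_, length(sps), length(tms),
              dimnames = list(sp = sps, tm = tms))
  M[cbind(match(d$sp, sps), match(d$tm, tms))] <- d[[metric]]
  M
}
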