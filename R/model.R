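#' Gradient-boosting model configuration
#'
#' Hyperparameters of the boosted regression-tree learner plus an optional
#' tuning grid. Loss is squared error on ddG (kcal/mol). The defaults are
#' deliberately conservative, single-threaded, and fully deterministic given
#' `seed`.
#'
#' @param nrounds Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @param subsample Row subsampling fraction per round.
#' @param colsample_bytree Column subsampling fraction per tree.
#' @param lambda L2 regularization on leaf weights.
#' @param nthread Threads used by the learner (default 1; results must not
#'   depend on it, and grid selection never does).
#' @param seed Integer seed for all stochastic parts of training.
#' @param grid Optional named list of candidate values for any of the above
#'   hyperparameters, used by [grid_search()].
#' @return An object of class `model_config`.
#' @export
model_config <- function(nrounds = 500L, max_depth = 4L, eta = 0.05,
                         subsample = 1, colsample_bytree = 1, lambda = 1,
                         nthread = 1L, seed = 1L, grid = NULL) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, subsample = subsample,
                 colsample_bytree = colsample_bytree, lambda = lambda,
                 nthread = as.integer(nthread), seed = as.integer(seed),
                 grid = grid),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> nrounds=", x$nrounds, " max_depth=", x$max_depth,
      " eta=", x$eta, " subsample=", x$subsample,
      " colsample_bytree=", x$colsample_bytree, " lambda=", x$lambda,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Fit the boosted-tree ddG regression model
#'
#' Trains a gradient-boosted decision-tree ensemble (via \pkg{xgboost},
#' squared-error loss) on a feature table produced by
#' [featurize_dataset()] or [assemble_feature_vector()]. The fitted object
#' carries the feature schema (names and groups), the configuration, and
#' training metadata; [predict.ddg_model()] enforces the schema on new data.
#'
#' @param x Numeric feature matrix with column names; optionally an attribute
#'   `groups` labelling each column's feature group.
#' @param y Numeric target vector (ddG, kcal/mol), same length as `nrow(x)`.
#' @param config A [model_config()].
#' @return An object of class `ddg_model`.
#' @export
ddg_fit <- function(x, y, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) != length(y)) {
    stop("nrow(x) (", nrow(x), ") != length(y) (", length(y), ")")
  }
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (any(!is.finite(y))) stop("targets must be finite")
  if (any(!is.finite(x))) stop("features must be finite (no missing values)")
  groups <- attr(x, "groups") %||% rep("feature", ncol(x))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "reg:squarederror",
                 max_depth = config$max_depth,
                 eta = config$eta,
                 subsample = config$subsample,
                 colsample_bytree = config$colsample_bytree,
                 lambda = config$lambda,
                 nthread = config$nthread,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nrounds, verbose = 0)
  structure(list(
    booster = booster,
    schema = data.frame(name = colnames(x), group = groups,
                        stringsAsFactors = FALSE),
    config = config,
    meta = list(n = nrow(x), p = ncol(x), seed = config$seed,
                trained = format(Sys.time(), "%Y-%m-%d"))
  ), class = "ddg_model")
}

#' @export
print.ddg_model <- function(x, ...) {
  cat("<ddg_model> boosted regression trees\n")
  cat("  features: ", nrow(x$schema), " (",
      paste(names(table(x$schema$group)), collapse = ", "), ")\n", sep = "")
  cat("  training: n=", x$meta$n, ", nrounds=", x$config$nrounds,
      ", max_depth=", x$config$max_depth, ", eta=", x$config$eta,
      ", seed=", x$meta$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ddg_model <- function(object, ...) {
  gi <- tryCatch(group_importance(object), error = function(e) NULL)
  out <- list(model = object, group_importance = gi)
  class(out) <- "summary.ddg_model"
  out
}

#' @export
print.summary.ddg_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$group_importance)) {
    cat("  group importance (gain, normalized):\n")
    gi <- sort(x$group_importance, decreasing = TRUE)
    for (g in names(gi)) cat(sprintf("    %-13s %.3f\n", g, gi[[g]]))
  }
  invisible(x)
}

#' Predict ddG for new mutations
#'
#' @param object A fitted `ddg_model`.
#' @param newdata Feature matrix conforming to the model's schema (same
#'   column names, any order; extra or missing columns raise an error
#'   naming them).
#' @param ... Unused.
#' @return Numeric vector of predicted ddG values (kcal/mol), one per row.
#' @export
predict.ddg_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (nrow(x) == 0L) return(numeric(0))
  if (is.null(colnames(x))) {
    if (ncol(x) != nrow(object$schema)) {
      stop("newdata has ", ncol(x), " columns; model expects ",
           nrow(object$schema))
    }
    colnames(x) <- object$schema$name
  }
  missing_f <- setdiff(object$schema$name, colnames(x))
  extra_f <- setdiff(colnames(x), object$schema$name)
  if (length(missing_f) || length(extra_f)) {
    stop("feature schema mismatch",
         if (length(missing_f)) paste0("; missing: ",
           paste(utils::head(missing_f, 5), collapse = ", ")),
         if (length(extra_f)) paste0("; extra: ",
           paste(utils::head(extra_f, 5), collapse = ", ")))
  }
  x <- x[, object$schema$name, drop = FALSE]
  stats::predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Importance bar plot of a fitted model
#'
#' @param x A `ddg_model`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ddg_model <- function(x, ...) {
  gi <- sort(group_importance(x), decreasing = TRUE)
  graphics::barplot(gi, ylab = "normalized gain importance",
                    xlab = "feature group", ...)
  invisible(x)
}

#' Grouped feature importance
#'
#' Per-feature gain importances of the fitted ensemble (average loss
#' reduction attributable to splits on the feature) are summed within each
#' schema group and normalized to sum to one over groups. Groups never used
#' for a split get importance zero.
#'
#' @param m A fitted `ddg_model`.
#' @return Named numeric vector over the model's feature groups, summing
#'   to 1.
#' @export
group_importance <- function(m) {
  stopifnot(inherits(m, "ddg_model"))
  imp <- xgboost::xgb.importance(model = m$booster)
  if (is.null(imp) || nrow(imp) == 0L) {
    stop("model has no splits; importance undefined")
  }
  gain <- stats::setNames(imp$Gain, imp$Feature)
  per_group <- tapply(
    gain[m$schema$name], m$schema$group,
    function(v) sum(v, na.rm = TRUE)
  )
  out <- as.numeric(per_group) / sum(per_group)
  names(out) <- names(per_group)
  out
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every point of `config$grid` by k-fold cross-validation and
#' returns the configuration with the best mean CV Pearson correlation
#' (ties broken by lower mean MSE, then by grid order). The fold split is
#' derived once from `config$seed` and shared by all grid points, so the
#' selection is deterministic and independent of thread count.
#'
#' @param x Feature matrix.
#' @param y Targets.
#' @param config A [model_config()] whose `grid` is a non-empty named list,
#'   e.g. `list(max_depth = c(3, 5, 7), eta = c(0.05, 0.1))`.
#' @param folds Number of CV folds (default 5).
#' @return The winning `model_config` (grid dropped), with attribute
#'   `grid_results`: a data frame of all evaluated points and their scores.
#' @export
grid_search <- function(x, y, config, folds = 5L) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(config$grid) || length(config$grid) == 0L) {
    stop("config$grid must be a non-empty named list")
  }
  x <- as.matrix(x)
  grid_df <- expand.grid(config$grid, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  res <- data.frame(grid_df, pcc = NA_real_, mse = NA_real_,
                    failed = FALSE)
  for (g in seq_len(nrow(grid_df))) {
    cfg_g <- config
    for (h in names(grid_df)) cfg_g[[h]] <- grid_df[g, h]
    cfg_g$grid <- NULL
    pccs <- mses <- numeric(folds)
    ok <- TRUE
    for (k in seq_len(folds)) {
      test <- fold_id == k
      fit <- tryCatch(
        ddg_fit(x[!test, , drop = FALSE], y[!test], cfg_g),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred <- predict(fit, x[test, , drop = FALSE])
      pccs[k] <- suppressWarnings(stats::cor(pred, y[test]))
      mses[k] <- mean((pred - y[test])^2)
    }
    if (ok) {
      res$pcc[g] <- mean(pccs)
      res$mse[g] <- mean(mses)
    } else {
      res$failed[g] <- TRUE
    }
  }
  if (all(res$failed)) stop("every grid point failed to fit")
  score <- ifelse(res$failed | is.na(res$pcc), -Inf, res$pcc)
  tiebreak <- ifelse(res$failed | is.na(res$mse), Inf, res$mse)
  best <- order(-score, tiebreak, seq_len(nrow(res)))[1]
  out <- config
  for (h in names(grid_df)) out[[h]] <- grid_df[best, h]
  out$nrounds <- as.integer(out$nrounds)
  out$max_depth <- as.integer(out$max_depth)
  out$grid <- NULL
  attr(out, "grid_results") <- res
  out
}

#' Default tuning grid
#'
#' Replaceable default candidate values for [grid_search()]: tree count
#' \{200, 500\}, depth \{3, 5, 7\}, learning rate \{0.05, 0.1\}, subsample
#' \{0.8, 1.0\}.
#'
#' @return Named list suitable for `model_config(grid = ...)`.
#' @export
default_grid <- function() {
  list(nrounds = c(200L, 500L), max_depth = c(3L, 5L, 7L),
       eta = c(0.05, 0.1), subsample = c(0.8, 1.0))
}

#' Repeated k-fold cross-validation
#'
#' The evaluation protocol of the package: for each repeat, records are
#' shuffled with a fresh seed derived from `seed`, split into `folds` folds
#' of sizes differing by at most one, and each fold is predicted by a model
#' trained on the remaining folds (so every record is tested exactly once
#' per repeat). Per-fold Pearson correlation, MSE and MAE are recorded and
#' aggregated.
#'
#' @param x Feature matrix.
#' @param y Targets.
#' @param config A [model_config()].
#' @param folds Folds per repeat (default 5).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed governing all fold assignments.
#' @return An object of class `cv_report`: list with `results` (one row per
#'   repeat x fold: `pcc`, `mse`, `mae`, `n_test`), `summary` (means and
#'   standard deviations), `assignments` (repeats x n fold-id matrix), and
#'   the call parameters.
#' @export
repeated_cv <- function(x, y, config = model_config(), folds = 5L,
                        repeats = 100L, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- as.integer(folds)
  repeats <- as.integer(repeats)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("n (", n, ") must be >= folds (", folds, ")")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  assignments <- matrix(NA_integer_, repeats, n)
  for (r in seq_len(repeats)) {
    assignments[r, ] <- sample(rep_len(seq_len(folds), n))
  }

  rows <- vector("list", repeats * folds)
  k_out <- 0L
  for (r in seq_len(repeats)) {
    for (k in seq_len(folds)) {
      test <- assignments[r, ] == k
      fit <- ddg_fit(x[!test, , drop = FALSE], y[!test], config)
      pred <- predict(fit, x[test, , drop = FALSE])
      k_out <- k_out + 1L
      rows[[k_out]] <- data.frame(
        rep = r, fold = k, n_test = sum(test),
        pcc = suppressWarnings(stats::cor(pred, y[test])),
        mse = mean((pred - y[test])^2),
        mae = mean(abs(pred - y[test]))
      )
    }
  }
  results <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("pcc", "mse", "mae"),
    mean = c(mean(results$pcc), mean(results$mse), mean(results$mae)),
    sd = c(stats::sd(results$pcc), stats::sd(results$mse),
           stats::sd(results$mae))
  )
  structure(list(results = results, summary = summary,
                 assignments = assignments, folds = folds,
                 repeats = repeats, seed = seed, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$repeats, " x ", x$folds, "-fold cross-validation (n=",
      ncol(x$assignments), ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s mean %.4f  sd %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Persist a fitted model to disk
#'
#' Writes a self-describing file: package version, feature schema,
#' configuration and the serialized ensemble.
#'
#' @param m A `ddg_model`.
#' @param path Output path.
#' @export
save_ddg_model <- function(m, path) {
  stopifnot(inherits(m, "ddg_model"))
  payload <- list(
    format = "seqddg_model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("seqddg")),
    schema = m$schema,
    config = unclass(m$config),
    meta = m$meta,
    booster_raw = xgboost::xgb.save.raw(m$booster)
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model saved by [save_ddg_model()]
#'
#' @param path Model file path.
#' @return A `ddg_model`.
#' @export
load_ddg_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "seqddg_model")) {
    stop("not a seqddg model file: ", path)
  }
  if (payload$format_version > 1L) {
    stop("model file version ", payload$format_version,
         " is newer than this package understands")
  }
  cfg <- payload$config
  class(cfg) <- "model_config"
  structure(list(booster = xgboost::xgb.load.raw(payload$booster_raw),
                 schema = payload$schema, config = cfg, meta = payload$meta),
            class = "ddg_model")
}
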