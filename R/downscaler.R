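#' Regression fit statistics
#'
#' The three metrics used to judge downscaling fits:
#' `r2 = 1 - sum((o-p)^2)/sum((o-mean(o))^2)`, `rmse = sqrt(mean((o-p)^2))`,
#' `mae = mean(|o-p|)`. `r2` is `NA` when the observations are constant.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return Named vector `c(r2, rmse, mae)`.
#' @export
fit_statistics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2) stop("need at least 2 observations")
  e <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  c(r2 = if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_,
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)))
}

feature_matrix <- function(samples) {
  as.data.frame(samples[, covariate_names(), drop = FALSE])
}

#' Tune random-forest hyperparameters by repeated cross-validation
#'
#' Evaluates every (mtry, ntree) pair by repeated k-fold cross-validation
#' on the training samples and returns the pair with the lowest mean CV
#' RMSE (ties broken toward smaller ntree, then smaller mtry — smaller
#' forests win). Fold assignments are shared across configurations within
#' a repeat, and everything is deterministic for a fixed seed.
#'
#' @param train Training `sample_set` with responses.
#' @param mtry_grid,ntree_grid Candidate values (defaults mtry 2/4/7/13,
#'   ntree 250/500).
#' @param cv_folds Folds per repeat (default 10).
#' @param cv_repeats Repeats (default 5).
#' @param seed Integer seed.
#' @return List with `mtry`, `ntree`, `cv` (named r2/rmse/mae of the chosen
#'   pair, fold-averaged) and `results` (all pairs).
#' @export
tune_hyperparameters <- function(train, mtry_grid = c(2, 4, 7, 13),
                                 ntree_grid = c(250, 500),
                                 cv_folds = 10, cv_repeats = 5, seed = 1) {
  if (length(mtry_grid) == 0 || length(ntree_grid) == 0)
    stop("empty hyperparameter grid")
  n <- nrow(train)
  if (n < cv_folds) stop("fewer samples than CV folds")
  x <- feature_matrix(train)
  y <- train$response
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid)
  folds <- lapply(seq_len(cv_repeats), function(r)
    with_seed(sub_seed(seed, 7L, r), sample(rep_len(seq_len(cv_folds), n))))

  scores <- matrix(NA_real_, nrow(grid), 3,
                   dimnames = list(NULL, c("r2", "rmse", "mae")))
  for (g in seq_len(nrow(grid))) {
    per_fold <- matrix(NA_real_, cv_repeats * cv_folds, 3)
    row <- 0L
    for (r in seq_len(cv_repeats)) {
      for (f in seq_len(cv_folds)) {
        hold <- folds[[r]] == f
        if (!any(hold) || sum(!hold) < 2) next
        fit <- ranger::ranger(
          x = x[!hold, , drop = FALSE], y = y[!hold],
          num.trees = grid$ntree[g], mtry = grid$mtry[g],
          seed = sub_seed(seed, g, r, f), num.threads = 1
        )
        pred <- stats::predict(fit, x[hold, , drop = FALSE],
                               num.threads = 1)$predictions
        row <- row + 1L
        per_fold[row, ] <- if (sum(hold) >= 2)
          fit_statistics(y[hold], pred)
        else c(NA, sqrt(mean((y[hold] - pred)^2)), mean(abs(y[hold] - pred)))
      }
    }
    scores[g, ] <- colMeans(per_fold[seq_len(row), , drop = FALSE],
                            na.rm = TRUE)
  }
  results <- cbind(grid, scores)
  best <- order(results$rmse, results$ntree, results$mtry)[1]
  list(mtry = results$mtry[best], ntree = results$ntree[best],
       cv = c(r2 = results$r2[best], rmse = results$rmse[best],
              mae = results$mae[best]),
       results = results)
}

#' Fit the random-forest density downscaler
#'
#' The core model: a random-forest regression of district census density
#' on the 13 covariates extracted at settlement pseudo-sampling points.
#' Because forest predictions are averages of leaf means, predictions are
#' always within the range of the training responses.
#'
#' @param train Training `sample_set` with responses attached.
#' @param mtry Candidate predictors per split (1..13).
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @return An object of class `density_rf`.
#' @examples
#' \donttest{
#' ls <- default_landscape(seed = 42, years = 2015, n_districts = 8,
#'                         n_rows = 60, n_cols = 60)
#' dens <- compute_density(aggregate_truth_to_census(ls))
#' samples <- build_sample_set(ls, dens, 2015, "small_ruminant")
#' fit <- density_rf(samples, mtry = 4, ntree = 250, seed = 1)
#' fit
#' }
#' @export
density_rf <- function(train, mtry = 4, ntree = 500, seed = 1) {
  if (mtry < 1 || mtry > length(covariate_names()))
    stop("mtry must be between 1 and ", length(covariate_names()))
  if (ntree < 1) stop("ntree must be >= 1")
  y <- train$response
  if (anyNA(y)) stop("training samples have missing responses")
  if (length(unique(round(y, 12))) < 2)
    warning("training responses are (nearly) constant")
  x <- feature_matrix(train)
  forest <- ranger::ranger(x = x, y = y, num.trees = ntree, mtry = mtry,
                           seed = seed, num.threads = 1)
  structure(
    list(forest = forest, mtry = mtry, ntree = ntree, seed = seed,
         covariates = covariate_names(),
         train_x = x, train_y = y,
         response_range = range(y),
         species = train$species[1], year = train$year[1],
         buffer_km = train$buffer_km[1]),
    class = "density_rf"
  )
}

#' @export
print.density_rf <- function(x, ...) {
  cat(sprintf(
    "<density_rf> %s @ %s: %d samples, mtry %d, %d trees (buffer %g km)\n",
    x$species, x$year, length(x$train_y), x$mtry, x$ntree, x$buffer_km))
  stats <- fit_statistics(x$train_y, stats::predict(
    x$forest, x$train_x, num.threads = 1)$predictions)
  cat(sprintf("  training fit: R2 %.3f, RMSE %.3f, MAE %.3f (resubstitution)\n",
              stats["r2"], stats["rmse"], stats["mae"]))
  invisible(x)
}

#' @export
predict.density_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$covariates, names(newdata))
  if (length(missing))
    stop("newdata missing covariate(s): ", paste(missing, collapse = ", "))
  stats::predict(object$forest,
                 newdata[, object$covariates, drop = FALSE],
                 num.threads = 1)$predictions
}

#' @export
residuals.density_rf <- function(object, ...) {
  object$train_y - stats::predict(object$forest, object$train_x,
                                  num.threads = 1)$predictions
}

#' @export
summary.density_rf <- function(object, ...) {
  pred <- stats::predict(object$forest, object$train_x,
                         num.threads = 1)$predictions
  out <- list(
    call_info = c(mtry = object$mtry, ntree = object$ntree),
    n = length(object$train_y),
    train = fit_statistics(object$train_y, pred),
    oob_mse = object$forest$prediction.error,
    importance = variable_importance(object, n_perm = 5,
                                     seed = object$seed)
  )
  class(out) <- "summary.density_rf"
  out
}

#' @export
print.summary.density_rf <- function(x, ...) {
  cat(sprintf("density_rf: n = %d, mtry = %d, ntree = %d\n",
              x$n, x$call_info["mtry"], x$call_info["ntree"]))
  cat(sprintf("  training  R2 %.3f  RMSE %.3f  MAE %.3f\n",
              x$train["r2"], x$train["rmse"], x$train["mae"]))
  cat(sprintf("  out-of-bag MSE %.3f\n", x$oob_mse))
  cat("  top predictors:\n")
  top <- utils::head(x$importance, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-20s %.4f\n", top$covariate[i], top$importance[i]))
  invisible(x)
}

#' @export
plot.density_rf <- function(x, ...) {
  pred <- stats::predict(x$forest, x$train_x, num.threads = 1)$predictions
  graphics::plot(x$train_y, pred,
                 xlab = "observed district density (head/km2)",
                 ylab = "predicted density (head/km2)",
                 main = "density_rf training fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Predict a gridded density surface
#'
#' Applies a fitted downscaler to a year's 13 covariate rasters, one
#' prediction per pixel; pixels with any missing covariate stay `NA`.
#'
#' @param object A [density_rf()] fit.
#' @param landscape Landscape with predictors for `year`.
#' @param year Prediction year.
#' @return A [density_surface()] with stage `"predicted"`.
#' @export
predict_surface <- function(object, landscape, year) {
  yr <- as.character(year)
  layers <- landscape$predictors[[yr]]
  if (is.null(layers)) stop("no predictors for year ", year)
  missing <- setdiff(object$covariates, names(layers))
  if (length(missing))
    stop("landscape missing covariate layer(s): ",
         paste(missing, collapse = ", "))
  geom <- landscape$geometry
  newdata <- as.data.frame(lapply(layers[object$covariates], as.vector))
  ok <- stats::complete.cases(newdata)
  vals <- rep(NA_real_, nrow(newdata))
  if (any(ok))
    vals[ok] <- stats::predict(object$forest,
                               newdata[ok, , drop = FALSE],
                               num.threads = 1)$predictions
  density_surface(matrix(vals, geom$n_rows, geom$n_cols), geom,
                  species = object$species, year = year,
                  stage = "predicted")
}

#' Fit on training samples and predict the year's surface
#'
#' @param train Training `sample_set`.
#' @param config List with `mtry`, `ntree` (e.g. from
#'   [tune_hyperparameters()]).
#' @param landscape Landscape with predictors.
#' @param year Prediction year.
#' @param seed Integer seed.
#' @return A predicted [density_surface()]; the fitted model is attached
#'   as attribute `"model"`.
#' @export
fit_and_predict <- function(train, config, landscape, year, seed = 1) {
  model <- density_rf(train, mtry = config$mtry, ntree = config$ntree,
                      seed = seed)
  surface <- predict_surface(model, landscape, year)
  attr(surface, "model") <- model
  surface
}

split_label <- function(fraction) {
  sprintf("%d:%d", round(fraction * 100), round((1 - fraction) * 100))
}

#' Run the buffer x split model-selection experiment
#'
#' Fits one independently tuned random forest per combination of buffer
#' radius (0/2/5/10 km) and train:test split (70:30/80:20/90:10) — twelve
#' models — and reports cross-validation and independent-test metrics for
#' each, the experiment used to fix the sampling design for all years.
#'
#' @param landscape Landscape with predictors for `year`.
#' @param census Census table covering `year`.
#' @param year,species Selection slice.
#' @param k Settlements per district (default 10).
#' @param buffers,splits Design grid (defaults: the twelve-cell grid).
#' @param mtry_grid,ntree_grid,cv_folds,cv_repeats Tuning controls, see
#'   [tune_hyperparameters()].
#' @param grouping Split grouping, see [split_train_test()].
#' @param seed Integer seed.
#' @return Data frame of class `experiment_grid`, one row per cell.
#' @export
run_experiment_grid <- function(landscape, census, year, species,
                                k = 10, buffers = c(0, 2, 5, 10),
                                splits = c(0.7, 0.8, 0.9),
                                mtry_grid = c(2, 4, 7, 13),
                                ntree_grid = c(250, 500),
                                cv_folds = 10, cv_repeats = 5,
                                grouping = "point", seed = 1) {
  densities <- compute_density(census)
  rows <- list()
  for (b in seq_along(buffers)) {
    samples <- build_sample_set(landscape, densities, year, species,
                                k = k, buffer_km = buffers[b])
    for (s in seq_along(splits)) {
      sp <- split_train_test(samples, splits[s],
                             seed = sub_seed(seed, b, s),
                             grouping = grouping)
      tuned <- tune_hyperparameters(sp$train, mtry_grid, ntree_grid,
                                    cv_folds, cv_repeats,
                                    seed = sub_seed(seed, b, s, 1L))
      model <- density_rf(sp$train, mtry = tuned$mtry, ntree = tuned$ntree,
                          seed = sub_seed(seed, b, s, 2L))
      test_stats <- fit_statistics(sp$test$response,
                                   predict(model, sp$test))
      rows[[length(rows) + 1L]] <- data.frame(
        buffer_km = buffers[b], split = split_label(splits[s]),
        train_fraction = splits[s],
        n_train = nrow(sp$train), n_test = nrow(sp$test),
        mtry = tuned$mtry, ntree = tuned$ntree,
        cv_r2 = tuned$cv[["r2"]], cv_rmse = tuned$cv[["rmse"]],
        cv_mae = tuned$cv[["mae"]],
        test_r2 = test_stats[["r2"]], test_rmse = test_stats[["rmse"]],
        test_mae = test_stats[["mae"]]
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("experiment_grid", "data.frame")
  out
}

#' Choose the best buffer and split from an experiment grid
#'
#' Selection is by the independent-test scores: highest test R^2, ties
#' broken by lower test RMSE, then lower test MAE, then larger buffer.
#' Test partitions differ across splits, so R^2 — which normalises by each
#' partition's own variance — is the comparable criterion; RMSE/MAE then
#' order rows of equal explanatory power.
#'
#' @param grid An `experiment_grid` (or any data frame with `buffer_km`,
#'   `split`, `test_r2`, `test_rmse`, `test_mae`).
#' @return List with `buffer_km`, `split`, and `train_fraction` (parsed
#'   from the split label).
#' @export
select_best_model <- function(grid) {
  need <- c("buffer_km", "split", "test_r2", "test_rmse", "test_mae")
  missing <- setdiff(need, names(grid))
  if (length(missing))
    stop("grid missing column(s): ", paste(missing, collapse = ", "))
  o <- order(-grid$test_r2, grid$test_rmse, grid$test_mae, -grid$buffer_km)
  best <- grid[o[1], ]
  frac <- as.numeric(sub(":.*$", "", best$split)) / 100
  list(buffer_km = best$buffer_km, split = best$split,
       train_fraction = frac)
}

#' Permutation variable importance
#'
#' For each covariate, the mean increase in training RMSE when that
#' column is permuted (over `n_perm` seeded permutations), floored at 0
#' and sorted in decreasing order. Permutation importance is defined by
#' the model's predictions alone, so it is comparable across forest
#' implementations.
#'
#' @param model A [density_rf()] fit.
#' @param n_perm Permutations per covariate (default 10).
#' @param seed Integer seed.
#' @return Data frame `covariate, importance` in decreasing order.
#' @export
variable_importance <- function(model, n_perm = 10, seed = 1) {
  x <- model$train_x
  y <- model$train_y
  base_rmse <- sqrt(mean((y - stats::predict(
    model$forest, x, num.threads = 1)$predictions)^2))
  imp <- vapply(model$covariates, function(nm) {
    deltas <- vapply(seq_len(n_perm), function(p) {
      xp <- x
      xp[[nm]] <- with_seed(sub_seed(seed, match(nm, model$covariates), p),
                            sample(xp[[nm]]))
      sqrt(mean((y - stats::predict(model$forest, xp,
                                    num.threads = 1)$predictions)^2)) -
        base_rmse
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  out <- data.frame(covariate = model$covariates,
                    importance = pmax(imp, 0))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Covariate response curve
#'
#' Mean predicted density along one covariate's observed range with every
#' other covariate held at its training median — the standard univariate
#' view of a forest's learned response.
#'
#' @param model A [density_rf()] fit.
#' @param covariate Covariate name.
#' @param n_points Grid size along the covariate's range (default 25).
#' @return Data frame `value, density`.
#' @export
response_curve <- function(model, covariate, n_points = 25) {
  if (!covariate %in% model$covariates)
    stop("unknown covariate: ", covariate)
  rng <- range(model$train_x[[covariate]])
  grid_vals <- seq(rng[1], rng[2], length.out = n_points)
  newdata <- as.data.frame(lapply(model$train_x, function(v)
    rep(stats::median(v), n_points)))
  newdata[[covariate]] <- grid_vals
  data.frame(value = grid_vals,
             density = stats::predict(model$forest, newdata,
                                      num.threads = 1)$predictions)
}
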