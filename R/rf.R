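#' Random-forest driver analysis configuration
#'
#' Settings for [fit_rf_cv()] and [permutation_importance_test()]: a 7:3
#' train/test split (stratified by land type when available), five-fold
#' cross-validated selection of `mtry` over 3–15, 500 trees, and a
#' 1000-permutation significance test of variable importance with
#' significance levels 0.001 / 0.01 / 0.05.
#'
#' @param train_fraction Fraction of observations used for training.
#' @param cv_folds Number of cross-validation folds for `mtry` selection.
#' @param mtry_grid Candidate values of `mtry` (variables tried per split).
#' @param n_trees Trees per forest.
#' @param n_permutations Response permutations for the significance test.
#' @param alpha Significance levels mapped to `***`, `**`, `*`.
#' @param plus_one Use the `(1 + count) / (1 + B)` permutation p-value
#'   instead of the plain proportion `count / B`.
#' @param seed Integer seed for the whole driver analysis.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(train_fraction = 0.7, cv_folds = 5, mtry_grid = 3:15,
                      n_trees = 500, n_permutations = 1000,
                      alpha = c(0.001, 0.01, 0.05), plus_one = FALSE,
                      seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1.")
  }
  if (n_permutations < 1) abort("n_permutations must be at least 1.")
  if (any(mtry_grid < 1)) abort("mtry values must be positive.")
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 mtry_grid = as.integer(mtry_grid), n_trees = as.integer(n_trees),
                 n_permutations = as.integer(n_permutations),
                 alpha = sort(alpha), plus_one = plus_one,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Fit a random-forest regression with cross-validated mtry
#'
#' Regresses a comprehensive score (typically the weighted grey relevance
#' per site) on vegetation and soil indicators. Observations are split
#' 7:3 into training and test sets — stratified by `strata` (default the
#' `land_type` column, if present) so no land type is lost from training —
#' `mtry` is chosen by k-fold cross-validation on the training set
#' (smallest CV RMSE; ties go to the smaller `mtry`), and fit quality is
#' reported as R-squared and RMSE on the held-out test set.
#'
#' @param predictors Tibble of predictor columns (numeric columns are
#'   used); may carry `plot_id` / `land_type` identifier columns.
#' @param response Numeric response, one value per row of `predictors`.
#' @param config An [rf_config()].
#' @param strata Optional factor for stratified splitting; defaults to
#'   `predictors$land_type` when present.
#'
#' @return An object of class `rf_fit`: list with `model` (the
#'   randomForest), `mtry`, `cv` (tibble of per-mtry CV RMSE),
#'   `r_squared`, `rmse` (held-out), `train_idx`, `test_idx`, `x`, `y`,
#'   `config`.
#' @export
#' @examples
#' set.seed(1)
#' x <- tibble::tibble(a = rnorm(30), b = rnorm(30))
#' fit <- fit_rf_cv(x, x$a + rnorm(30, 0, 0.1),
#'                  rf_config(mtry_grid = 1:2, n_trees = 100, seed = 4))
#' glance(fit)
fit_rf_cv <- function(predictors, response, config = rf_config(),
                      strata = NULL) {
  num_cols <- names(predictors)[vapply(predictors, is.numeric, logical(1))]
  x <- as.data.frame(predictors[num_cols])
  n <- nrow(x)
  if (n < 10) abort("driver analysis needs at least 10 observations.")
  if (length(response) != n) abort("response length must match predictors.")
  if (!all(is.finite(response))) abort("response must be finite.")
  if (sd(response) == 0) abort("response is constant; nothing to model.")
  if (is.null(strata) && "land_type" %in% names(predictors)) {
    strata <- predictors$land_type
  }
  if (is.null(strata)) strata <- rep("all", n)

  grid <- config$mtry_grid
  if (any(grid > ncol(x))) {
    warn(sprintf("mtry grid truncated to the %d available predictors.", ncol(x)))
    grid <- grid[grid <= ncol(x)]
    if (length(grid) == 0) grid <- ncol(x)
  }

  withr::with_seed(config$seed, {
    # stratified 7:3 split: each stratum keeps ~train_fraction in training
    train_idx <- unlist(lapply(split(seq_len(n), strata), function(idx) {
      k <- max(1, round(length(idx) * config$train_fraction))
      if (k == length(idx) && length(idx) > 1) k <- length(idx) - 1
      sample(idx, k)
    }), use.names = FALSE)
    test_idx <- setdiff(seq_len(n), train_idx)

    xt <- x[train_idx, , drop = FALSE]
    yt <- response[train_idx]
    k_folds <- min(config$cv_folds, length(yt))
    fold <- sample(rep(seq_len(k_folds), length.out = length(yt)))
    cv <- purrr::map_dfr(grid, function(m) {
      sq_err <- unlist(lapply(seq_len(k_folds), function(f) {
        tr <- fold != f
        rf <- randomForest::randomForest(xt[tr, , drop = FALSE], yt[tr],
                                         mtry = m, ntree = config$n_trees,
                                         replace = FALSE)
        (predict(rf, xt[!tr, , drop = FALSE]) - yt[!tr])^2
      }))
      tibble::tibble(mtry = m, cv_rmse = sqrt(mean(sq_err)))
    })
    best_mtry <- cv$mtry[which.min(cv$cv_rmse)]
    # trees are grown on 0.632n subsamples without replacement: with a
    # site-level sample a bootstrap tree can have an empty out-of-bag set,
    # which leaves the OOB permutation importance undefined
    model <- randomForest::randomForest(xt, yt, mtry = best_mtry,
                                        ntree = config$n_trees,
                                        replace = FALSE,
                                        importance = TRUE)
    pred <- predict(model, x[test_idx, , drop = FALSE])
  })
  y_test <- response[test_idx]
  ss_res <- sum((y_test - pred)^2)
  ss_tot <- sum((y_test - mean(y_test))^2)
  structure(
    list(model = model, mtry = best_mtry, cv = cv,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         rmse = sqrt(mean((y_test - pred)^2)),
         train_idx = sort(train_idx), test_idx = test_idx,
         x = x, y = response, config = config),
    class = "rf_fit"
  )
}

#' @export
print.rf_fit <- function(x, ...) {
  cat("<rf_fit>\n")
  cat(sprintf("  %d predictors, %d train / %d test observations\n",
              ncol(x$x), length(x$train_idx), length(x$test_idx)))
  cat(sprintf("  mtry = %d (CV), ntree = %d\n", x$mtry, x$config$n_trees))
  cat(sprintf("  held-out R^2 = %.4f, RMSE = %.4f\n", x$r_squared, x$rmse))
  invisible(x)
}

#' @rdname fit_rf_cv
#' @param x An `rf_fit`.
#' @param ... Unused.
#' @export
glance.rf_fit <- function(x, ...) {
  tibble::tibble(mtry = x$mtry, n_trees = x$config$n_trees,
                 n_train = length(x$train_idx), n_test = length(x$test_idx),
                 r_squared = x$r_squared, rmse = x$rmse)
}

# %IncMSE: mean increase in OOB squared error under predictor permutation,
# as a percentage of the forest's OOB MSE (unscaled raw importance; the
# per-tree-sd-scaled variant is undefined for predictors no tree uses)
pct_inc_mse <- function(model) {
  raw <- randomForest::importance(model, type = 1, scale = FALSE)[, 1]
  100 * raw / tail(model$mse, 1)
}

#' Permutation significance test of random-forest importance
#'
#' Tests each predictor's permutation importance (%IncMSE: the mean
#' percentage increase in out-of-bag squared error when the predictor is
#' permuted) against the null that the response is unrelated to the
#' predictors. The response is randomly permuted `n_permutations` times;
#' for each permutation the forest is retrained (same `mtry` and tree
#' count, on the training rows) and the importance of every predictor
#' recorded. The p-value of predictor *j* is the proportion of
#' permutations whose importance reaches or exceeds the original
#' importance; with `plus_one = TRUE` the positively biased
#' `(1 + count) / (1 + B)` estimate is used instead. Stars: `***` p <
#' 0.001, `**` p < 0.01, `*` p < 0.05.
#'
#' @param fit An [fit_rf_cv()] result.
#' @param config Settings (defaults to those stored in `fit`); only
#'   `n_permutations`, `alpha`, `plus_one` and `seed` are used here.
#'
#' @return An object of class `rf_importance`: list with `importance`
#'   (tibble: `predictor`, `importance`, `p_value`, `stars`, ordered by
#'   decreasing importance), `null_importance` (B x predictors matrix),
#'   and `fit`.
#' @export
#' @examples
#' set.seed(1)
#' x <- tibble::tibble(a = rnorm(30), b = rnorm(30))
#' fit <- fit_rf_cv(x, x$a + rnorm(30, 0, 0.1),
#'                  rf_config(mtry_grid = 1:2, n_trees = 100,
#'                            n_permutations = 20, seed = 4))
#' tidy(permutation_importance_test(fit))
permutation_importance_test <- function(fit, config = fit$config) {
  if (config$n_permutations < 1) abort("n_permutations must be at least 1.")
  xt <- fit$x[fit$train_idx, , drop = FALSE]
  yt <- fit$y[fit$train_idx]
  orig <- pct_inc_mse(fit$model)
  withr::with_seed(config$seed + 1L, {
    null_imp <- t(vapply(seq_len(config$n_permutations), function(b) {
      rf <- randomForest::randomForest(xt, sample(yt), mtry = fit$mtry,
                                       ntree = config$n_trees,
                                       replace = FALSE,
                                       importance = TRUE)
      pct_inc_mse(rf)
    }, numeric(ncol(xt))))
  })
  count <- colSums(null_imp >= matrix(orig, nrow = nrow(null_imp),
                                      ncol = length(orig), byrow = TRUE))
  p <- if (config$plus_one) (1 + count) / (1 + config$n_permutations)
       else count / config$n_permutations
  a <- config$alpha
  stars <- dplyr::case_when(p < a[1] ~ "***", p < a[2] ~ "**",
                            p < a[3] ~ "*", TRUE ~ "")
  imp <- tibble::tibble(predictor = names(orig), importance = unname(orig),
                        p_value = unname(p), stars = stars) |>
    arrange(dplyr::desc(.data$importance))
  structure(list(importance = imp, null_importance = null_imp, fit = fit,
                 n_permutations = config$n_permutations),
            class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat("<rf_importance>  (", x$n_permutations, "permutations )\n")
  df <- as.data.frame(head(x$importance, 10))
  df$importance <- sprintf("%.2f", df$importance)
  df$p_value <- sprintf("%.3f", df$p_value)
  print(df, row.names = FALSE)
  if (nrow(x$importance) > 10) cat("  ...", nrow(x$importance) - 10, "more\n")
  invisible(x)
}

#' @rdname permutation_importance_test
#' @param x,object An `rf_importance`.
#' @param ... Unused.
#' @export
tidy.rf_importance <- function(x, ...) x$importance

#' @rdname permutation_importance_test
#' @export
glance.rf_importance <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble::tibble(n_permutations = x$n_permutations))
}

#' @rdname permutation_importance_test
#' @export
autoplot.rf_importance <- function(object, ...) {
  d <- object$importance |>
    mutate(predictor = stats::reorder(.data$predictor, .data$importance),
           label = ifelse(.data$stars == "", "", .data$stars))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$predictor)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$importance,
                                       yend = .data$predictor),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "darkgreen", size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.4) +
    ggplot2::labs(x = "%IncMSE", y = NULL) +
    ggplot2::theme_minimal()
}
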