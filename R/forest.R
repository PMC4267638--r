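#' Train a random-forest ensemble (rf_score model)
#'
#' Wraps `randomForest` with the standard defaults (500 trees,
#' `mtry = floor(sqrt(p))`). Random forests cannot handle missing feature
#' cells: incomplete rows are dropped at training (the count is messaged
#' and recorded) and receive a missing score at prediction.
#'
#' @param data Data frame with feature columns and a 0/1 label column.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Optional integer seed (forest growth is stochastic).
#' @param importance Compute out-of-bag permutation importance (mean
#'   decrease in accuracy); default TRUE.
#' @param label_col Name of the label column.
#' @return An object of classes `"scsnv_forest"`, `"scsnv_ensemble"`.
#' @seealso [predict_scores()], [relative_importance()]
#' @export
train_random_forest <- function(data, n_trees = 500L, mtry = NULL,
                                seed = NULL, importance = TRUE,
                                label_col = "label") {
  feats <- feature_cols(data, label_col)
  y <- data[[label_col]]
  if (is.null(y)) stop("no label column '", label_col, "'", call. = FALSE)
  X <- data[feats]
  complete <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!complete)
  if (!any(complete))
    stop("all rows have missing feature cells; random forests need complete cases",
         call. = FALSE)
  if (n_dropped > 0L)
    message(n_dropped, " incomplete row(s) dropped before random-forest training")
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("single-class training set", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  set_seed_if(seed)
  fit <- randomForest::randomForest(
    x = X, y = factor(y, levels = c(0, 1)),
    ntree = n_trees, mtry = mtry, importance = importance)
  structure(list(
    kind = "random_forest", fit = fit, features = feats,
    n_trees = as.integer(n_trees), mtry = as.integer(mtry),
    n_dropped = n_dropped, seed = seed,
    oob_error = unname(fit$err.rate[n_trees, "OOB"]),
    class_counts = c(neg = sum(y == 0), pos = sum(y == 1))
  ), class = c("scsnv_forest", "scsnv_ensemble"))
}

#' @export
print.scsnv_forest <- function(x, ...) {
  cat(sprintf("random-forest ensemble: %d trees, mtry %d, %d features, OOB error %.3f\n",
              x$n_trees, x$mtry, length(x$features), x$oob_error))
  if (x$n_dropped > 0L)
    cat(sprintf("%d incomplete training row(s) were dropped\n", x$n_dropped))
  invisible(x)
}
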