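# Adaptive boosting with small tree base learners. Two variants: "gentle"
# (weighted least-squares fit of the working response, the setting used for
# the 7-feature ada_score model) and "real" (weighted class-probability
# trees contributing half log-odds, used for the 11-feature model). Both
# run under a choice of logistic (default) or exponential loss on the
# margin y*F. The additive model F is mapped to a probability with the
# logistic link 1/(1 + exp(-2F)).

#' @noRd
feature_cols <- function(data, label_col = "label") {
  known <- intersect(scsnv_features(11), names(data))
  if (length(known)) return(known)
  setdiff(names(data)[vapply(data, is.numeric, logical(1L))],
          c(label_col, "id", "pos"))
}

#' @noRd
margin_loss <- function(loss, yy, F) {
  m <- yy * F
  if (loss == "logistic") {
    # log(1 + exp(-2m)), overflow-safe
    ifelse(m < -15, -2 * m, log1p(exp(-2 * pmax(m, -15))))
  } else {
    exp(pmin(-m, 50))
  }
}

#' Train a boosting ensemble (ada_score model)
#'
#' Fits an additive model of `n_iter` depth-limited trees by adaptive
#' boosting. `variant = "gentle"` fits each tree by weighted least squares
#' to the -1/+1 labels; `variant = "real"` fits weighted class-probability
#' trees and adds half log-odds. Weights derive from the chosen margin
#' loss (`logistic`, the default, or `exponential`). Each accepted step is
#' guaranteed not to increase the training loss (step halving; iteration
#' stops early if no improving step exists). Rows with missing feature
#' cells are usable both in training and prediction: every node stores a
#' missing-value route chosen to minimize weighted training loss.
#'
#' @param data Data frame with feature columns (see [scsnv_features()]) and
#'   a 0/1 label column.
#' @param variant `"gentle"` or `"real"`.
#' @param loss `"logistic"` or `"exponential"`.
#' @param n_iter Number of boosting iterations (default 50).
#' @param shrinkage Step-size multiplier applied to each tree (default 1).
#' @param maxdepth Base-tree depth (default 2).
#' @param seed Optional integer; recorded and set for reproducibility (the
#'   fit itself is deterministic).
#' @param label_col Name of the label column.
#' @return An object of classes `"scsnv_boost"`, `"scsnv_ensemble"`.
#' @seealso [predict_scores()], [relative_importance()]
#' @export
train_adaboost <- function(data, variant = c("gentle", "real"),
                           loss = c("logistic", "exponential"),
                           n_iter = 50L, shrinkage = 1, maxdepth = 2L,
                           seed = NULL, label_col = "label") {
  variant <- match.arg(variant)
  loss <- match.arg(loss)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  set_seed_if(seed)
  feats <- feature_cols(data, label_col)
  y <- data[[label_col]]
  if (is.null(y)) stop("no label column '", label_col, "'", call. = FALSE)
  if (anyNA(y)) stop("labels must be complete for training", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (min(table(factor(y, levels = c(0, 1)))) < 2L)
    stop("need at least 2 rows in each class", call. = FALSE)
  X <- data[feats]
  yy <- 2 * y - 1
  z01 <- y
  n <- length(yy)
  Fv <- numeric(n)
  trees <- list()
  scales <- numeric(0L)
  loss_path <- mean(margin_loss(loss, yy, Fv))
  method <- if (variant == "gentle") "anova" else "class"
  for (it in seq_len(n_iter)) {
    w <- boost_weights(loss, yy, Fv)
    if (!any(w > 0)) break
    w <- w / sum(w)
    tree <- fit_base_tree(X, yy, w, method, maxdepth)
    tree <- route_missing(tree, X, if (method == "anova") yy else z01, w)
    f <- predict_tree(tree, X)
    nu <- shrinkage
    cur <- loss_path[length(loss_path)]
    ok <- FALSE
    for (h in 1:30) {
      cand <- mean(margin_loss(loss, yy, Fv + nu * f))
      if (cand <= cur + 1e-12) { ok <- TRUE; break }
      nu <- nu / 2
    }
    if (!ok) break
    Fv <- Fv + nu * f
    trees[[length(trees) + 1L]] <- tree
    scales <- c(scales, nu)
    loss_path <- c(loss_path, cand)
  }
  structure(list(
    kind = "adaboost", variant = variant, loss = loss,
    n_iter = length(trees), n_iter_requested = as.integer(n_iter),
    shrinkage = shrinkage, maxdepth = as.integer(maxdepth),
    trees = trees, scales = scales, features = feats,
    loss_path = loss_path, seed = seed,
    n_train = n, class_counts = c(neg = sum(y == 0), pos = sum(y == 1))
  ), class = c("scsnv_boost", "scsnv_ensemble"))
}

#' @noRd
boost_weights <- function(loss, yy, F) {
  m <- yy * F
  if (loss == "logistic") 1 / (1 + exp(pmin(2 * m, 50)))
  else exp(-pmax(pmin(m, 50), -50))
}

#' @noRd
boost_margin <- function(model, data) {
  X <- data[model$features]
  if (length(model$trees) == 0L) return(numeric(nrow(X)))
  contrib <- vapply(seq_along(model$trees), function(i)
    model$scales[i] * predict_tree(model$trees[[i]], X), numeric(nrow(X)))
  if (nrow(X) == 1L) sum(contrib) else rowSums(contrib)
}

#' @export
print.scsnv_boost <- function(x, ...) {
  cat(sprintf("boosting ensemble: %s boost, %s loss, %d trees (depth <= %d), %d features\n",
              x$variant, x$loss, x$n_iter, x$maxdepth, length(x$features)))
  cat(sprintf("training loss %.4f -> %.4f\n",
              x$loss_path[1L], x$loss_path[length(x$loss_path)]))
  invisible(x)
}
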