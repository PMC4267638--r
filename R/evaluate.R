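# ROC analysis with 10-fold cross-validation: per-fold AUC, an
# accuracy-maximizing cutoff chosen on the training folds, confusion
# metrics on the held-out fold, vertically averaged ROC curves, and the
# cross-validated paired t-test for AUC differences.

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique score values (ties grouped into a
#' single step) and integrates by the trapezoid rule, which equals the
#' Mann-Whitney statistic with ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive); `NA` pairs are
#'   dropped.
#' @param labels 0/1 labels, parallel to `scores`.
#' @return Object of class `"scsnv_roc"`: data frame `curve` with columns
#'   `fpr`, `tpr` (from (0,0) to (1,1)), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group tied scores into one step
  grp <- cumsum(!duplicated(s))
  tp <- rowsum(as.numeric(y == 1), grp)
  fp <- rowsum(as.numeric(y == 0), grp)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "scsnv_roc")
}

#' @export
print.scsnv_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC %.4f (%d positives, %d negatives, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}

#' Accuracy-maximizing cutoff
#'
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' scores plus -Inf and +Inf; a score strictly above the cutoff is called
#' positive. Among accuracy-maximizing candidates, ties break by the
#' highest sensitivity + specificity, then by the smallest cutoff.
#'
#' @inheritParams roc_auc
#' @return The selected cutoff (numeric scalar) with attribute `accuracy`.
#' @export
optimum_cutoff <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  n <- length(labels); n_pos <- sum(labels == 1); n_neg <- n - n_pos
  stats <- vapply(cand, function(ct) {
    pos <- scores > ct
    tp <- sum(pos & labels == 1); tn <- sum(!pos & labels == 0)
    c(acc = (tp + tn) / n, ss = tp / n_pos + tn / n_neg)
  }, numeric(2L))
  best <- which(stats["acc", ] == max(stats["acc", ]))
  best <- best[stats["ss", best] == max(stats["ss", best])]
  ct <- cand[min(best)]
  attr(ct, "accuracy") <- max(stats["acc", ])
  ct
}

#' Confusion-matrix metrics from counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts (total > 0).
#' @return Object of class `"scsnv_confusion"`: the counts plus
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`. A ratio with a
#'   zero denominator is `NA` and its name is listed in the `undefined`
#'   field rather than propagating NaN.
#' @examples
#' confusion_from_counts(tp = 19, fn = 0, fp = 6, tn = 20)
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("total count must be > 0", call. = FALSE)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              accuracy = (tp + tn) / total,
              ppv = safe(tp, tp + fp),
              npv = safe(tn, tn + fn))
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  out$undefined <- metrics[vapply(out[metrics], is.na, logical(1L))]
  structure(out, class = "scsnv_confusion")
}

#' @export
print.scsnv_confusion <- function(x, ...) {
  cat(sprintf("tp %d fn %d fp %d tn %d | sens %.3f spec %.3f acc %.3f ppv %.3f npv %.3f\n",
              x$tp, x$fn, x$fp, x$tn, x$sensitivity, x$specificity,
              x$accuracy, x$ppv, x$npv))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' @noRd
confusion_at_cutoff <- function(scores, labels, cutoff) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- scores > cutoff
  confusion_from_counts(tp = sum(pos & labels == 1),
                        fn = sum(!pos & labels == 1),
                        fp = sum(pos & labels == 0),
                        tn = sum(!pos & labels == 0))
}

#' Model specification for cross-validation
#'
#' Describes the scoring model refit in each fold of [cross_validate()]:
#' a boosting ensemble, a random forest, or a single feature used directly
#' as the score (no fitting), as when evaluating one score variation on its
#' own.
#'
#' @param type `"adaboost"`, `"random_forest"` or `"single"`.
#' @param feature Feature name (required for `type = "single"`).
#' @param ... Extra arguments passed to the training function.
#' @return A list of class `"cv_model_spec"`.
#' @export
cv_model <- function(type = c("adaboost", "random_forest", "single"),
                     feature = NULL, ...) {
  type <- match.arg(type)
  if (type == "single" && is.null(feature))
    stop("type = 'single' needs a feature name", call. = FALSE)
  structure(list(type = type, feature = feature, args = list(...)),
            class = "cv_model_spec")
}

#' @noRd
fit_and_score <- function(spec, train, test, label_col, seed = NULL) {
  if (spec$type == "single") {
    list(train_scores = train[[spec$feature]],
         test_scores = test[[spec$feature]])
  } else if (spec$type == "adaboost") {
    fit <- do.call(train_adaboost,
                   c(list(data = train, label_col = label_col, seed = seed),
                     spec$args))
    list(train_scores = predict_scores(fit, train),
         test_scores = predict_scores(fit, test))
  } else {
    fit <- do.call(train_random_forest,
                   c(list(data = train, label_col = label_col, seed = seed),
                     spec$args))
    list(train_scores = predict_scores(fit, train),
         test_scores = predict_scores(fit, test))
  }
}

#' Stratified k-fold assignment
#'
#' @noRd
fold_assignment <- function(labels, k, stratified) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' k-fold cross-validated ROC analysis
#'
#' For each fold: the model is fit on the other k-1 folds, the
#' accuracy-maximizing cutoff is selected on those training folds, and AUC
#' plus confusion metrics at that cutoff are computed on the held-out fold.
#' Fold curves are vertically averaged on a fixed 101-point FPR grid; AUCs,
#' cutoffs and metrics are averaged arithmetically across folds.
#'
#' @param data Feature table with a 0/1 label column.
#' @param spec A [cv_model()] specification.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment (and any model
#'   stochasticity).
#' @param stratified Assign folds within each class (default TRUE), which
#'   guarantees both classes in every fold for imbalanced data.
#' @param label_col Name of the label column.
#' @return Object of class `"scsnv_cv"`: `folds` (per-fold AUC, cutoff and
#'   metrics), `mean_auc`, `mean_cutoff`, `mean_metrics`, `curve` (averaged
#'   ROC on the FPR grid), `fold_assignment`, `seed`.
#' @export
cross_validate <- function(data, spec, k = 10L, seed = NULL,
                           stratified = TRUE, label_col = "label") {
  stopifnot(inherits(spec, "cv_model_spec"))
  y <- data[[label_col]]
  if (is.null(y)) stop("no label column '", label_col, "'", call. = FALSE)
  n <- nrow(data)
  if (n < k) stop("need at least k rows", call. = FALSE)
  set_seed_if(seed)
  fold <- fold_assignment(y, k, stratified)
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < 2L)
      stop("training folds lack a class; use stratified = TRUE", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = 101L)
  tpr_grid <- matrix(NA_real_, nrow = k, ncol = length(grid))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    sc <- fit_and_score(spec, train, test, label_col, seed = seed)
    cut <- optimum_cutoff(sc$train_scores, train[[label_col]])
    cm <- confusion_at_cutoff(sc$test_scores, test[[label_col]], cut)
    y_test <- test[[label_col]][!is.na(sc$test_scores)]
    auc_f <- NA_real_
    if (length(unique(y_test)) == 2L) {
      roc <- roc_auc(sc$test_scores, test[[label_col]])
      auc_f <- roc$auc
      # vertical averaging: tpr(g) = max tpr attained at fpr <= g
      tpr_grid[f, ] <- stats::approx(roc$curve$fpr, roc$curve$tpr, xout = grid,
                                     method = "constant", f = 0, rule = 2,
                                     ties = max)$y
    }
    rows[[f]] <- data.frame(fold = f, auc = auc_f, cutoff = as.numeric(cut),
                            accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                            specificity = cm$specificity, ppv = cm$ppv,
                            npv = cm$npv)
  }
  folds <- do.call(rbind, rows)
  curve <- data.frame(fpr = grid, tpr = colMeans(tpr_grid, na.rm = TRUE))
  curve$tpr[is.nan(curve$tpr)] <- NA_real_
  curve$tpr[1L] <- 0; curve$tpr[length(grid)] <- 1
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  structure(list(
    folds = folds,
    mean_auc = mean(folds$auc, na.rm = TRUE),
    mean_cutoff = mean(folds$cutoff),
    mean_metrics = colMeans(folds[metrics], na.rm = TRUE),
    curve = curve,
    fold_assignment = fold,
    k = as.integer(k), seed = seed, spec = spec
  ), class = "scsnv_cv")
}

#' @export
print.scsnv_cv <- function(x, ...) {
  what <- if (x$spec$type == "single") paste0("single:", x$spec$feature)
          else x$spec$type
  cat(sprintf("%d-fold CV of %s: mean AUC %.3f, mean cutoff %.3f\n",
              x$k, what, x$mean_auc, x$mean_cutoff))
  print(round(x$mean_metrics, 3))
  invisible(x)
}

#' Cross-validated paired t-test on per-fold AUCs
#'
#' Tests whether two models sharing the same fold assignment differ in AUC:
#' `t = mean(d) * sqrt(k) / sd(d)` on the per-fold differences with k-1
#' degrees of freedom, two-sided.
#'
#' @param aucs_a,aucs_b Numeric vectors of per-fold AUCs (equal length k >=
#'   2, same folds underlying both).
#' @return List of class `"scsnv_cvtt"`: `t`, `df`, `p`, `differences`.
#' @export
cv_paired_ttest <- function(aucs_a, aucs_b) {
  if (length(aucs_a) != length(aucs_b))
    stop("per-fold AUC vectors must have equal length", call. = FALSE)
  k <- length(aucs_a)
  if (k < 2L) stop("need k >= 2 folds", call. = FALSE)
  d <- aucs_a - aucs_b
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0  # zero-variance limit
  } else {
    t <- mean(d) * sqrt(k) / s
    p <- 2 * stats::pt(-abs(t), df = k - 1L)
  }
  structure(list(t = t, df = k - 1L, p = p, differences = d),
            class = "scsnv_cvtt")
}

#' @export
print.scsnv_cvtt <- function(x, ...) {
  cat(sprintf("cross-validated paired t-test: t = %.3f, df = %d, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Cross-validated evaluation of a published-style scored-variant table
#'
#' Runs the full evaluation on a labeled feature table in the package TSV
#' dialect (for example a table of per-tool wild-type/mutant score
#' variations for curated variants): 10-fold CV of both ensembles and of
#' every single score variation.
#'
#' @param path TSV feature table (see [read_feature_table()]).
#' @param n_features 7 or 11.
#' @param k,seed Passed to [cross_validate()].
#' @return Named list of `"scsnv_cv"` reports: `adaboost`, `random_forest`,
#'   and one `single:<feature>` entry per feature.
#' @export
evaluate_published_table <- function(path, n_features = 7, k = 10L, seed = 1L) {
  if (!file.exists(path))
    stop("scored-variant table not found: ", path,
         " (supply the labeled TSV described in ?read_feature_table)",
         call. = FALSE)
  tab <- read_feature_table(path)
  feats <- scsnv_features(n_features)
  missing_cols <- setdiff(feats, names(tab))
  if (length(missing_cols))
    stop("table lacks feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab <- tab[c(feats, "label")]
  variant <- if (n_features == 11) "real" else "gentle"
  out <- list(
    adaboost = cross_validate(tab, cv_model("adaboost", variant = variant),
                              k = k, seed = seed),
    random_forest = cross_validate(tab, cv_model("random_forest"),
                                   k = k, seed = seed)
  )
  for (f in feats)
    out[[paste0("single:", f)]] <-
      cross_validate(tab, cv_model("single", feature = f), k = k, seed = seed)
  out
}
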