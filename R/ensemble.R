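#' Splice-altering probability scores from a trained ensemble
#'
#' Returns one probability in \[0, 1\] per row: the confidence that the
#' variant alters splicing. Boosting models score rows with missing feature
#' cells (stored missing-value routes); random-forest models return `NA`
#' for incomplete rows.
#'
#' @param model A `"scsnv_ensemble"` model.
#' @param data Data frame containing the model's feature columns.
#' @return Numeric vector of probabilities (`NA` = missing score).
#' @export
predict_scores <- function(model, data) UseMethod("predict_scores")

#' @export
predict_scores.scsnv_boost <- function(model, data) {
  missing_cols <- setdiff(model$features, names(data))
  if (length(missing_cols))
    stop("data lacks feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) return(numeric(0L))
  Fv <- boost_margin(model, data)
  1 / (1 + exp(-2 * Fv))
}

#' @export
predict_scores.scsnv_forest <- function(model, data) {
  missing_cols <- setdiff(model$features, names(data))
  if (length(missing_cols))
    stop("data lacks feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) return(numeric(0L))
  X <- data[model$features]
  out <- rep(NA_real_, nrow(X))
  complete <- stats::complete.cases(X)
  if (any(complete)) {
    Xc <- X[complete, , drop = FALSE]
    out[complete] <- if (is.null(model$fit))
      forest_votes_restored(model, Xc)  # model restored from JSON
    else
      stats::predict(model$fit, newdata = Xc, type = "prob")[, "1"]
  }
  out
}

#' Relative importance of the individual scores in an ensemble
#'
#' For boosting: the frequency with which each feature was selected for a
#' split across all boosting trees (frequencies sum to 1). For random
#' forests: the out-of-bag permutation mean decrease in accuracy.
#'
#' @param model A trained `"scsnv_ensemble"` model.
#' @return Data frame with columns `feature`, `importance`; attribute
#'   `measure` is `"boost_selection_frequency"` or
#'   `"mean_decrease_accuracy"`.
#' @export
relative_importance <- function(model) UseMethod("relative_importance")

#' @export
relative_importance.scsnv_boost <- function(model) {
  vars <- unlist(lapply(model$trees, function(tr) tr$var[!tr$is_leaf]))
  counts <- table(factor(vars, levels = model$features))
  if (sum(counts) == 0L)
    stop("model has no splits; importance undefined", call. = FALSE)
  out <- data.frame(feature = model$features,
                    importance = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- "boost_selection_frequency"
  out
}

#' @export
relative_importance.scsnv_forest <- function(model) {
  imp <- model$fit$importance
  if (is.null(imp) || !"MeanDecreaseAccuracy" %in% colnames(imp))
    stop("forest was trained with importance = FALSE", call. = FALSE)
  out <- data.frame(feature = rownames(imp),
                    importance = unname(imp[, "MeanDecreaseAccuracy"]),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- "mean_decrease_accuracy"
  out
}

#' Binary splice-altering call from the two ensemble scores
#'
#' Applies the decision rule used downstream of the ensembles: a variant is
#' called splice-altering when its score strictly exceeds the cutoff
#' (default 0.6). Rule `"either"` calls positive if at least one available
#' score exceeds the cutoff (the screening rule); rule `"both"` requires
#' both scores to exceed it (the conservative rule) and returns `"missing"`
#' when either score is absent.
#'
#' @param ada_score,rf_score Numeric vectors (recycled; `NA` = missing).
#' @param cutoff Decision cutoff (default 0.6; strict `>`).
#' @param rule `"either"` or `"both"`.
#' @return Character vector: `"positive"`, `"negative"` or `"missing"`.
#' @examples
#' call_splice_altering(0.7, 0.5, rule = "both")    # "negative"
#' call_splice_altering(0.7, 0.5, rule = "either")  # "positive"
#' call_splice_altering(0.6, 0.6, rule = "either")  # "negative": strict >
#' @export
call_splice_altering <- function(ada_score, rf_score, cutoff = 0.6,
                                 rule = c("either", "both")) {
  rule <- match.arg(rule)
  n <- max(length(ada_score), length(rf_score))
  ada <- rep_len(as.numeric(ada_score), n)
  rf <- rep_len(as.numeric(rf_score), n)
  out <- character(n)
  if (rule == "either") {
    pos <- (!is.na(ada) & ada > cutoff) | (!is.na(rf) & rf > cutoff)
    miss <- is.na(ada) & is.na(rf)
    out[pos] <- "positive"
    out[!pos & !miss] <- "negative"
    out[miss] <- "missing"
  } else {
    miss <- is.na(ada) | is.na(rf)
    pos <- !miss & ada > cutoff & rf > cutoff
    out[pos] <- "positive"
    out[!pos & !miss] <- "negative"
    out[miss] <- "missing"
  }
  out
}
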