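# Score variations: transform a wild-type/mutant score pair from one
# splice-site scoring tool into the change measures fed to the classifiers.

#' Canonical feature names
#'
#' The fixed, documented feature order used everywhere in the package: the
#' seven score variations (PWM relative/absolute, MaxEnt-style log-odds
#' relative only, NNSplice relative/absolute, HSF relative/absolute), plus
#' the four optional annotation scores (two phyloP conservation scores and
#' two CADD scores) for the 11-feature models. Serialized models and TSV
#' feature tables rely on this order being frozen.
#'
#' @param n_features 7 or 11.
#' @return Character vector of feature (column) names.
#' @export
scsnv_features <- function(n_features = 7) {
  base7 <- c("pwm_rel", "pwm_abs", "mes_rel",
             "nnsplice_rel", "nnsplice_abs", "hsf_rel", "hsf_abs")
  extra4 <- c("phylop_placental", "phylop_primate", "cadd_raw", "cadd_phred")
  if (n_features == 7) return(base7)
  if (n_features == 11) return(c(base7, extra4))
  stop("n_features must be 7 or 11", call. = FALSE)
}

#' Relative and absolute score variation for one tool
#'
#' The signed score difference is `d = wt_score - mut_score`, so loss of
#' splice-site signal is positive (the dominant mechanism for variants in
#' consensus regions; gains come out negative and are left to the
#' classifier). The relative variation is `d / wt_score`; it is missing
#' (`NA`) when the wild-type score is zero, because a tool that scores the
#' true site zero has failed to detect it. The absolute variation is
#' `d / (hi - lo)` for tools with a finite declared score range and is
#' undefined (`NULL` range -> `NA` with attribute) otherwise, as for an
#' unbounded log-odds score.
#'
#' @param wt_score,mut_score Finite numeric scores for the wild-type and
#'   mutant allele.
#' @param score_range Length-2 numeric `c(lo, hi)` with `lo < hi`, or `NULL`
#'   if the tool's score has no finite range.
#' @param tool_id Optional label carried through.
#' @return A list of class `"score_variation"` with `tool_id`, `relative`
#'   (numeric or `NA` = missing), `absolute` (numeric, `NA` = missing, or
#'   `NA` with `undefined = TRUE` when no range exists), and logical flags
#'   `missing` and `absolute_undefined`.
#' @examples
#' score_variation(80, 60, c(0, 100))  # relative 0.25, absolute 0.20
#' score_variation(0, 5)$missing       # TRUE: wild-type site not detected
#' @export
score_variation <- function(wt_score, mut_score, score_range = NULL,
                            tool_id = NA_character_) {
  stopifnot(is.finite(wt_score), is.finite(mut_score))
  if (!is.null(score_range)) {
    if (length(score_range) != 2L || !all(is.finite(score_range)) ||
        score_range[1] >= score_range[2])
      stop("score_range must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  d <- wt_score - mut_score
  missing <- wt_score == 0
  relative <- if (missing) NA_real_ else d / wt_score
  undefined <- is.null(score_range)
  absolute <- if (undefined || missing) NA_real_ else
    d / (score_range[2] - score_range[1])
  structure(list(tool_id = tool_id, relative = relative, absolute = absolute,
                 missing = missing, absolute_undefined = undefined),
            class = "score_variation")
}

#' Screen scoring tools by missing-score rate
#'
#' A score is missing when the tool's wild-type score for a variant is zero
#' (the tool failed to identify the true splice site). Tools whose missing
#' rate exceeds the threshold (default 5%) are excluded from evaluation.
#'
#' @param wt_scores Named list: one numeric vector of wild-type scores per
#'   tool.
#' @param threshold Maximum tolerated missing rate (default 0.05).
#' @return A data frame with one row per tool: `tool_id`, `n_missing`,
#'   `n_total`, `missing_rate`, `retained`.
#' @examples
#' screen_tools(list(pwm = c(1, 0, 3), genscan = c(0, 0, 1)), threshold = 0.4)
#' @export
screen_tools <- function(wt_scores, threshold = 0.05) {
  if (length(wt_scores) == 0L) stop("no tools supplied", call. = FALSE)
  if (is.null(names(wt_scores)) || any(!nzchar(names(wt_scores))))
    stop("wt_scores must be a named list (one entry per tool)", call. = FALSE)
  rows <- lapply(names(wt_scores), function(id) {
    s <- wt_scores[[id]]
    if (length(s) == 0L) stop("tool '", id, "' has no scores", call. = FALSE)
    n_missing <- sum(s == 0)
    data.frame(tool_id = id, n_missing = n_missing, n_total = length(s),
               missing_rate = n_missing / length(s),
               retained = n_missing / length(s) <= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Missing-rate report from precomputed counts
#'
#' Same screening rule as [screen_tools()] when only the per-tool counts of
#' missing and total scores are known.
#'
#' @param n_missing,n_total Integer vectors (parallel, optionally named by
#'   tool).
#' @param threshold Maximum tolerated missing rate (default 0.05).
#' @return Data frame as in [screen_tools()].
#' @export
screen_tools_from_counts <- function(n_missing, n_total, threshold = 0.05) {
  stopifnot(length(n_missing) == length(n_total), all(n_total > 0),
            all(n_missing >= 0), all(n_missing <= n_total))
  ids <- names(n_missing) %||% paste0("tool", seq_along(n_missing))
  data.frame(tool_id = ids, n_missing = as.integer(n_missing),
             n_total = as.integer(n_total),
             missing_rate = n_missing / n_total,
             retained = n_missing / n_total <= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a labeled feature row from score variations
#'
#' Maps per-tool [score_variation()] results onto the frozen feature order
#' (see [scsnv_features()]): PWM relative+absolute, MES relative only (no
#' finite range), NNSplice relative+absolute, HSF relative+absolute, plus
#' optionally the four annotation scores. Missing variations stay `NA`
#' cells; rows are never dropped here.
#'
#' @param variations List of `"score_variation"` objects whose `tool_id`s
#'   must be exactly `pwm`, `mes`, `nnsplice`, `hsf` (any order, no
#'   duplicates).
#' @param extra_scores Optional named numeric of length 4
#'   (`phylop_placental`, `phylop_primate`, `cadd_raw`, `cadd_phred`) or
#'   unnamed in that order.
#' @param label Optional 0/1 class label (1 = splice-altering).
#' @param id Optional row identifier.
#' @return One-row data frame: `id`, the 7 or 11 feature columns, `label`.
#' @export
build_feature_row <- function(variations, extra_scores = NULL, label = NA,
                              id = NA_character_) {
  ids <- vapply(variations, function(v) v$tool_id, character(1L))
  expected <- c("pwm", "mes", "nnsplice", "hsf")
  if (anyDuplicated(ids))
    stop("duplicate tool id: ", ids[duplicated(ids)][1L], call. = FALSE)
  unknown <- setdiff(ids, expected)
  if (length(unknown))
    stop("unknown tool id: ", unknown[1L], call. = FALSE)
  if (!setequal(ids, expected))
    stop("need exactly the retained tools: ", paste(expected, collapse = ", "),
         call. = FALSE)
  v <- setNames(variations, ids)
  row <- data.frame(
    id = id,
    pwm_rel = v$pwm$relative, pwm_abs = v$pwm$absolute,
    mes_rel = v$mes$relative,
    nnsplice_rel = v$nnsplice$relative, nnsplice_abs = v$nnsplice$absolute,
    hsf_rel = v$hsf$relative, hsf_abs = v$hsf$absolute,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_scores)) {
    if (length(extra_scores) != 4L)
      stop("extra_scores must have length 4", call. = FALSE)
    extras <- scsnv_features(11)[8:11]
    if (!is.null(names(extra_scores))) {
      if (!setequal(names(extra_scores), extras))
        stop("extra_scores names must be: ", paste(extras, collapse = ", "),
             call. = FALSE)
      extra_scores <- extra_scores[extras]
    }
    row[extras] <- as.numeric(extra_scores)
  }
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0, 1 or NA", call. = FALSE)
  row$label <- as.integer(label)
  row
}

#' Read / write the TSV feature-table dialect
#'
#' Tab-delimited with a header; `.` encodes missing cells; columns `id`
#' (plus optionally `chrom`, `pos`, `ref`, `alt`), the 7 or 11 feature
#' columns in the frozen order, and `label`.
#'
#' @param path File path.
#' @param x Feature-table data frame.
#' @return `read_feature_table()` returns the data frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = ".", stringsAsFactors = FALSE,
                           check.names = FALSE)
  feats <- intersect(scsnv_features(11), names(tab))
  if (!all(scsnv_features(7) %in% feats))
    stop("feature table lacks the seven score-variation columns",
         call. = FALSE)
  for (f in feats) tab[[f]] <- as.numeric(tab[[f]])
  if ("label" %in% names(tab)) tab$label <- as.integer(tab$label)
  tab
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  out <- x
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
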