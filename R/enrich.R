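# Contingency-table statistics for the downstream enrichment analyses:
# does the proportion of predicted splice-altering variants rise with
# recurrence (trend in proportions), and does it differ between cancer and
# non-cancer genes (Pearson chi-squared)?

#' Chi-squared test for trend in proportions
#'
#' Cochran-Armitage-style trend test across k ordered groups (no continuity
#' correction), df = 1. The p-value is invariant under affine
#' transformations of the group scores. Delegates to
#' [stats::prop.trend.test()].
#'
#' @param n_total Per-group totals.
#' @param n_event Per-group event counts (`0 <= n_event <= n_total`).
#' @param scores Group scores (default `1..k`).
#' @return List of class `"scsnv_trend"`: `chi2`, `df` (1), `p`,
#'   `proportions`, plus the inputs. Degenerate tables (all events 0 or all
#'   events equal to totals) give `chi2 = 0`, `p = 1` with a warning.
#' @examples
#' chisq_trend(c(41455, 299, 129), c(29322, 222, 109))
#' @export
chisq_trend <- function(n_total, n_event, scores = seq_along(n_total)) {
  stopifnot(length(n_total) == length(n_event),
            length(scores) == length(n_total))
  if (length(n_total) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(n_event < 0) || any(n_event > n_total))
    stop("need 0 <= n_event <= n_total in every group", call. = FALSE)
  if (sum(n_total > 0) < 2L)
    stop("need at least two groups with n_total > 0", call. = FALSE)
  if (sum(n_event) == 0 || all(n_event == n_total)) {
    warning("degenerate table: all-zero or all-complete events; chi2 = 0, p = 1")
    chi2 <- 0; p <- 1
  } else {
    ht <- suppressWarnings(stats::prop.trend.test(n_event, n_total,
                                                  score = scores))
    chi2 <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(chi2 = chi2, df = 1L, p = p,
                 proportions = n_event / n_total,
                 n_total = n_total, n_event = n_event, scores = scores),
            class = "scsnv_trend")
}

#' @export
print.scsnv_trend <- function(x, ...) {
  cat(sprintf("trend in proportions: chi2 = %.4f, df = 1, p = %s\n",
              x$chi2, format_pvalue(x$p)))
  cat("proportions:", paste(sprintf("%.3f", x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' Pearson's chi-squared test on a 2x2 table
#'
#' Uncorrected by default (`yates = TRUE` applies the continuity
#' correction). Delegates to [stats::chisq.test()].
#'
#' @param a,b,c,d Counts: rows are event/non-event, columns group1/group2
#'   (`a` = events in group 1, `b` = events in group 2, `c`, `d` the
#'   complements).
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return List of class `"scsnv_chisq"`: `chi2`, `df` (1), `p`,
#'   `p_display` (the display convention `"< 2.2e-16"` below representable
#'   precision, alongside the raw float), `table`.
#' @examples
#' pearson_chisq(2025, 541, 27628, 11689)
#' @export
pearson_chisq <- function(a, b, c, d, yates = FALSE) {
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(tab) == 0) stop("total must be > 0", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero row or column marginal makes the test undefined",
         call. = FALSE)
  ht <- stats::chisq.test(tab, correct = yates)
  structure(list(chi2 = unname(ht$statistic), df = 1L, p = ht$p.value,
                 p_display = format_pvalue(ht$p.value),
                 yates = yates, table = tab),
            class = "scsnv_chisq")
}

#' @export
print.scsnv_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (%s): chi2 = %.4f, df = 1, p = %s\n",
              if (x$yates) "Yates-corrected" else "uncorrected",
              x$chi2, x$p_display))
  invisible(x)
}

# display convention: p-values below representable precision are shown as
# "< 2.2e-16"; the raw float is kept in the result
#' @noRd
format_pvalue <- function(p) {
  if (p < .Machine$double.eps) "< 2.2e-16" else format(p, digits = 4)
}

#' Bin variant calls by recurrence into a trend table
#'
#' Groups variants by how many times each was observed (default bins: once
#' or twice, three or four times, five or more) and counts predicted
#' splice-altering positives per bin. Empty bins are omitted.
#'
#' @param recurrence Integer vector (>= 1): times each variant was
#'   observed.
#' @param is_positive Logical/0-1 vector: predicted splice-altering.
#' @param bins List of `c(lo, hi)` ranges (inclusive; `Inf` allowed).
#' @return Data frame: `group`, `n_total`, `n_event`, `proportion`.
#' @export
recurrence_table <- function(recurrence, is_positive,
                             bins = list(c(1, 2), c(3, 4), c(5, Inf))) {
  if (length(recurrence) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(recurrence) == length(is_positive))
  if (any(recurrence < 1)) stop("recurrence must be >= 1", call. = FALSE)
  is_positive <- as.logical(is_positive)
  rows <- lapply(bins, function(b) {
    sel <- recurrence >= b[1] & recurrence <= b[2]
    if (!any(sel)) return(NULL)
    data.frame(group = if (is.finite(b[2])) paste0(b[1], "-", b[2])
                       else paste0(b[1], "+"),
               n_total = sum(sel), n_event = sum(is_positive[sel]),
               proportion = sum(is_positive[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no variant falls in any bin", call. = FALSE)
  out
}
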