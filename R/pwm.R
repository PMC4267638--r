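#' Train a position weight matrix splice-site model
#'
#' Estimates per-position base frequencies from aligned example site
#' sequences, with an additive pseudocount, and records the min/max
#' log-frequency sums used to normalize scores to the 0-100 scale.
#'
#' @param site_sequences Character vector of equal-length DNA strings
#'   (alphabet ACGT; lowercase is uppercased, ambiguity codes are rejected).
#' @param region Optional [region_definition()]; when supplied, sequence
#'   length must equal the region length.
#' @param pseudocount Added to every cell of the count table (default 0.5,
#'   so no frequency is ever zero with a non-empty training set).
#' @return An object of class `"pwm_model"`: `site_kind`, `length`, `freq`
#'   (L x 4 matrix, rows summing to 1), `pseudocount`, `min_logsum`,
#'   `max_logsum`.
#' @seealso [score_pwm()]
#' @export
train_pwm <- function(site_sequences, region = NULL, pseudocount = 0.5) {
  if (length(site_sequences) == 0L)
    stop("empty training set", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  m <- seq_matrix(site_sequences)
  L <- ncol(m)
  if (!is.null(region)) {
    stopifnot(inherits(region, "splice_region"))
    if (L != region$length)
      stop(sprintf("sequences have length %d but the %s region has %d positions",
                   L, region$site_kind, region$length), call. = FALSE)
  }
  n <- nrow(m)
  counts <- vapply(seq_len(L), function(p) tabulate(m[, p], nbins = 4L),
                   numeric(4L))
  freq <- t(counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(freq) <- list(NULL, DNA_BASES)
  lf <- log(pmax(freq, .Machine$double.xmin))
  structure(list(
    site_kind = if (is.null(region)) NA_character_ else region$site_kind,
    length = L,
    freq = freq,
    pseudocount = pseudocount,
    min_logsum = sum(apply(lf, 1L, min)),
    max_logsum = sum(apply(lf, 1L, max))
  ), class = "pwm_model")
}

#' Score a sequence with a position weight matrix model
#'
#' The raw score is the sum over positions of log base frequencies; it is
#' min-max normalized to 0-100 (the consensus sequence scores 100, the
#' anti-consensus 0) and clamped to that range.
#'
#' @param model A [train_pwm()] model.
#' @param seq DNA string(s) of the model length.
#' @return Numeric vector of scores in \[0, 100\].
#' @export
score_pwm <- function(model, seq) {
  stopifnot(inherits(model, "pwm_model"))
  m <- seq_matrix(seq)
  if (ncol(m) != model$length)
    stop(sprintf("sequence length %d does not match model length %d",
                 ncol(m), model$length), call. = FALSE)
  lf <- log(pmax(model$freq, .Machine$double.xmin))
  logsum <- vapply(seq_len(nrow(m)), function(i)
    sum(lf[cbind(seq_len(model$length), m[i, ])]), numeric(1L))
  denom <- model$max_logsum - model$min_logsum
  if (denom <= 0) return(rep(100, nrow(m)))  # degenerate: all positions fixed
  pmin(pmax(100 * (logsum - model$min_logsum) / denom, 0), 100)
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("PWM splice-site model (%s), %d positions, pseudocount %g\n",
              x$site_kind, x$length, x$pseudocount))
  invisible(x)
}
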