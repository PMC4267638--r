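# Maximum-entropy splice-site model with low-order marginal constraints.
#
# The constraint set is all position singletons plus, for constraint_order
# >= 2, all adjacent pairs (and for order 3, adjacent triples). Adjacent
# subsets form a decomposable (chain-structured) graph, so the entropy
# maximizer subject to those marginals has an exact closed form: a
# (constraint_order - 1)-order Markov chain whose gram tables are the
# empirical marginals. Pseudocounts are applied to the highest-order gram
# tables only, which keeps all implied lower-order marginals mutually
# consistent. For small L the fit is verified against every constraint
# marginal by full enumeration.

#' Train a maximum-entropy splice-site model
#'
#' Fits the maximum-entropy distribution over sequences of length L subject
#' to empirical marginal constraints on all single positions
#' (`constraint_order = 1`), plus adjacent position pairs (order 2) or
#' adjacent triples (order 3). Order 1 yields the independence model;
#' higher orders yield Markov-chain factorizations, which are the exact
#' solutions of the constrained entropy maximization for adjacent
#' (chain-decomposable) constraint sets.
#'
#' @param site_sequences Character vector of equal-length DNA strings.
#' @param region Optional [region_definition()] (length check + site kind).
#' @param constraint_order 1, 2 or 3.
#' @param pseudocount Added to each cell of the highest-order gram count
#'   tables (default 0.5).
#' @param background `"uniform"` (each sequence has probability 4^-L) or
#'   `"positional"` (product of the empirical per-position frequencies).
#' @param tol Maximum allowed absolute deviation between fitted and
#'   empirical constraint marginals; verified by full enumeration when
#'   `4^L` is small enough (`L <= 8`), guaranteed analytically otherwise.
#' @return An object of class `"maxent_model"`.
#' @seealso [score_maxent()], [maxent_distribution()]
#' @export
train_maxent <- function(site_sequences, region = NULL, constraint_order = 2,
                         pseudocount = 0.5, background = c("uniform", "positional"),
                         tol = 1e-6) {
  background <- match.arg(background)
  if (length(site_sequences) == 0L)
    stop("empty training set", call. = FALSE)
  if (!constraint_order %in% 1:3)
    stop("constraint_order must be 1, 2 or 3", call. = FALSE)
  m <- seq_matrix(site_sequences)
  L <- ncol(m)
  if (!is.null(region)) {
    stopifnot(inherits(region, "splice_region"))
    if (L != region$length)
      stop(sprintf("sequences have length %d but the %s region has %d positions",
                   L, region$site_kind, region$length), call. = FALSE)
  }
  k <- min(constraint_order, L)
  n <- nrow(m)

  # smoothed k-gram tables at start positions 1 .. L-k+1
  # (array dim j = position s+j-1; cells coded column-major)
  grams <- lapply(seq_len(L - k + 1L), function(s) {
    idx <- m[, s:(s + k - 1L), drop = FALSE]
    tab <- array(tabulate(array_cell(idx), nbins = 4L^k) + pseudocount,
                 dim = rep(4L, k))
    tab / (n + 4L^k * pseudocount)
  })

  # per-position background frequencies (used for background = "positional")
  pos_freq <- t(vapply(seq_len(L), function(p)
    (tabulate(m[, p], nbins = 4L) + pseudocount) / (n + 4 * pseudocount),
    numeric(4L)))

  model <- structure(list(
    site_kind = if (is.null(region)) NA_character_ else region$site_kind,
    length = L,
    constraint_order = as.integer(constraint_order),
    k = as.integer(k),
    grams = grams,
    pseudocount = pseudocount,
    background = background,
    pos_freq = pos_freq,
    n_train = n,
    tol = tol
  ), class = "maxent_model")

  if (L <= 8L) {
    res <- maxent_marginal_residual(model, m)
    if (res > tol)
      stop(sprintf("maximum-entropy fit failed: worst constraint marginal residual %.3g exceeds tol %.3g",
                   res, tol), call. = FALSE)
  }
  model
}

# column-major linear index into an array of dim rep(4, ncol(idx))
#' @noRd
array_cell <- function(idx) {
  as.vector((idx - 1L) %*% 4L^(0:(ncol(idx) - 1L))) + 1L
}

# log probability of integer-coded rows under the chain factorization
#' @noRd
maxent_logprob <- function(model, m) {
  k <- model$k
  L <- model$length
  grams <- model$grams
  if (k == 1L) {
    lp <- numeric(nrow(m))
    for (s in seq_len(L)) lp <- lp + as.vector(log(grams[[s]]))[m[, s]]
    return(lp)
  }
  lp <- log(grams[[1L]])[array_cell(m[, 1:k, drop = FALSE])]
  if (L > k) {
    for (s in 2L:(L - k + 1L)) {
      num <- grams[[s]]
      # marginal of gram s over its last position = conditioning table
      den <- apply(num, seq_len(k - 1L), sum)
      lp <- lp + log(num)[array_cell(m[, s:(s + k - 1L), drop = FALSE])] -
        log(den)[array_cell(m[, s:(s + k - 2L), drop = FALSE])]
    }
  }
  as.vector(lp)
}

#' @noRd
maxent_logprob_bg <- function(model, m) {
  if (model$background == "uniform") {
    rep(-model$length * log(4), nrow(m))
  } else {
    lf <- log(model$pos_freq)
    vapply(seq_len(nrow(m)), function(i)
      sum(lf[cbind(seq_len(model$length), m[i, ])]), numeric(1L))
  }
}

#' Score a sequence with a maximum-entropy model
#'
#' Returns the log2 odds ratio `log2(P_model(seq) / P_background(seq))`,
#' unbounded in both directions (positive: more splice-site-like than
#' background).
#'
#' @param model A [train_maxent()] model.
#' @param seq DNA string(s) of the model length.
#' @return Numeric vector of log-odds scores.
#' @export
score_maxent <- function(model, seq) {
  stopifnot(inherits(model, "maxent_model"))
  m <- seq_matrix(seq)
  if (ncol(m) != model$length)
    stop(sprintf("sequence length %d does not match model length %d",
                 ncol(m), model$length), call. = FALSE)
  (maxent_logprob(model, m) - maxent_logprob_bg(model, m)) / log(2)
}

#' Full fitted distribution of a maximum-entropy model
#'
#' Enumerates all `4^L` sequences and their fitted probabilities (only
#' feasible for small L; used for verification and analysis).
#'
#' @param model A [train_maxent()] model with `length <= 10`.
#' @return Numeric vector of length `4^L` (lexicographic order A<C<G<T with
#'   position 1 most significant), summing to 1.
#' @export
maxent_distribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  if (model$length > 10L)
    stop("refusing to enumerate 4^", model$length, " sequences", call. = FALSE)
  km <- enumerate_kmers(model$length)
  exp(maxent_logprob(model, km))
}

# worst |fitted - empirical| over all constraint-set marginals; the
# empirical values are the pseudocount-smoothed marginals implied by the
# highest-order gram tables
#' @noRd
maxent_marginal_residual <- function(model, m) {
  p <- maxent_distribution(model)
  km <- enumerate_kmers(model$length)
  k <- model$k
  worst <- 0
  for (ord in seq_len(k)) {
    for (s in seq_len(model$length - ord + 1L)) {
      cell <- array_cell(km[, s:(s + ord - 1L), drop = FALSE])
      fitted <- as.vector(rowsum(p, cell))     # ordered by column-major cell
      gi <- min(s, length(model$grams))        # a gram covering s..s+ord-1
      off <- s - gi                            # offset within that gram
      tab <- model$grams[[gi]]
      keep <- (off + 1L):(off + ord)
      marg <- apply(tab, keep, sum)            # dims in position order
      worst <- max(worst, max(abs(fitted - as.vector(marg))))
    }
  }
  worst
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maximum-entropy splice-site model (%s), %d positions, constraint order %d, background %s\n",
              x$site_kind, x$length, x$constraint_order, x$background))
  invisible(x)
}
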