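# Independent oracles used across tests. These deliberately re-derive the
# quantities by different algorithms than the package (brute force,
# exhaustive enumeration, iterative proportional fitting) so agreement is
# informative.

# AUC as the Mann-Whitney statistic by exhaustive pair counting, ties = 1/2
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# constrained entropy maximization over the enumerated 4^L simplex by
# iterative proportional fitting on adjacent pair marginals (constraints
# identical to the package's: smoothed pair tables, singletons implied)
ipf_maxent_order2 <- function(seqs, pseudocount = 0.5, sweeps = 500) {
  m <- matrix(match(unlist(strsplit(toupper(seqs), "")), c("A", "C", "G", "T")),
              ncol = nchar(seqs[1]), byrow = TRUE)
  L <- ncol(m); n <- nrow(m)
  km <- as.matrix(expand.grid(rep(list(1:4), L)))[, L:1, drop = FALSE]
  p <- rep(1 / 4^L, 4^L)
  targets <- lapply(1:(L - 1), function(s) {
    cell <- (m[, s] - 1) + 4 * (m[, s + 1] - 1) + 1
    (tabulate(cell, 16) + pseudocount) / (n + 16 * pseudocount)
  })
  for (it in seq_len(sweeps)) {
    for (s in 1:(L - 1)) {
      cell <- (km[, s] - 1) + 4 * (km[, s + 1] - 1) + 1
      cur <- as.vector(rowsum(p, cell))
      p <- p * (targets[[s]] / cur)[cell]
    }
  }
  list(p = p, kmers = km)
}

# all 4^L sequences as strings, in the package's enumeration order
all_sequences <- function(L) {
  km <- as.matrix(expand.grid(rep(list(1:4), L)))[, L:1, drop = FALSE]
  apply(km, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = ""))
}

# small linearly separable feature table with canonical feature names
separable_table <- function(n = 100, seed = 1) {
  set.seed(seed)
  x <- c(runif(n / 2, 0.2, 1), runif(n / 2, -1, -0.2))
  data.frame(pwm_rel = x,
             pwm_abs = rnorm(n, 0, 0.1),
             mes_rel = rnorm(n, 0, 0.1),
             label = as.integer(x > 0))
}
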