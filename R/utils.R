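DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
check_dna <- function(seqs, what = "sequence") {
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-ACGT symbol '%s' in %s %d at position %d",
                 substr(seqs[i], bad[i], bad[i]), what, i, bad[i]),
         call. = FALSE)
  }
  seqs
}

# sequences -> integer matrix (n x L), values 1..4 indexing A,C,G,T
#' @noRd
seq_matrix <- function(seqs) {
  seqs <- check_dna(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences have unequal lengths: ", paste(sort(L), collapse = ", "),
         call. = FALSE)
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES),
              ncol = L, byrow = TRUE)
  m
}

#' @noRd
int_to_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

# all 4^L sequences as an integer matrix (rows in lexicographic order,
# position 1 most significant)
#' @noRd
enumerate_kmers <- function(L) {
  m <- as.matrix(expand.grid(rep(list(1:4), L)))[, L:1, drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
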