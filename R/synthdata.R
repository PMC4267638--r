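# Seeded generators for every input the pipeline consumes: calibrated
# labeled feature tables (standing in for a curated scored-variant table),
# splice-site sequence sets, toy genomes with planted gene models, and
# recurrence/call tables. All generators are pure functions of
# (spec, seed).

#' Specification for a synthetic labeled feature table
#'
#' Class-conditional Gaussian features sharing a within-class latent factor
#' (the score variations of one variant are correlated by construction:
#' they measure the same underlying event). Each feature's positive-class
#' mean shift is solved in closed form from its target single-feature AUC:
#' for equal-variance Gaussians, `AUC = pnorm(delta / (sd * sqrt(2)))`, so
#' `delta = qnorm(AUC) * sd * sqrt(2)`. Per-tool missing masks emulate
#' wild-type scores of zero (both variations of the affected tool go
#' missing on the same rows).
#'
#' Defaults emulate the curated study conditions: 1164 positives vs 1795
#' negatives (2959 rows), single-feature AUC targets 0.95, 0.95, 0.94,
#' 0.90, 0.91, 0.93, 0.93 for the seven score variations and 0.80 for the
#' four annotation scores, and per-tool missing rates of 2.6% (PWM), 2.8%
#' (MES), 2.3% (NNSplice) and 2.2% (HSF).
#'
#' @param n_pos,n_neg Class sizes.
#' @param n_features 7 or 11.
#' @param target_auc Per-feature target AUCs, in `(0.5, 1)`.
#' @param sd Within-class standard deviation (all features).
#' @param rho Within-class correlation from the shared latent factor, in
#'   `[0, 1)`.
#' @param missing_rate Named per-tool missing rates
#'   (`pwm`, `mes`, `nnsplice`, `hsf`), each in `[0, 1)`.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_pos = 1164L, n_neg = 1795L, n_features = 7,
                           target_auc = NULL, sd = 1, rho = 0.5,
                           missing_rate = c(pwm = 0.026, mes = 0.028,
                                            nnsplice = 0.023, hsf = 0.022)) {
  feats <- scsnv_features(n_features)
  if (is.null(target_auc)) {
    target_auc <- c(0.95, 0.95, 0.94, 0.90, 0.91, 0.93, 0.93,
                    0.80, 0.80, 0.80, 0.80)[seq_along(feats)]
  }
  if (length(target_auc) != length(feats))
    stop("target_auc must have one value per feature", call. = FALSE)
  if (any(target_auc <= 0.5) || any(target_auc >= 1))
    stop("target AUCs must lie in (0.5, 1)", call. = FALSE)
  if (n_pos < 1L || n_neg < 1L) stop("class sizes must be positive", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (any(missing_rate < 0) || any(missing_rate >= 1))
    stop("missing rates must be in [0, 1)", call. = FALSE)
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    features = feats, target_auc = target_auc, sd = sd, rho = rho,
    delta = stats::qnorm(target_auc) * sd * sqrt(2),
    missing_rate = missing_rate
  ), class = "synthetic_spec")
}

#' Generate a calibrated labeled feature table
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (required: generation is a pure function of
#'   spec and seed).
#' @return Data frame: `id`, feature columns, `label`; attribute
#'   `manifest` records realized class sizes, per-feature empirical AUCs
#'   and missing rates.
#' @export
gen_feature_table <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_pos + spec$n_neg
  label <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  latent <- stats::rnorm(n)
  p <- length(spec$features)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, spec$features))
  for (j in seq_len(p)) {
    noise <- stats::rnorm(n)
    X[, j] <- spec$sd * (sqrt(spec$rho) * latent + sqrt(1 - spec$rho) * noise) +
      spec$delta[j] * label
  }
  tool_of <- c(pwm_rel = "pwm", pwm_abs = "pwm", mes_rel = "mes",
               nnsplice_rel = "nnsplice", nnsplice_abs = "nnsplice",
               hsf_rel = "hsf", hsf_abs = "hsf")
  for (tool in names(spec$missing_rate)) {
    rate <- spec$missing_rate[[tool]]
    if (rate <= 0) next
    cols <- names(tool_of)[tool_of == tool]
    cols <- intersect(cols, spec$features)
    if (!length(cols)) next
    mask <- stats::runif(n) < rate
    X[mask, cols] <- NA_real_
  }
  tab <- data.frame(id = sprintf("v%04d", seq_len(n)), X, label = label,
                    stringsAsFactors = FALSE)
  # shuffle row order so folds are not trivially class-blocked
  tab <- tab[sample.int(n), , drop = FALSE]
  rownames(tab) <- NULL
  emp_auc <- vapply(spec$features, function(f)
    roc_auc(tab[[f]], tab$label)$auc, numeric(1L))
  attr(tab, "manifest") <- list(
    seed = as.integer(seed), n_pos = spec$n_pos, n_neg = spec$n_neg,
    target_auc = stats::setNames(spec$target_auc, spec$features),
    empirical_auc = emp_auc,
    missing_rate = vapply(spec$features, function(f) mean(is.na(tab[[f]])),
                          numeric(1L)))
  tab
}

DONOR_CONSENSUS <- "CAGGTAAGTAT"     # -3..-1 exon | GT AAGTAT intron
ACCEPTOR_CONSENSUS <- "TTTTTTTTTCAGGT" # 12 intronic ending AG | GT exon

#' Generate splice-site sequences from a consensus mixture
#'
#' The invariant dinucleotide (donor GT, acceptor AG) is always planted;
#' every other position draws the consensus base with probability
#' `strength + (1 - strength)/4` and each other base uniformly otherwise,
#' so `strength = 1` reproduces the consensus exactly and `strength -> 0`
#' approaches uniform background.
#'
#' @param site_kind `"donor"` or `"acceptor"`.
#' @param strength Consensus weight in `(0, 1]`.
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed.
#' @return Character vector of sequences (length 11 or 14).
#' @export
gen_splice_sites <- function(site_kind = c("donor", "acceptor"), strength,
                             n, seed) {
  site_kind <- match.arg(site_kind)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (strength <= 0 || strength > 1)
    stop("strength must be in (0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  region <- region_definition(site_kind)
  consensus <- if (site_kind == "donor") DONOR_CONSENSUS else ACCEPTOR_CONSENSUS
  cons <- strsplit(consensus, "")[[1L]]
  stopifnot(length(cons) == region$length)
  fixed <- region$offsets %in% region$invariant
  out <- matrix("", n, region$length)
  for (p in seq_len(region$length)) {
    if (fixed[p]) {
      out[, p] <- cons[p]
    } else {
      probs <- rep((1 - strength) / 4, 4L)
      probs[match(cons[p], DNA_BASES)] <- strength + (1 - strength) / 4
      out[, p] <- sample(DNA_BASES, n, replace = TRUE, prob = probs)
    }
  }
  apply(out, 1L, paste, collapse = "")
}

#' Generate a toy genome with planted genes
#'
#' Builds a random chromosome with `n_genes` multi-exon genes laid out on
#' alternating strands, plants the invariant GT/AG dinucleotides (in
#' transcription orientation) at every intron end, and returns both the
#' parsed objects and FASTA/GTF text in the dialects the pipeline reads.
#'
#' @param n_genes Number of genes (alternate + / - strand).
#' @param exons_per_gene Exons per gene (>= 2 to own introns).
#' @param exon_length,intron_length Lengths in bp (`intron_length >= 30` so
#'   donor and acceptor windows never overlap).
#' @param spacing Intergenic spacing in bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return List: `genome` (named character), `models` (list of
#'   [gene_model()]), `fasta` and `gtf` (character vectors of file lines).
#' @export
gen_toy_genome <- function(n_genes = 2L, exons_per_gene = 3L,
                           exon_length = 60L, intron_length = 90L,
                           spacing = 100L, chrom = "chrT", seed = 1L) {
  if (exons_per_gene < 1L) stop("need at least one exon", call. = FALSE)
  if (intron_length < 30L)
    stop("intron_length must be >= 30 so consensus windows cannot overlap",
         call. = FALSE)
  if (exon_length < 15L)
    stop("exon_length must be >= 15", call. = FALSE)
  set.seed(as.integer(seed))
  gene_span <- exons_per_gene * exon_length +
    (exons_per_gene - 1L) * intron_length
  total <- n_genes * gene_span + (n_genes + 1L) * spacing
  base <- sample(DNA_BASES, total, replace = TRUE)
  models <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    start <- spacing * g + gene_span * (g - 1L) + 1L
    ex_starts <- start + (seq_len(exons_per_gene) - 1L) *
      (exon_length + intron_length)
    ex_ends <- ex_starts + exon_length - 1L
    if (exons_per_gene > 1L) {
      for (i in seq_len(exons_per_gene - 1L)) {
        is <- ex_ends[i] + 1L       # intron start
        ie <- ex_starts[i + 1L] - 1L  # intron end
        if (strand == "+") {
          base[c(is, is + 1L)] <- c("G", "T")
          base[c(ie - 1L, ie)] <- c("A", "G")
        } else {
          # transcribed GT..AG = genomic revcomp: CT at the left end, AC at
          # the right end of the genomic intron
          base[c(is, is + 1L)] <- c("C", "T")
          base[c(ie - 1L, ie)] <- c("A", "C")
        }
      }
    }
    models[[g]] <- gene_model(
      transcript_id = sprintf("TX%02d", g),
      gene_id = sprintf("GENE%02d", g),
      chrom = chrom, strand = strand,
      exons = cbind(ex_starts, ex_ends))
  }
  genome <- stats::setNames(paste(base, collapse = ""), chrom)
  fasta <- c(paste0(">", chrom),
             substring(genome, seq(1L, total, 60L),
                       pmin(seq(1L, total, 60L) + 59L, total)))
  gtf <- unlist(lapply(models, function(m) {
    vapply(seq_len(nrow(m$exons)), function(i) {
      paste(m$chrom, "toy", "exon", m$exons[i, "start"], m$exons[i, "end"],
            ".", m$strand, ".",
            sprintf('gene_id "%s"; transcript_id "%s";',
                    m$gene_id, m$transcript_id),
            sep = "\t")
    }, character(1L))
  }))
  names(models) <- vapply(models, `[[`, character(1L), "transcript_id")
  list(genome = genome, models = models, fasta = fasta, gtf = gtf)
}

#' Generate a synthetic recurrence/call table
#'
#' Draws variants in recurrence bins with configured per-bin proportions of
#' predicted splice-altering calls (defaults mirror the enrichment analysis
#' of somatic variants observed once/twice, three/four times, five or more
#' times).
#'
#' @param n_per_bin Variants per bin.
#' @param prop_positive Per-bin probability of a positive call.
#' @param bins List of inclusive `c(lo, hi)` recurrence ranges.
#' @param seed Integer seed.
#' @return Data frame: `recurrence`, `positive` (logical). Bins with
#'   `n = 0` are omitted.
#' @export
gen_recurrence <- function(n_per_bin = c(41455L, 299L, 129L),
                           prop_positive = c(0.707, 0.742, 0.845),
                           bins = list(c(1, 2), c(3, 4), c(5, Inf)),
                           seed = 1L) {
  stopifnot(length(n_per_bin) == length(bins),
            length(prop_positive) == length(bins),
            all(prop_positive >= 0), all(prop_positive <= 1))
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(bins), function(i) {
    n <- n_per_bin[i]
    if (n == 0L) return(NULL)
    hi <- if (is.finite(bins[[i]][2])) bins[[i]][2] else bins[[i]][1] + 5
    data.frame(recurrence = sample(seq(bins[[i]][1], hi), n, replace = TRUE),
               positive = stats::runif(n) < prop_positive[i])
  })
  do.call(rbind, rows)
}
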