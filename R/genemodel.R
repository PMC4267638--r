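# Gene models: minimal transcript structures (chrom, strand, ordered
# exons) from which intron boundaries and splicing consensus windows are
# derived. Coordinates are 1-based inclusive throughout the user-facing
# surface (the db and VCF convention).

#' Construct a gene model
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome/sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of exon `start`, `end`
#'   (1-based inclusive); any order, must not overlap.
#' @param gene_id Gene identifier (defaults to the transcript id).
#' @return Object of class `"gene_model"`; exons stored sorted by genomic
#'   start.
#' @export
gene_model <- function(transcript_id, chrom, strand, exons,
                       gene_id = transcript_id) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  ex <- as.matrix(as.data.frame(exons)[, 1:2])
  colnames(ex) <- c("start", "end")
  storage.mode(ex) <- "integer"
  if (nrow(ex) == 0L) stop("gene model needs at least one exon", call. = FALSE)
  if (any(ex[, "start"] > ex[, "end"]))
    stop("exon start > end", call. = FALSE)
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"]))
    stop("exons overlap", call. = FALSE)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = ex),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons), max(x$exons), x$strand, nrow(x$exons)))
  invisible(x)
}

# introns in genomic order: matrix with columns start, end (1-based,
# inclusive, the intronic bases themselves)
#' @noRd
model_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0L), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

#' Read gene models from a GTF/GFF file
#'
#' Imports exon features with `rtracklayer` and assembles one
#' [gene_model()] per transcript.
#'
#' @param path GTF or GFF3 file.
#' @return Named list of `"gene_model"` objects (by transcript id).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path, call. = FALSE)
  tx <- as.character(gr$transcript_id)
  gene <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tx
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  out <- lapply(split(seq_along(gr), tx), function(idx) {
    gene_model(transcript_id = tx[idx[1L]], chrom = chrom[idx[1L]],
               strand = strand[idx[1L]],
               exons = cbind(starts[idx], ends[idx]),
               gene_id = gene[idx[1L]])
  })
  out
}

# genomic positions of the modeled (non-GT-AG) consensus offsets around one
# intron; returns data.frame(pos, site, offset, side)
#' @noRd
consensus_positions <- function(intron_start, intron_end, strand) {
  donor_off <- variant_offsets(region_definition("donor"))
  acc_off <- variant_offsets(region_definition("acceptor"))
  if (strand == "+") {
    donor_pos <- ifelse(donor_off < 0, intron_start + donor_off,
                        intron_start + donor_off - 1L)
    acc_pos <- ifelse(acc_off < 0, intron_end + acc_off + 1L,
                      intron_end + acc_off)
  } else {
    donor_pos <- ifelse(donor_off < 0, intron_end - donor_off,
                        intron_end - donor_off + 1L)
    acc_pos <- ifelse(acc_off < 0, intron_start - acc_off - 1L,
                      intron_start - acc_off)
  }
  rbind(
    data.frame(pos = as.integer(donor_pos), site = "donor", offset = donor_off,
               side = ifelse(donor_off < 0, "exonic", "intronic"),
               stringsAsFactors = FALSE),
    data.frame(pos = as.integer(acc_pos), site = "acceptor", offset = acc_off,
               side = ifelse(acc_off < 0, "intronic", "exonic"),
               stringsAsFactors = FALSE)
  )
}

#' @noRd
genome_as_strings <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(out))  # FASTA description -> id
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  stop("genome must be a FASTA path, DNAStringSet, or named character vector",
       call. = FALSE)
}

#' Enumerate all potential scSNVs for a set of gene models
#'
#' For every intron of every transcript, emits the 21 modeled consensus
#' positions (donor -3..+8 and acceptor -12..+2 minus the invariant GT-AG
#' dinucleotides) with all 3 alternative alleles per position: 63 records
#' per intron before cross-transcript merging. Reference and alternative
#' alleles are reported on the + strand regardless of transcript strand.
#' Records present in several transcripts are merged into one row with the
#' transcript list joined.
#'
#' @param models List of [gene_model()] objects (or a single one).
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @return Data frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `transcripts` (comma-joined), `site`, `offset`, `side`, `ada_score`,
#'   `rf_score` (NA until scored), sorted by (chrom, pos, alt).
#' @export
enumerate_scsnvs <- function(models, genome) {
  if (inherits(models, "gene_model")) models <- list(models)
  seqs <- genome_as_strings(genome)
  per_tx <- lapply(models, function(mod) {
    if (!mod$chrom %in% names(seqs))
      stop("unknown chromosome: ", mod$chrom, call. = FALSE)
    chrom_seq <- seqs[[mod$chrom]]
    if (max(mod$exons) > nchar(chrom_seq) || min(mod$exons) < 1L)
      stop("exon outside sequence bounds for ", mod$transcript_id,
           call. = FALSE)
    intr <- model_introns(mod)
    if (nrow(intr) == 0L) return(NULL)
    sites <- do.call(rbind, lapply(seq_len(nrow(intr)), function(i)
      consensus_positions(intr[i, "start"], intr[i, "end"], mod$strand)))
    ref <- substring(chrom_seq, sites$pos, sites$pos)
    bad <- !ref %in% DNA_BASES
    if (any(bad))
      stop("non-ACGT reference base at ", mod$chrom, ":",
           sites$pos[bad][1L], call. = FALSE)
    alt <- lapply(ref, function(b) setdiff(DNA_BASES, b))
    data.frame(
      chrom = mod$chrom,
      pos = rep(sites$pos, each = 3L),
      ref = rep(ref, each = 3L),
      alt = unlist(alt),
      gene_id = mod$gene_id,
      transcripts = mod$transcript_id,
      site = rep(sites$site, each = 3L),
      offset = rep(sites$offset, each = 3L),
      side = rep(sites$side, each = 3L),
      stringsAsFactors = FALSE
    )
  })
  recs <- do.call(rbind, per_tx)
  if (is.null(recs))
    return(empty_scsnv_records())
  key <- paste(recs$chrom, recs$pos, recs$ref, recs$alt, sep = ":")
  first <- !duplicated(key)
  merged <- recs[first, , drop = FALSE]
  tx_by_key <- vapply(split(recs$transcripts, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1L))
  gene_by_key <- vapply(split(recs$gene_id, key), function(x)
    paste(sort(unique(x)), collapse = ","), character(1L))
  merged$transcripts <- tx_by_key[key[first]]
  merged$gene_id <- gene_by_key[key[first]]
  merged$ada_score <- NA_real_
  merged$rf_score <- NA_real_
  merged <- merged[order(merged$chrom, merged$pos, merged$alt), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' @noRd
empty_scsnv_records <- function() {
  data.frame(chrom = character(0L), pos = integer(0L), ref = character(0L),
             alt = character(0L), gene_id = character(0L),
             transcripts = character(0L), site = character(0L),
             offset = integer(0L), side = character(0L),
             ada_score = numeric(0L), rf_score = numeric(0L),
             stringsAsFactors = FALSE)
}

#' Classify a variant against splicing consensus regions
#'
#' Reports every consensus region of every intron that contains the
#' position: GT-AG positions are excluded by construction, and anything
#' other than a single-nucleotide substitution returns no hits. An empty
#' result means the variant is not an scSNV.
#'
#' @param chrom,pos,ref,alt The variant (1-based position, single bases).
#' @param models List of [gene_model()] objects.
#' @param genome Optional genome (as in [enumerate_scsnvs()]); when given,
#'   a reference-allele mismatch is attached as a warning attribute
#'   `ref_mismatch` rather than an error.
#' @return Data frame: `transcript_id`, `site`, `offset`, `side` (0 rows if
#'   not an scSNV).
#' @export
classify_variant <- function(chrom, pos, ref, alt, models, genome = NULL) {
  if (inherits(models, "gene_model")) models <- list(models)
  out <- data.frame(transcript_id = character(0L), site = character(0L),
                    offset = integer(0L), side = character(0L),
                    stringsAsFactors = FALSE)
  snv <- nchar(ref) == 1L && nchar(alt) == 1L && ref != alt &&
    all(c(ref, alt) %in% DNA_BASES)
  if (!snv) return(out)
  hits <- lapply(models, function(mod) {
    if (mod$chrom != chrom) return(NULL)
    intr <- model_introns(mod)
    if (nrow(intr) == 0L) return(NULL)
    sites <- do.call(rbind, lapply(seq_len(nrow(intr)), function(i)
      consensus_positions(intr[i, "start"], intr[i, "end"], mod$strand)))
    sites <- sites[sites$pos == pos, , drop = FALSE]
    if (nrow(sites) == 0L) return(NULL)
    data.frame(transcript_id = mod$transcript_id, site = sites$site,
               offset = sites$offset, side = sites$side,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (!is.null(hits)) out <- hits
  rownames(out) <- NULL
  if (!is.null(genome) && nrow(out) > 0L) {
    seqs <- genome_as_strings(genome)
    if (chrom %in% names(seqs)) {
      actual <- substring(seqs[[chrom]], pos, pos)
      if (actual != ref) {
        warning("reference allele mismatch at ", chrom, ":", pos,
                " (genome has ", actual, ", variant says ", ref, ")")
        attr(out, "ref_mismatch") <- actual
      }
    }
  }
  out
}
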