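# Tab-delimited scSNV score database: one row per (chrom, pos, ref, alt)
# with site annotation and the two ensemble probabilities. Dialect:
# header line "#chr pos ref alt refseq_tx ensembl_tx site offset ada_score
# rf_score" (tab-separated), "." for missing values, rows sorted by
# (chrom, pos).

DB_COLUMNS <- c("chr", "pos", "ref", "alt", "refseq_tx", "ensembl_tx",
                "site", "offset", "ada_score", "rf_score")

#' Write an scSNV score database
#'
#' @param records Data frame as produced by [enumerate_scsnvs()] (columns
#'   `chrom`, `pos`, `ref`, `alt`, `transcripts`, `site`, `offset`,
#'   `ada_score`, `rf_score`; an `ensembl_tx` column is optional). Must be
#'   sorted by (chrom, pos).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_db <- function(records, path) {
  if (nrow(records) > 1L) {
    o <- order(records$chrom, records$pos)
    if (!identical(o, seq_len(nrow(records))))
      stop("records must be sorted by (chrom, pos) before writing",
           call. = FALSE)
  }
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 6,
                                                      scientific = FALSE,
                                                      trim = TRUE))
  lines <- paste(
    records$chrom, records$pos, records$ref, records$alt,
    records$transcripts %||% ".",
    records$ensembl_tx %||% rep(".", nrow(records)),
    records$site, records$offset,
    fmt_num(records$ada_score), fmt_num(records$rf_score),
    sep = "\t")
  writeLines(c(paste0("#", paste(DB_COLUMNS, collapse = "\t")), lines), path)
  invisible(path)
}

#' Read an scSNV score database
#'
#' @param path A file written by [write_db()].
#' @return Data frame in [enumerate_scsnvs()] layout. Malformed lines are
#'   reported with their line numbers.
#' @export
read_db <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#"))
    stop("missing db header line in ", path, call. = FALSE)
  body <- lines[-1L]
  if (length(body) == 0L) return(empty_scsnv_records())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(DB_COLUMNS))
  if (length(bad))
    stop("malformed db line(s) ", paste(bad + 1L, collapse = ", "),
         " in ", path, " (expected ", length(DB_COLUMNS), " fields)",
         call. = FALSE)
  m <- matrix(unlist(parts), ncol = length(DB_COLUMNS), byrow = TRUE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  pos <- num(m[, 2L]); offset <- num(m[, 8L])
  bad <- which(is.na(pos) | (m[, 8L] != "." & is.na(offset)))
  if (length(bad))
    stop("malformed db line(s) ", paste(bad + 1L, collapse = ", "),
         " in ", path, " (non-numeric pos/offset)", call. = FALSE)
  data.frame(chrom = m[, 1L], pos = as.integer(pos), ref = m[, 3L],
             alt = m[, 4L], gene_id = NA_character_,
             transcripts = m[, 5L], site = m[, 7L],
             offset = as.integer(offset),
             side = NA_character_,
             ada_score = num(m[, 9L]), rf_score = num(m[, 10L]),
             ensembl_tx = m[, 6L],
             stringsAsFactors = FALSE)
}

#' Query an scSNV database
#'
#' Either an exact variant lookup (`pos`, `ref`, `alt` given) or a
#' half-open region query `[start, end)` on one chromosome.
#'
#' @param db Data frame from [read_db()] or [enumerate_scsnvs()].
#' @param chrom Chromosome.
#' @param pos,ref,alt Exact variant (all three required together).
#' @param start,end Half-open region bounds.
#' @return The matching record rows.
#' @export
query_db <- function(db, chrom, pos = NULL, ref = NULL, alt = NULL,
                     start = NULL, end = NULL) {
  if (!is.null(pos)) {
    if (is.null(ref) || is.null(alt))
      stop("exact query needs pos, ref and alt", call. = FALSE)
    sel <- db$chrom == chrom & db$pos == pos & db$ref == ref & db$alt == alt
  } else if (!is.null(start) && !is.null(end)) {
    sel <- db$chrom == chrom & db$pos >= start & db$pos < end
  } else {
    stop("supply either (pos, ref, alt) or (start, end)", call. = FALSE)
  }
  out <- db[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a VCF with scSNV ensemble scores
#'
#' Adds `SCSNV_ADA`, `SCSNV_RF` and `SCSNV_SITE` INFO fields to records
#' whose (chrom, pos, ref, alt) match a database row. Non-matching records
#' and the record order are untouched; output is plain-text VCF.
#'
#' @param vcf_path Input VCF (plain or gzipped; read with `vcfR`).
#' @param db Database data frame.
#' @param out_path Output VCF path.
#' @return Number of annotated records, invisibly.
#' @export
annotate_vcf <- function(vcf_path, db, out_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  key <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  db_key <- paste(db$chrom, db$pos, db$ref, db$alt, sep = ":")
  hit <- match(key, db_key)
  n_hit <- sum(!is.na(hit))
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 4, trim = TRUE))
  for (i in which(!is.na(hit))) {
    r <- db[hit[i], ]
    tag <- sprintf("SCSNV_ADA=%s;SCSNV_RF=%s;SCSNV_SITE=%s|%+d",
                   fmt(r$ada_score), fmt(r$rf_score), r$site, r$offset)
    old <- fix[i, "INFO"]
    fix[i, "INFO"] <- if (is.na(old) || old == "." || old == "") tag
                      else paste(old, tag, sep = ";")
  }
  header_extra <- c(
    '##INFO=<ID=SCSNV_ADA,Number=1,Type=Float,Description="scSNV boosting (ada) splice-altering probability">',
    '##INFO=<ID=SCSNV_RF,Number=1,Type=Float,Description="scSNV random-forest splice-altering probability">',
    '##INFO=<ID=SCSNV_SITE,Number=1,Type=String,Description="scSNV site kind and signed offset">')
  meta <- v@meta
  meta <- append(meta, header_extra, after = length(meta))
  cols <- colnames(fix)
  gt <- v@gt
  if (!is.null(gt) && ncol(gt) > 0L) cols <- c(cols, colnames(gt))
  body <- apply(cbind(fix, if (!is.null(gt) && ncol(gt) > 0L) gt), 1L,
                function(r) paste(ifelse(is.na(r), ".", r), collapse = "\t"))
  writeLines(c(meta, paste0("#", paste(cols, collapse = "\t")), body),
             out_path)
  invisible(n_hit)
}
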