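test_that("gene models validate exon geometry", {
  gm <- gene_model("tx1", "chr1", "+", rbind(c(10, 20), c(40, 60)))
  expect_s3_class(gm, "gene_model")
  expect_error(gene_model("tx1", "chr1", "*", rbind(c(1, 5))), "strand")
  expect_error(gene_model("tx1", "chr1", "+", rbind(c(10, 5))), "start > end")
  expect_error(gene_model("tx1", "chr1", "+", rbind(c(1, 20), c(15, 30))),
               "overlap")
})

test_that("a two-exon transcript yields exactly 63 scSNV records", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 3)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  expect_equal(nrow(recs), 63)
  expect_equal(length(unique(recs$pos)), 21)
  expect_equal(sum(recs$site == "donor"), 27)     # 9 positions x 3 alts
  expect_equal(sum(recs$site == "acceptor"), 36)  # 12 positions x 3 alts
  expect_true(all(recs$ref != recs$alt))
  # no GT-AG offsets present
  expect_false(any(recs$site == "donor" & recs$offset %in% c(1, 2)))
  expect_false(any(recs$site == "acceptor" & recs$offset %in% c(-1, -2)))
})

test_that("single-exon transcripts produce no records", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 1, seed = 4)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  expect_equal(nrow(recs), 0)
})

test_that("record count is 63 per intron on random gene geometries", {
  for (s in 1:5) {
    n_ex <- sample(2:5, 1)
    toy <- gen_toy_genome(n_genes = 2, exons_per_gene = n_ex,
                          exon_length = sample(c(40, 80), 1),
                          intron_length = sample(c(60, 120), 1), seed = 50 + s)
    recs <- enumerate_scsnvs(toy$models, toy$genome)
    expect_equal(nrow(recs), 2 * (n_ex - 1) * 63)
  }
})

test_that("emitted reference alleles match the genome", {
  toy <- gen_toy_genome(n_genes = 2, exons_per_gene = 3, seed = 6)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  g <- toy$genome[[1]]
  expect_true(all(substring(g, recs$pos, recs$pos) == recs$ref))
})

test_that("minus-strand enumeration matches a reverse-complement oracle", {
  toy <- gen_toy_genome(n_genes = 2, exons_per_gene = 2, seed = 7)
  minus <- toy$models[[which(vapply(toy$models, `[[`, "", "strand") == "-")]]
  recs <- enumerate_scsnvs(minus, toy$genome)
  expect_equal(nrow(recs), 63)
  g <- toy$genome[[1]]
  intron_start <- unname(minus$exons[1, "end"] + 1L)
  intron_end <- unname(minus$exons[2, "start"] - 1L)
  # oracle: on the reverse complement the minus-strand gene reads like a
  # plus-strand gene; donor +3 (transcription sense) is genomic
  # intron_end - 2, and the transcribed base is the complement
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  donor3 <- recs[recs$site == "donor" & recs$offset == 3, ]
  expect_equal(unique(donor3$pos), intron_end - 2L)
  # transcribed GT at intron 5' end = genomic complement "AC" at the right edge
  expect_equal(substring(g, intron_end - 1L, intron_end), "AC")
  expect_equal(substring(g, intron_start, intron_start + 1L), "CT")
  # acceptor exonic +1 (first exon base after the intron, transcription
  # sense) is genomic intron_start - 1
  acc1 <- recs[recs$site == "acceptor" & recs$offset == 1, ]
  expect_equal(unique(acc1$pos), intron_start - 1L)
})

test_that("variant classification applies the scSNV filters", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 8)
  m <- toy$models[[1]]
  g <- toy$genome[[1]]
  intron_start <- unname(m$exons[1, "end"] + 1L)

  # donor +3 is intronic and classified
  pos3 <- intron_start + 2L
  ref3 <- substring(g, pos3, pos3)
  alt3 <- setdiff(c("A", "C", "G", "T"), ref3)[1]
  hit <- classify_variant("chrT", pos3, ref3, alt3, toy$models)
  hit <- hit[1, ]
  expect_equal(hit$site, "donor")
  expect_equal(hit$offset, 3L)
  expect_equal(hit$side, "intronic")

  # donor +1 (the G of GT) is excluded
  expect_equal(nrow(classify_variant("chrT", intron_start, "G", "A",
                                     toy$models)), 0)
  # non-SNV input is not an scSNV
  expect_equal(nrow(classify_variant("chrT", pos3, paste0(ref3, "T"),
                                     alt3, toy$models)), 0)
  expect_equal(nrow(classify_variant("chrT", pos3, ref3, ref3, toy$models)), 0)
  # position outside any consensus window
  expect_equal(nrow(classify_variant("chrT", 3L, substring(g, 3, 3), "A",
                                     toy$models)), 0)
  # reference mismatch triggers a warning-carrying result
  ref <- substring(g, pos3, pos3)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_warning(res <- classify_variant("chrT", pos3, wrong,
                                         setdiff(c("A", "C", "G", "T"),
                                                 wrong)[1],
                                         toy$models, toy$genome),
                 "mismatch")
  expect_identical(attr(res, "ref_mismatch"), ref)
})

test_that("a short exon can sit in two consensus windows at once", {
  # exon2 of length 8 lies inside the upstream acceptor +1..+2 and the
  # downstream donor -3..-1 windows; pick a base in both
  gm <- gene_model("tx", "chrS", "+",
                   rbind(c(1, 50), c(151, 158), c(259, 300)))
  set.seed(9)
  g <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  genome <- c(chrS = g)
  pos <- 152L  # acceptor +2 of intron 1 and donor -3 (158-6) of intron 2? no:
  # donor -3..-1 of intron 2 are 156,157,158; acceptor +1,+2 are 151,152.
  hits <- classify_variant("chrS", pos, substring(g, pos, pos),
                           setdiff(c("A", "C", "G", "T"),
                                   substring(g, pos, pos))[1],
                           list(gm))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site, "acceptor")
  # a 4-base exon puts single positions into both windows
  gm2 <- gene_model("tx2", "chrS", "+",
                    rbind(c(1, 50), c(151, 154), c(255, 300)))
  hits2 <- classify_variant("chrS", 152L, substring(g, 152, 152),
                            setdiff(c("A", "C", "G", "T"),
                                    substring(g, 152, 152))[1],
                            list(gm2))
  expect_equal(nrow(hits2), 2)
  expect_setequal(hits2$site, c("acceptor", "donor"))
})

test_that("overlapping transcripts merge into one record with both ids", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 10)
  m1 <- toy$models[[1]]
  m2 <- m1; m2$transcript_id <- "TX99"
  recs <- enumerate_scsnvs(list(m1, m2), toy$genome)
  expect_equal(nrow(recs), 63)
  expect_true(all(recs$transcripts == paste(sort(c(m1$transcript_id, "TX99")),
                                            collapse = ",")))
})

test_that("the db dialect round-trips and rejects malformed input", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 11)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  set.seed(1)
  recs$ada_score <- round(runif(nrow(recs)), 3)
  recs$rf_score[seq(1, 63, 2)] <- round(runif(32), 3)  # half missing
  f <- withr::local_tempfile(fileext = ".tsv")
  write_db(recs, f)
  back <- read_db(f)
  for (col in c("chrom", "pos", "ref", "alt", "transcripts", "site", "offset"))
    expect_equal(back[[col]], recs[[col]])
  expect_equal(back$ada_score, recs$ada_score, tolerance = 1e-9)
  expect_equal(back$rf_score, recs$rf_score, tolerance = 1e-9)
  # byte-identical second write
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_db(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # unsorted input refused
  expect_error(write_db(recs[rev(seq_len(nrow(recs))), ], f), "sorted")
  # malformed line reported with its number
  lines <- readLines(f)
  lines[5] <- "chrT\toops"
  writeLines(lines, f)
  expect_error(read_db(f), "line.* 5")
})

test_that("db queries return exact variants and half-open regions", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 12)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  r <- recs[10, ]
  hit <- query_db(recs, r$chrom, pos = r$pos, ref = r$ref, alt = r$alt)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$offset, r$offset)
  # query at a GT-AG position is empty
  m <- toy$models[[1]]
  gtag <- m$exons[1, "end"] + 1L
  expect_equal(nrow(query_db(recs, "chrT", pos = gtag, ref = "G", alt = "A")),
               0)
  # half-open region excludes the end position
  p1 <- sort(unique(recs$pos))[1:2]
  reg <- query_db(recs, "chrT", start = p1[1], end = p1[2])
  expect_true(all(reg$pos == p1[1]))
  expect_error(query_db(recs, "chrT", pos = 5), "ref and alt")
})

test_that("VCF annotation tags matching records and preserves the rest", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 13)
  recs <- enumerate_scsnvs(toy$models, toy$genome)
  set.seed(2)
  recs$ada_score <- round(runif(nrow(recs)), 3)
  recs$rf_score <- round(runif(nrow(recs)), 3)
  g <- toy$genome[[1]]
  hits <- recs[c(5, 20, 40), ]
  far <- c(3L, 7L)  # positions outside any consensus window
  rows <- data.frame(
    chrom = "chrT",
    pos = c(hits$pos, far),
    ref = c(hits$ref, substring(g, far, far)),
    alt = c(hits$alt, vapply(substring(g, far, far), function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")))
  rows <- rows[order(rows$pos), ]
  vcf_in <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chrT>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt, ".",
                     "PASS", ".", sep = "\t")), vcf_in)
  vcf_out <- withr::local_tempfile(fileext = ".vcf")
  n <- annotate_vcf(vcf_in, recs, vcf_out)
  expect_equal(n, 3)
  out <- readLines(vcf_out)
  body <- out[!startsWith(out, "#")]
  expect_equal(length(body), 5)  # record order and count preserved
  expect_equal(sum(grepl("SCSNV_ADA=", body)), 3)
  # non-matching records untouched
  untouched <- body[!grepl("SCSNV_ADA=", body)]
  expect_true(all(grepl("\tPASS\t\\.$", untouched)))
  # output remains parseable VCF
  v2 <- vcfR::read.vcfR(vcf_out, verbose = FALSE)
  expect_equal(nrow(v2@fix), 5)
})

test_that("enumeration validates chromosome names and bounds", {
  toy <- gen_toy_genome(n_genes = 1, exons_per_gene = 2, seed = 14)
  bad <- toy$models[[1]]
  bad$chrom <- "chrMissing"
  expect_error(enumerate_scsnvs(bad, toy$genome), "unknown chromosome")
  bad2 <- toy$models[[1]]
  bad2$exons[2, "end"] <- nchar(toy$genome[[1]]) + 100L
  expect_error(enumerate_scsnvs(bad2, toy$genome), "bounds")
})
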