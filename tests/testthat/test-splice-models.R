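test_that("region definitions have the documented geometry", {
  donor <- region_definition("donor")
  acceptor <- region_definition("acceptor")
  expect_equal(donor$length, 11L)
  expect_equal(acceptor$length, 14L)
  expect_true(all(diff(donor$offsets) > 0))
  expect_true(all(diff(acceptor$offsets) > 0))
  expect_false(0 %in% c(donor$offsets, acceptor$offsets))
  expect_equal(donor$invariant, c(1L, 2L))
  expect_equal(acceptor$invariant, c(-2L, -1L))
  expect_equal(length(variant_offsets(donor)), 9L)
  expect_equal(length(variant_offsets(acceptor)), 12L)
  expect_equal(donor$exonic_span, 3L)
  expect_equal(acceptor$exonic_span, 2L)
})

test_that("PWM training recovers degenerate and pseudocounted frequencies", {
  reg <- region_definition("donor")
  m <- train_pwm(rep("CAGGTAAGTAT", 4), reg, pseudocount = 0)
  expect_true(all(apply(m$freq, 1, max) == 1))
  expect_equal(rowSums(m$freq), rep(1, 11), tolerance = 1e-9)

  m2 <- train_pwm(c("AA", "CC"), pseudocount = 1)
  # A observed once of two at position 1: (1 + 1) / (2 + 4)
  expect_equal(unname(m2$freq[1, "A"]), 1 / 3)
  expect_equal(unname(m2$freq[1, "C"]), 1 / 3)
  expect_equal(unname(m2$freq[1, "G"]), 1 / 6)
})

test_that("PWM training recovers a known frequency table from samples", {
  truth <- matrix(c(0.5, 0.2, 0.2, 0.1,
                    0.1, 0.6, 0.2, 0.1,
                    0.25, 0.25, 0.25, 0.25), nrow = 3, byrow = TRUE)
  set.seed(42)
  seqs <- replicate(400, paste(sapply(1:3, function(p)
    sample(c("A", "C", "G", "T"), 1, prob = truth[p, ])), collapse = ""))
  m <- train_pwm(seqs, pseudocount = 0.5)
  expect_lt(max(abs(m$freq - truth)), 0.1)
})

test_that("PWM rejects empty, ragged and non-ACGT input with positions", {
  expect_error(train_pwm(character(0)), "empty")
  expect_error(train_pwm(c("AAA", "AAAA")), "unequal")
  expect_error(train_pwm(c("AAA", "ANA")), "position 2")
  m <- train_pwm(c("ACGT", "ACGT"))
  expect_error(score_pwm(m, "ACNT"), "position 3")
  # lowercase accepted
  expect_silent(train_pwm(c("acgt", "ACGT")))
})

test_that("PWM score endpoints and a hand-computed value are exact", {
  set.seed(7)
  seqs <- replicate(300, paste(sample(c("A", "C", "G", "T"), 5, TRUE,
                                      prob = c(.4, .3, .2, .1)), collapse = ""))
  m <- train_pwm(seqs)
  consensus <- paste(colnames(m$freq)[apply(m$freq, 1, which.max)], collapse = "")
  worst <- paste(colnames(m$freq)[apply(m$freq, 1, which.min)], collapse = "")
  expect_equal(score_pwm(m, consensus), 100)
  expect_equal(score_pwm(m, worst), 0)

  # 3-position toy matrix, hand-computed via the normalization formula
  m3 <- train_pwm(c("AAC", "ACC", "AAG", "CAC"), pseudocount = 0)
  lf <- log(m3$freq)
  lo <- sum(apply(lf[, ], 1, function(r) min(r[is.finite(r) | TRUE])))
  expected <- 100 * (lf[1, "A"] + lf[2, "A"] + lf[3, "C"] - m3$min_logsum) /
    (m3$max_logsum - m3$min_logsum)
  expect_equal(score_pwm(m3, "AAC"), min(max(expected, 0), 100))
})

test_that("PWM scores are bounded and monotone in per-position frequency", {
  set.seed(11)
  seqs <- replicate(200, paste(sample(c("A", "C", "G", "T"), 6, TRUE,
                                      prob = c(.4, .3, .2, .1)), collapse = ""))
  m <- train_pwm(seqs)
  probes <- replicate(50, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                collapse = ""))
  s <- score_pwm(m, probes)
  expect_true(all(s >= 0 & s <= 100))
  # substituting any base by a higher-frequency base never lowers the score
  for (probe in probes[1:10]) {
    base <- strsplit(probe, "")[[1]]
    s0 <- score_pwm(m, probe)
    for (p in 1:6) {
      f_here <- m$freq[p, base[p]]
      for (b in c("A", "C", "G", "T")) {
        if (m$freq[p, b] >= f_here) {
          alt <- base; alt[p] <- b
          expect_gte(score_pwm(m, paste(alt, collapse = "")), s0 - 1e-9)
        }
      }
    }
  }
})

test_that("order-1 maximum entropy equals the independence model", {
  set.seed(3)
  seqs <- replicate(60, paste(sample(c("A", "C", "G", "T"), 4, TRUE,
                                     prob = c(.4, .3, .2, .1)), collapse = ""))
  m <- train_maxent(seqs, constraint_order = 1, pseudocount = 0.5)
  p <- maxent_distribution(m)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # product of smoothed per-position marginals at every 4^L cell
  km <- cbind(rep(1:4, each = 64), rep(rep(1:4, each = 16), 4),
              rep(rep(1:4, each = 4), 16), rep(1:4, 64))
  pf <- m$pos_freq
  p_ind <- pf[1, km[, 1]] * pf[2, km[, 2]] * pf[3, km[, 3]] * pf[4, km[, 4]]
  expect_equal(unname(p), unname(p_ind), tolerance = 1e-10)
})

test_that("training on all sequences once yields the uniform distribution", {
  for (ord in 1:3) {
    m <- train_maxent(all_sequences(3), constraint_order = ord)
    expect_equal(maxent_distribution(m), rep(1 / 64, 64), tolerance = 1e-12)
  }
})

test_that("order-2 fit matches brute-force constrained entropy maximization", {
  set.seed(5)
  seqs <- replicate(50, paste(sample(c("A", "C", "G", "T"), 4, TRUE,
                                     prob = c(.4, .3, .2, .1)), collapse = ""))
  m <- train_maxent(seqs, constraint_order = 2, pseudocount = 0.5)
  oracle <- ipf_maxent_order2(seqs, pseudocount = 0.5)
  tv <- 0.5 * sum(abs(maxent_distribution(m) - oracle$p))
  expect_lt(tv, 1e-4)
})

test_that("maximum-entropy scores are log2 odds against background", {
  # model trained on the uniform library equals the background -> score 0
  m <- train_maxent(all_sequences(3), constraint_order = 2)
  expect_equal(score_maxent(m, c("AAA", "CGT", "TTT")), rep(0, 3),
               tolerance = 1e-9)

  # scores equal log2 ratios from the enumerated distribution
  set.seed(8)
  seqs <- replicate(50, paste(sample(c("A", "C", "G", "T"), 4, TRUE,
                                     prob = c(.5, .2, .2, .1)), collapse = ""))
  m2 <- train_maxent(seqs, constraint_order = 2)
  p <- maxent_distribution(m2)
  allseq <- all_sequences(4)
  probes <- sample(allseq, 10)
  expected <- log2(p[match(probes, allseq)] / (1 / 256))
  expect_equal(score_maxent(m2, probes), expected, tolerance = 1e-9)

  # a sequence with P_model = 2 * P_background scores exactly +1
  idx <- which.min(abs(p - 2 / 256))
  if (abs(p[idx] - 2 / 256) < 1e-6)
    expect_equal(score_maxent(m2, allseq[idx]), 1, tolerance = 1e-3)
})

test_that("fitted entropy is at least the smoothed empirical entropy", {
  set.seed(13)
  for (L in c(3, 5)) {
    seqs <- replicate(40, paste(sample(c("A", "C", "G", "T"), L, TRUE,
                                       prob = c(.5, .25, .15, .1)),
                                collapse = ""))
    for (ord in 1:3) {
      m <- train_maxent(seqs, constraint_order = ord)
      p <- maxent_distribution(m)
      ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
      emp <- table(factor(seqs, levels = all_sequences(L))) / length(seqs)
      expect_gte(ent(p) + 1e-9, ent(as.numeric(emp)))
    }
  }
})

test_that("both scorers are deterministic and training is reproducible", {
  seqs <- gen_splice_sites("donor", 0.8, 100, seed = 21)
  m1 <- train_maxent(seqs, region_definition("donor"), constraint_order = 2)
  m2 <- train_maxent(seqs, region_definition("donor"), constraint_order = 2)
  expect_identical(m1$grams, m2$grams)
  p1 <- train_pwm(seqs, region_definition("donor"))
  p2 <- train_pwm(seqs, region_definition("donor"))
  expect_identical(p1$freq, p2$freq)
  probe <- gen_splice_sites("donor", 0.3, 5, seed = 22)
  expect_identical(score_maxent(m1, probe), score_maxent(m2, probe))
  expect_identical(score_pwm(p1, probe), score_pwm(p2, probe))
})

test_that("donor and acceptor models train at their native lengths", {
  donors <- gen_splice_sites("donor", 0.9, 150, seed = 2)
  acceptors <- gen_splice_sites("acceptor", 0.9, 150, seed = 2)
  pm <- train_pwm(donors, region_definition("donor"))
  me <- train_maxent(acceptors, region_definition("acceptor"),
                     constraint_order = 2)
  expect_equal(pm$length, 11L)
  expect_equal(me$length, 14L)
  # region length mismatch is rejected
  expect_error(train_pwm(donors, region_definition("acceptor")), "14")
})
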