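test_that("isoform merging widens overlapping exons to extreme bounds", {
  genome <- randomRnaString(500)
  ann <- data.frame(
    gene_id = "g", isoform_id = c("i1", "i1", "i2", "i2"),
    feature = "exon",
    start = c(1L, 201L, 1L, 251L), end = c(100L, 300L, 100L, 400L))
  mt <- suppressWarnings(mergeIsoforms(ann, genome))
  expect_equal(IRanges::start(exonBlocks(mt)), c(1L, 201L))
  expect_equal(IRanges::end(exonBlocks(mt)), c(100L, 400L))
  expect_equal(as.character(mergedSeq(mt)),
               paste0(substring(genome, 1, 100), substring(genome, 201, 400)))
  expect_equal(mergedLength(mt), 300L)
  # single isoform: identity
  ann1 <- ann[ann$isoform_id == "i1", ]
  mt1 <- suppressWarnings(mergeIsoforms(ann1, genome))
  expect_equal(IRanges::end(exonBlocks(mt1)), c(100L, 300L))
  # order independence and idempotence
  mt_r <- suppressWarnings(mergeIsoforms(ann[c(3, 4, 1, 2), ], genome))
  expect_equal(as.character(mergedSeq(mt_r)), as.character(mergedSeq(mt)))
  # disjoint alternative exons are all retained in order
  ann2 <- rbind(ann, data.frame(gene_id = "g", isoform_id = "i3",
                                feature = "exon", start = 450L, end = 480L))
  mt2 <- suppressWarnings(mergeIsoforms(ann2, genome))
  expect_equal(length(exonBlocks(mt2)), 3L)
})

test_that("region extents use the most extreme isoform annotations", {
  genome <- randomRnaString(1200)
  ann <- data.frame(
    gene_id = "g",
    isoform_id = c("i1", "i1", "i1", "i2", "i2", "i2"),
    feature = rep(c("exon", "five_prime_utr", "orf"), 2),
    start = c(1L, 1L, 101L, 1L, 1L, 101L),
    end = c(1000L, 100L, 900L, 1000L, 100L, 950L))
  mt <- mergeIsoforms(ann, genome)
  reg <- regionBounds(mt)
  expect_equal(IRanges::end(reg["orf"]), 950L)
  expect_equal(IRanges::end(reg["five_prime_utr"]), 100L)
  # missing ORF annotation warns and leaves regions unknown
  ann_no <- ann[ann$feature == "exon", ]
  expect_warning(mt_no <- mergeIsoforms(ann_no, genome), "no ORF")
  expect_equal(length(regionBounds(mt_no)), 0L)
  # boundary convention: a position at the ORF end is ORF
  mt2 <- sharedStudy()$genes$G1$merged
  reg2 <- regionBounds(mt2)
  expect_equal(regionOfPosition(mt2, IRanges::end(reg2["orf"])), "orf")
  expect_equal(regionOfPosition(mt2, IRanges::end(reg2["orf"]) + 1L),
               "three_prime_utr")
})

test_that("consensus windows mark isoform disagreements with '?'", {
  g <- sharedStudy()$genes$G1
  ann <- genesToAnnotation(sharedStudy()$genes)
  aligned <- alignIsoforms(ann, g$isoform_seqs, g$merged)
  fr <- setNames(g$isoforms$fraction, g$isoforms$isoform_id)
  mt <- consensusFromAligned(g$merged, aligned, fr)
  cons <- strsplit(consensusSeq(mt), "")[[1]]
  # '?' exactly at the planted SNP positions
  expect_equal(which(cons == "?"), g$snps)

  # pick a site whose window is free of planted SNPs
  start <- 200
  while (any(g$snps >= start - 15 & g$snps <= start + 34))
    start <- start + 50
  # identical isoforms give a '?'-free 50-mer
  w <- common50mer(mt, start)
  expect_equal(nchar(w$window), 50L)
  expect_false(grepl("\\?", w$window))
  # engineered disagreement at window position 3 only
  al2 <- aligned[, , drop = FALSE]
  pos <- start - 15 + 2  # window position 3
  al2["I2", pos] <- setdiff(c("A", "C", "G", "U"), al2["I1", pos])[1]
  mt2 <- consensusFromAligned(g$merged, al2, fr)
  w2 <- common50mer(mt2, start)
  qpos <- which(strsplit(w2$window, "")[[1]] == "?")
  expect_equal(qpos, 3L)
  # left truncation at the transcript start is flagged
  w3 <- common50mer(mt, 10)
  expect_equal(nchar(w3$window), 44L)
  expect_true(w3$truncated)
  expect_false(w$truncated)
  # a site absent from every expressed isoform is an error
  al3 <- aligned
  al3[, 300:319] <- NA
  expect_error(common50mer(mt, 300, aligned = al3), "absent")
})

test_that("poly(A) calling reproduces the hand-worked consolidation", {
  tags <- data.frame(gene_id = "g",
                     position = c(100L, 101L, 500L),
                     count = c(60L, 30L, 10L),
                     terminal_a_run = c(5L, 2L, 6L))
  pas <- callPolyASites(tags)
  expect_equal(nrow(pas), 2L)
  expect_equal(pas$position, c(100L, 500L))
  expect_equal(pas$fraction, c(0.90, 0.10))
  expect_true(all(pas$qualified))
  # insufficient terminal-A evidence disqualifies
  one <- data.frame(position = 50L, count = 100L, terminal_a_run = 3L)
  p1 <- callPolyASites(one)
  expect_false(p1$qualified)
  # all tags at one A-evidenced position: one site, fraction 1
  p2 <- callPolyASites(data.frame(position = 50L, count = 10L,
                                  terminal_a_run = 4L))
  expect_equal(p2$fraction, 1)
  expect_true(p2$qualified)
  expect_equal(nrow(callPolyASites(one[0, ])), 0L)
  # threshold-first consolidation agrees here
  expect_equal(callPolyASites(tags, mode = "threshold_first")$fraction,
               c(0.90, 0.10))
})

test_that("qualified fractions sum to at most 1 on random tag tables", {
  set.seed(9)
  for (i in 1:10) {
    tt <- data.frame(position = sort(sample(1:3000, 50)),
                     count = rpois(50, 20),
                     terminal_a_run = sample(0:8, 50, replace = TRUE))
    pas <- callPolyASites(tt)
    expect_lte(sum(pas$fraction[pas$qualified]), 1 + 1e-12)
    expect_lte(sum(pas$fraction), 1 + 1e-12)
  }
})

test_that("planted usage fractions are recovered within 0.05 at 10k tags", {
  cfg <- simConfig(usage_fractions = c(0.7, 0.3))
  g <- simulateGenes(cfg, seed = 22)$G1
  tags <- simulateTags(g, n_tags = 10000, seed = 23)
  pas <- callPolyASites(tags)
  q <- pas[pas$qualified, ]
  expect_equal(nrow(q), 2L)
  expect_true(all(abs(sort(q$fraction) - c(0.3, 0.7)) <= 0.05))
  expect_true(all(abs(sort(q$position) - sort(g$pas$position)) <= 5))
})

test_that("unexpressed-site flags follow isoform presence and PAS rules", {
  aligned <- matrix("A", nrow = 2, ncol = 200,
                    dimnames = list(c("I1", "I2"), NULL))
  aligned["I1", 101:140] <- NA   # exon present only in minor isoform I2
  fr <- c(I1 = 0.98, I2 = 0.02)
  fl <- flagUnexpressedTargets(c(10L, 110L), aligned, fr,
                               qualified_pas = 190L)
  expect_true(fl$expressed[fl$start == 10])
  expect_false(fl$expressed[fl$start == 110])
  expect_equal(fl$reason[fl$start == 110], "absent_isoforms")
  # downstream of the 3'-most qualified PAS
  fl2 <- flagUnexpressedTargets(c(150L, 181L), aligned, fr,
                                qualified_pas = 180L)
  expect_true(fl2$expressed[fl2$start == 150])
  expect_false(fl2$expressed[fl2$start == 181])
  expect_equal(fl2$reason[fl2$start == 181], "downstream_of_pas")
  # never flags a site present in all isoforms upstream of all PAS
  fl3 <- flagUnexpressedTargets(c(5L, 50L), aligned, fr,
                                qualified_pas = integer(0))
  expect_true(all(fl3$expressed))
})

test_that("translation efficiency is a plain TPM ratio with guards", {
  expect_equal(ribosomeDensity(26, 10), 2.6)
  expect_equal(ribosomeDensity(7, 7), 1)
  expect_error(ribosomeDensity(5, 0), "> 0")
  # round trip through the coverage simulator at TE 0.6
  g <- simulateGenes(simConfig(n_genes = 1), seed = 24)$G1
  cv <- simulateCoverage(g, rna_tpm = 12, translation_efficiency = 0.6,
                         seed = 25)
  expect_equal(ribosomeDensity(cv$tpm$ribo_tpm, cv$tpm$rna_tpm), 0.6)
})

test_that("coverage normalization divides by mapped reads in millions", {
  expect_equal(normalizeCoverage(50, 10e6), 5)
  expect_equal(normalizeCoverage(rep(0, 5), 2e6), rep(0, 5))
  x <- c(10, 20, 30)
  expect_equal(normalizeCoverage(x, 4e6), 2 * normalizeCoverage(x, 8e6))
  expect_error(normalizeCoverage(x, 0), "> 0")
})
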