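test_that("candidate enumeration yields n - L + 1 ordered sites", {
  sq <- randomRnaString(25)
  cand <- enumerateCandidates(sq, gene_id = "g")
  expect_equal(nrow(cand), 6L)
  expect_equal(cand$start, 1:6)
  expect_equal(cand$target_seq, substring(sq, 1:6, 20:25))
  expect_equal(nrow(enumerateCandidates(randomRnaString(20))), 1L)
  expect_warning(none <- enumerateCandidates(randomRnaString(19)),
                 "shorter")
  expect_equal(nrow(none), 0L)
})

test_that("the GC rule excludes at exactly 60 percent", {
  # 12 of 20 G/C fails, 11 of 20 passes
  gc12 <- paste0(strrep("GC", 6), strrep("AU", 4))
  gc11 <- paste0(strrep("GC", 5), "G", strrep("AU", 4), "A")
  stopifnot(gcFraction(gc12) == 0.60, gcFraction(gc11) == 0.55)
  cand <- data.frame(gene_id = "g", site_id = c("s1", "s2"), start = 1:2,
                     target_seq = c(gc12, gc11))
  res <- suppressWarnings(filterCandidates(cand))
  expect_equal(res$report$reason, c("gc_content", NA))
  expect_equal(res$passed$site_id, "s2")
})

test_that("homopolymer stretches are excluded with the right reason", {
  cand <- data.frame(gene_id = "g", site_id = "s1", start = 1,
                     target_seq = "AAGGGGAUAUCUAGCUAGCA")
  res <- suppressWarnings(filterCandidates(cand))
  expect_equal(res$report$reason, "homopolymer")
  # CCCC also trips the rule
  cand$target_seq <- "AACCCCAUAUCUAGCUAGCA"
  res <- suppressWarnings(filterCandidates(cand))
  expect_equal(res$report$reason, "homopolymer")
})

test_that("a planted 16-mer match in another transcript is excluded", {
  set.seed(7)
  target <- "AAUGCAUCGAUCGAAUCGAU"   # GC 8/20, no homopolymer
  core <- substring(target, 4, 19)   # guide positions 2-17
  other <- paste0(randomRnaString(30), core, randomRnaString(30))
  cand <- data.frame(gene_id = "g", site_id = "s1", start = 1,
                     target_seq = target)
  res <- filterCandidates(cand, transcriptome = c(other_gene = other))
  expect_equal(res$report$reason, "off_target_homology")
  # without the planted match the candidate survives
  res2 <- filterCandidates(cand,
                           transcriptome = c(o = randomRnaString(80)))
  expect_true(res2$report$pass)
  # empty transcriptome: homology rule skipped with a warning
  expect_warning(filterCandidates(cand, transcriptome = NULL),
                 "skipped")
})

test_that("the first failing rule is the recorded primary reason", {
  # fails GC (14/20) and contains GGGG: reason must be gc_content
  seq <- "GGGGCGCGCGCGCGAUAUAU"
  cand <- data.frame(gene_id = "g", site_id = "s", start = 1,
                     target_seq = seq)
  res <- suppressWarnings(filterCandidates(cand))
  expect_equal(res$report$reason, "gc_content")
})

test_that("original panel selection follows the every-50th-plus-PAS rule", {
  set.seed(11)
  n <- 300
  non_pas <- data.frame(
    gene_id = "g", site_id = sprintf("np%d", 1:n), start = seq_len(n) * 10,
    target_seq = replicate(n, {
      s <- randomRnaString(20)
      while (grepl("AAUAAA", s)) s <- randomRnaString(20)
      s
    }),
    region = "orf")
  # every-50th rule on 300 remaining sequences yields 6 list entries
  panel0 <- suppressWarnings(
    selectOriginalPanel(non_pas, panel_size = 48, pas_quota = 5))
  expect_equal(sum(!panel0$contains_pas_motif), 6L)
  expect_equal(sum(panel0$contains_pas_motif), 0L)
  expect_warning(
    expect_warning(selectOriginalPanel(non_pas, pas_quota = 5), "AAUAAA"),
    "exhausted")

  # with enough PAS-motif candidates the default panel is 48 with 5 PAS
  pas <- data.frame(
    gene_id = "g", site_id = sprintf("p%d", 1:8), start = 3000 + 1:8,
    target_seq = vapply(1:8, function(i)
      paste0("AAUAAA", randomRnaString(14)), ""),
    region = "three_prime_utr")
  pool <- rbind(non_pas[rep(1:300, 9), ], pas)  # 2700 spaced -> 54 entries
  pool$site_id <- make.unique(pool$site_id)
  pool$start <- seq_len(nrow(pool))
  panel <- selectOriginalPanel(pool, panel_size = 48, pas_quota = 5)
  expect_equal(nrow(panel), 48L)
  expect_equal(sum(panel$contains_pas_motif), 5L)
  expect_equal(unique(panel$design_set), "original")
})

test_that("walk design proposes +/-10 nt starts at 2-nt steps", {
  # oracle: explicit enumeration of the offset set minus the origin
  offs <- setdiff(seq(-10, 10, by = 2), 0)
  w <- designWalk(1000, transcript_length = 5000)
  expect_equal(w, sort(1000 + offs))
  expect_length(w, 10L)
  # boundary clipping at the transcript 5' end
  w2 <- designWalk(5, transcript_length = 5000)
  expect_equal(w2, sort(setdiff(5 + offs, c(5, 5 - 10, 5 - 8, 5 - 6))))
  expect_true(all(w2 >= 1))
  # overlapping hits: union without duplicates, seeds excluded
  w3 <- designWalk(c(100, 104), transcript_length = 5000)
  oracle <- sort(setdiff(unique(c(100 + offs, 104 + offs)), c(100, 104)))
  expect_equal(w3, oracle)
  # every walk candidate lies within 10 nt of some hit
  expect_true(all(vapply(w3, function(s)
    min(abs(s - c(100, 104))) <= 10, TRUE)))
})

test_that("3'UTR-selective design takes every other pre-PAS candidate", {
  surv <- data.frame(gene_id = "g", site_id = sprintf("s%d", 1:10),
                     start = c(seq(100, 170, by = 10), 500, 600),
                     target_seq = replicate(10, randomRnaString(20)),
                     region = c(rep("three_prime_utr", 8), "orf",
                                "three_prime_utr"))
  sel <- designUtrSelective(surv, first_pas_position = 200)
  expect_equal(sel$site_id, c("s1", "s3", "s5", "s7"))
  expect_equal(unique(sel$design_set), "utr_selective")
  # first PAS at the region start leaves nothing
  expect_warning(none <- designUtrSelective(surv, first_pas_position = 100),
                 "no 3'UTR")
  expect_equal(nrow(none), 0L)
  # deterministic given ordered input
  expect_identical(sel, designUtrSelective(surv, 200))
})

test_that("guide strands are reverse complements and involutive", {
  expect_equal(guideFromTarget("AAAAAAAAAAAAAAAAAAAA"),
               "UUUUUUUUUUUUUUUUUUUU")
  expect_equal(guideFromTarget("AUGCAUGCAUGCAUGCAUGC"),
               "GCAUGCAUGCAUGCAUGCAU")
  set.seed(3)
  for (i in 1:10) {
    t <- randomRnaString(20)
    expect_equal(guideFromTarget(guideFromTarget(t)), t)
  }
  expect_error(guideFromTarget("AAAAAAAAAAAAAAAAAAAX"), "position 20")
})

test_that("emitted target sites round-trip against the transcript", {
  st <- sharedStudy()
  g <- st$genes$G1
  sq <- as.character(mergedSeq(g$merged))
  cand <- enumerateCandidates(sq, gene_id = "G1")
  idx <- sample(nrow(cand), 50)
  expect_equal(cand$target_seq[idx],
               substring(sq, cand$start[idx], cand$start[idx] + 19))
})

test_that("scaffold specifications carry the structural contracts", {
  for (nm in c("blunt_omef", "asym_omef", "asym_omerich")) {
    sp <- scaffoldSpec(nm)
    expect_equal(sp$guide_length, 20L)
    expect_true(sp$passenger_length %in% c(15L, 20L))
    expect_equal(substring(sp$guide_mods, 20, 20), "F")
    expect_true(sp$guide_5p_phosphate)
  }
  expect_equal(scaffoldSpec("blunt_omef")$passenger_length, 20L)
  expect_equal(scaffoldSpec("asym_omef")$passenger_length, 15L)
})
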