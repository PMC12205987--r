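test_that("plate normalization follows the blank/norm/untreated formula", {
  # arithmetic oracle: sample ratio 0.5 against untreated mean ratio 1.0
  pct <- normalizePlate(sample_signal = 600, blank_mean = 100,
                        norm_signal = 1100, norm_blank_mean = 100,
                        untreated_ratios = 1.0)
  expect_equal(pct, 100 * ((600 - 100) / (1100 - 100)) / 1.0)
  expect_equal(pct, 50)
  # untreated wells through the same formula average exactly 100
  unt_sig <- c(1100, 900, 1000); blank <- 100
  ratios <- (unt_sig - blank) / (1100 - 100)
  expect_equal(mean(normalizePlate(unt_sig, blank, rep(1100, 3), 100,
                                   ratios)), 100)
  # negative numerator clamps to zero
  expect_warning(z <- normalizePlate(90, 100, 1100, 100, 1), "clamped")
  expect_equal(z, 0)
  # nonpositive normalization denominator invalidates the record
  expect_warning(bad <- normalizePlate(600, 100, 90, 100, 1), "invalid")
  expect_true(is.na(bad))
  expect_error(normalizePlate(600, 100, 1100, 100, numeric(0)),
               "nonempty")
})

test_that("Grubbs decisions match the t-distribution critical formula", {
  # independent oracle for G_crit, coded from the closed form
  gcrit_oracle <- function(n, alpha) {
    t2 <- qt(1 - alpha / (2 * n), n - 2)^2
    (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
  }
  for (n in 3:10) for (a in c(0.05, 0.2))
    expect_equal(grubbsCritical(n, a), gcrit_oracle(n, a),
                 tolerance = 1e-12)
  # decision on (50, 52, 90) matches the oracle at alpha = 0.2
  x <- c(50, 52, 90)
  G <- max(abs(x - mean(x))) / sd(x)
  expect_equal(grubbsFilter(x, 0.2)$flagged, G > gcrit_oracle(3, 0.2))
  expect_true(grubbsFilter(x, 0.2)$flagged)
  expect_equal(grubbsFilter(x, 0.2)$retained, c(50, 52))
  # degenerate inputs: no variance, or too few replicates
  expect_false(grubbsFilter(c(40, 40, 40))$flagged)
  expect_equal(grubbsFilter(c(40, 90))$retained, c(40, 90))
  # at most one value is ever removed
  r <- grubbsFilter(c(10, 11, 12, 90, 95), 0.2)
  expect_gte(length(r$retained), 4L)
})

test_that("summaries cap at 100 before mean and SD", {
  s <- summarizeRecord(c(120, 130, 110))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  expect_true(s$capped)
  s2 <- summarizeRecord(c(30, 40, 50))
  expect_equal(s2$mean, 40)
  expect_equal(s2$sd, 10)
  expect_false(s2$capped)
})

test_that("trichotomous classification has the documented boundaries", {
  th <- labelThresholds()
  expect_equal(classifyHit(35.0, th), "effective")
  expect_equal(classifyHit(35.0001, th), "undefined")
  expect_equal(classifyHit(55.0, th), "undefined")
  expect_equal(classifyHit(55.0001, th), "ineffective")
  expect_equal(classifyHit(70, th), "ineffective")
  # monotone: raising the mean never moves toward effective
  rank <- c(effective = 1, undefined = 2, ineffective = 3)
  set.seed(5)
  a <- runif(500, 0, 100); b <- a + runif(500, 0, 40)
  expect_true(all(rank[classifyHit(b, th)] >= rank[classifyHit(a, th)]))
})

test_that("scaffold pairs classify as permissive/restrictive/other", {
  th <- labelThresholds()
  expect_equal(classifyScaffoldPair(30, 32, th), "permissive")
  expect_equal(classifyScaffoldPair(30, 60, th), "restrictive_A")
  expect_equal(classifyScaffoldPair(60, 30, th), "restrictive_B")
  expect_equal(classifyScaffoldPair(30, 45, th), "other")
  expect_equal(classifyScaffoldPair(30, 50, th), "other")   # > 50 strictly
  expect_equal(classifyScaffoldPair(30, 50.01, th), "restrictive_A")
  # symmetric up to relabeling
  set.seed(6)
  a <- runif(200, 0, 100); b <- runif(200, 0, 100)
  swap <- c(permissive = "permissive", other = "other",
            restrictive_A = "restrictive_B",
            restrictive_B = "restrictive_A")
  expect_equal(unname(swap[classifyScaffoldPair(a, b, th)]),
               classifyScaffoldPair(b, a, th))
})

test_that("hit rates count boundary hits and reject empty input", {
  expect_equal(hitRate(c(10, 20, rep(80, 8))), 20)
  expect_equal(hitRate(c(35, 80)), 50)
  expect_equal(hitRate(rep(60, 5)), 0)
  expect_error(hitRate(numeric(0)), "no records")
})

test_that("Fisher hit-rate comparison agrees with hypergeometric enumeration", {
  expect_equal(compareHitRates(5, 10, 5, 10), 1)
  # 10/10 vs 0/10: the two extreme tables of the hypergeometric
  expect_equal(compareHitRates(10, 10, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(compareHitRates(3, 9, 7, 11), compareHitRates(7, 11, 3, 9))
  expect_error(compareHitRates(0, 0, 1, 5), "empty")
  # brute-force oracle: sum of table probabilities <= the observed one
  oracle <- function(a, nA, b, nB) {
    k <- a + b
    xs <- max(0, k - nB):min(nA, k)
    probs <- dhyper(xs, nA, nB, k)
    sum(probs[probs <= dhyper(a, nA, nB, k) * (1 + 1e-7)])
  }
  for (nA in c(4, 7, 12)) for (nB in c(5, 12))
    for (a in 0:nA) for (b in c(0, nB %/% 2, nB))
      expect_equal(compareHitRates(a, nA, b, nB), oracle(a, nA, b, nB),
                   tolerance = 1e-7)
})

test_that("assay correlation matches the closed-form Pearson sum", {
  x <- c(2.6, 1.6, 1.0, 0.6); y <- c(38, 36, 10, 4)
  dx <- x - mean(x); dy <- y - mean(y)
  oracle <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(assayCorrelation(x, y), oracle, tolerance = 1e-12)
  expect_equal(assayCorrelation(1:5, 1:5 * 2 + 3), 1)
  expect_equal(assayCorrelation(1:5, -(1:5)), -1)
  expect_error(assayCorrelation(c(1, 1, 1), 1:3), "zero variance")
  expect_error(assayCorrelation(1:2, 1:2), "3")
})

test_that("dose-response selection unions the three criteria", {
  rec <- data.frame(
    site_id = rep(c("a", "b", "c", "d", "e"), each = 2),
    scaffold = rep(c("s1", "s2"), 5),
    mean = c(25, 45,    # a: <=30 in s1 -> criterion (a)
             55, 80,    # b: <60 and range 25 -> criterion (c)
             50, 58,    # c: range 8 -> not selected
             70, 90,    # d: range 20 but min 70 (not < 60) -> no
             65, 62))   # e: nothing
  sel <- selectForDoseResponse(rec)
  expect_true(all(c("a", "b") %in% sel))
  expect_false(any(c("c", "d", "e") %in% sel))
  # top-decile rule: best-of-scaffold site with mean <= 40 is selected
  rec2 <- data.frame(site_id = sprintf("s%02d", 1:20), scaffold = "s1",
                     mean = c(32, seq(42, 98, length.out = 19)))
  expect_true("s01" %in% selectForDoseResponse(rec2))
  expect_false("s02" %in% selectForDoseResponse(rec2))
})

test_that("hotspot chaining follows the 50-nt rule with -15/+35 extension", {
  hs <- findHotspots(c(100, 140))
  expect_equal(hs$start, 85L)
  expect_equal(hs$end, 175L)
  expect_equal(hs$n_hits, 2L)
  # a 51-nt gap breaks the chain
  expect_equal(nrow(findHotspots(c(100, 151))), 0L)
  # transitive chaining across three hits
  hs3 <- findHotspots(c(100, 145, 190))
  expect_equal(nrow(hs3), 1L)
  expect_equal(hs3$start, 85L)
  expect_equal(hs3$end, 225L)
  # a single isolated hit never forms a hotspot
  expect_equal(nrow(findHotspots(250)), 0L)
  # clipping to transcript bounds
  hc <- findHotspots(c(5, 30), transcript_length = 70)
  expect_equal(hc$start, 1L)
  expect_equal(hc$end, 65L)
})

test_that("hotspot intervals are disjoint and contain their members", {
  set.seed(8)
  for (i in 1:20) {
    starts <- sort(sample(1:2000, 40))
    hs <- findHotspots(starts, transcript_length = 2100)
    members <- attr(hs, "members")
    if (nrow(hs) > 1)
      expect_true(all(hs$start[-1] > hs$end[-nrow(hs)]))
    for (k in seq_len(nrow(hs)))
      expect_true(all(members[[k]] >= hs$start[k] &
                      members[[k]] <= hs$end[k]))
  }
})

test_that("processScreen recovers truth labels on the shared study", {
  st <- sharedStudy()
  rec <- sharedRecords()
  expect_setequal(unique(rec$assay), c("native", "reporter"))
  # untreated are excluded from records, all panel sites present
  expect_setequal(unique(rec$site_id), st$panel$site_id)
  # with noise SD 10 and 3 replicates, means track truth closely
  tr <- st$truth[st$truth$scaffold == "asym_omef", ]
  nat <- rec[rec$assay == "native" & rec$scaffold == "asym_omef", ]
  m <- nat$mean[match(tr$site_id, nat$site_id)]
  expect_gt(cor(m, pmin(tr$native_truth, 100)), 0.9)
})
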