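# Screen processing: raw plate signals -> percent-of-untreated expression,
# Grubbs outlier QC, capped summaries, trichotomous hit classification,
# scaffold-pair analysis, hit rates, dose-response selection and hotspot
# detection.

#' Classification thresholds
#'
#' @param h1 effective cutoff: mean expression <= `h1` percent.
#' @param h2 ineffective cutoff: mean expression > `h2` percent; values in
#'   `(h1, h2]` are undefined.
#' @param restrictive cutoff for scaffold-pair restrictiveness: a sequence
#'   effective (<= `h1`) in one scaffold and > `restrictive` in the other
#'   is restrictive toward the effective scaffold.
#' @return validated list of thresholds.
#' @export
labelThresholds <- function(h1 = 35, h2 = 55, restrictive = 50) {
  stopifnot(h1 > 0, h2 < 100, h1 < h2,
            restrictive > h1, restrictive < 100)
  list(h1 = h1, h2 = h2, restrictive = restrictive)
}

#' Normalize plate signals to percent of untreated expression
#'
#' `percent = 100 * ((sample - blank_mean) / (norm - norm_blank_mean)) /
#' mean(untreated_ratios)`: blank means are subtracted from both channels,
#' the target signal is divided by the normalization-control signal, and
#' the ratio is expressed as a percentage of the mean untreated ratio.
#' Negative numerators are clamped to 0 with a warning; a nonpositive
#' normalization denominator (cell death / assay failure) yields `NA` with
#' a warning.
#'
#' @param sample_signal raw target-channel signal(s).
#' @param blank_mean mean target-channel signal of blank wells.
#' @param norm_signal raw normalization-channel signal(s), same length.
#' @param norm_blank_mean mean normalization-channel signal of blanks.
#' @param untreated_ratios blank-corrected target/normalization ratios of
#'   untreated wells (nonempty).
#' @return numeric percent expression, `NA` where invalid.
#' @export
normalizePlate <- function(sample_signal, blank_mean, norm_signal,
                           norm_blank_mean, untreated_ratios) {
  if (length(untreated_ratios) == 0L)
    stop("untreated_ratios must be nonempty")
  num <- sample_signal - blank_mean
  if (any(num < 0)) {
    warning("negative blank-corrected signal clamped to 0")
    num <- pmax(num, 0)
  }
  den <- norm_signal - norm_blank_mean
  bad <- den <= 0
  if (any(bad)) warning("nonpositive normalization signal: record invalid")
  out <- 100 * (num / den) / mean(untreated_ratios)
  out[bad] <- NA_real_
  out
}

#' Critical value of the two-sided single-outlier Grubbs test
#'
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t` the upper `alpha / (2n)` quantile of the t distribution on
#' `n - 2` degrees of freedom.
#'
#' @param n number of replicates (>= 3).
#' @param alpha test level.
#' @return critical value of `G = max|x - mean| / sd`.
#' @export
grubbsCritical <- function(n, alpha = 0.2) {
  stopifnot(n >= 3)
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Single-outlier Grubbs filter on replicate values
#'
#' Applies one two-sided Grubbs test and removes at most one value per
#' record. Fewer than three replicates, or zero variance, retains all.
#'
#' @param replicates numeric replicate values.
#' @param alpha test level (screening convention 0.2).
#' @return list with `retained`, `outlier` (removed value or `NA`) and
#'   `flagged` (logical).
#' @export
grubbsFilter <- function(replicates, alpha = 0.2) {
  x <- replicates[!is.na(replicates)]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0)
    return(list(retained = x, outlier = NA_real_, flagged = FALSE))
  dev <- abs(x - mean(x))
  G <- max(dev) / stats::sd(x)
  if (G > grubbsCritical(n, alpha)) {
    i <- which.max(dev)
    list(retained = x[-i], outlier = x[i], flagged = TRUE)
  } else {
    list(retained = x, outlier = NA_real_, flagged = FALSE)
  }
}

#' Summarize post-QC replicates with capping at 100 percent
#'
#' Replicates are capped at 100 before the mean and sample SD are taken;
#' raw values are preserved alongside. Capping only affects values above
#' 100, so it never changes the label of a record with mean <= the
#' ineffective cutoff.
#'
#' @param replicates post-QC replicate percents.
#' @param cap cap value.
#' @return list with `mean`, `sd`, `capped` (any value was capped),
#'   `raw`, `capped_values`.
#' @export
summarizeRecord <- function(replicates, cap = 100) {
  cv <- pmin(replicates, cap)
  list(mean = mean(cv),
       sd = if (length(cv) > 1) stats::sd(cv) else NA_real_,
       capped = any(replicates > cap), raw = replicates,
       capped_values = cv)
}

#' Trichotomous hit classification
#'
#' `<= h1` percent mean expression is `effective`, `> h2` is
#' `ineffective`, values in between are `undefined`. Boundary semantics:
#' exactly `h1` is effective; exactly `h2` is undefined.
#'
#' @param mean_percent mean percent expression (vectorized).
#' @param thresholds [labelThresholds()].
#' @return character vector of labels.
#' @export
classifyHit <- function(mean_percent, thresholds = labelThresholds()) {
  ifelse(mean_percent <= thresholds$h1, "effective",
         ifelse(mean_percent > thresholds$h2, "ineffective", "undefined"))
}

#' Permissive/restrictive classification of a scaffold pair
#'
#' Both means `<= h1`: permissive. One `<= h1` and the other above the
#' restrictive cutoff: restrictive toward the effective scaffold
#' (`restrictive_A` means scaffold A silences, B does not). Anything else
#' is `other`.
#'
#' @param mean_A,mean_B mean percent expression in the two scaffolds
#'   (vectorized).
#' @param thresholds [labelThresholds()].
#' @return character vector among `permissive`, `restrictive_A`,
#'   `restrictive_B`, `other`.
#' @export
classifyScaffoldPair <- function(mean_A, mean_B,
                                 thresholds = labelThresholds()) {
  h1 <- thresholds$h1; rc <- thresholds$restrictive
  out <- rep("other", length(mean_A))
  out[mean_A <= h1 & mean_B <= h1] <- "permissive"
  out[mean_A <= h1 & mean_B > rc] <- "restrictive_A"
  out[mean_B <= h1 & mean_A > rc] <- "restrictive_B"
  out
}

#' Hit rate of a record set
#'
#' @param means mean percent expression values (nonempty).
#' @param cutoff hit cutoff; means `<= cutoff` count as hits.
#' @return hit rate as a percent.
#' @export
hitRate <- function(means, cutoff = 35) {
  means <- means[!is.na(means)]
  if (length(means) == 0L) stop("no records")
  100 * mean(means <= cutoff)
}

#' Compare two hit rates by Fisher's exact test
#'
#' @param hits_A,n_A hits and total in group A.
#' @param hits_B,n_B hits and total in group B.
#' @return two-sided exact p-value.
#' @export
compareHitRates <- function(hits_A, n_A, hits_B, n_B) {
  stopifnot(hits_A >= 0, hits_B >= 0, hits_A <= n_A, hits_B <= n_B)
  if (n_A == 0 || n_B == 0) stop("empty group")
  m <- matrix(c(hits_A, n_A - hits_A, hits_B, n_B - hits_B), nrow = 2)
  stats::fisher.test(m)$p.value
}

#' Pearson correlation of paired assay means
#'
#' @param x_means,y_means paired mean expression vectors (n >= 3).
#' @return Pearson product-moment coefficient.
#' @export
assayCorrelation <- function(x_means, y_means) {
  ok <- stats::complete.cases(x_means, y_means)
  x <- x_means[ok]; y <- y_means[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Select sites for dose-response follow-up
#'
#' Union of (a) sites with mean <= 30 percent in any scaffold, (b) sites
#' in the top decile (lowest expression) of some scaffold with mean <= 40
#' percent, and (c) sites with mean < 60 percent in some scaffold and a
#' cross-scaffold range >= 20 percentage points.
#'
#' @param records data.frame with `site_id`, `scaffold`, `mean`.
#' @return character vector of selected `site_id`s.
#' @export
selectForDoseResponse <- function(records) {
  sel_a <- unique(records$site_id[records$mean <= 30])
  sel_b <- character(0)
  for (sc in unique(records$scaffold)) {
    sub <- records[records$scaffold == sc, ]
    dec <- stats::quantile(sub$mean, 0.10, type = 7)
    sel_b <- c(sel_b, sub$site_id[sub$mean <= dec & sub$mean <= 40])
  }
  rng <- tapply(records$mean, records$site_id,
                function(v) diff(range(v)))
  mn <- tapply(records$mean, records$site_id, min)
  sel_c <- names(rng)[rng >= 20 & mn < 60]
  sort(unique(c(sel_a, sel_b, sel_c)))
}

#' Detect hotspots of effective siRNA start sites
#'
#' Hits are chained transitively while consecutive start sites are within
#' `link_dist` nt; each chain of two or more hits defines a hotspot
#' interval from `upstream` nt before the first start to `downstream` nt
#' after the last start, clipped to the transcript.
#'
#' @param hit_starts start positions of effective siRNAs on one merged
#'   transcript.
#' @param transcript_length transcript length for clipping (default none).
#' @param link_dist maximum nt between chained consecutive starts.
#' @param upstream,downstream interval extension in nt (35 = the 20-nt
#'   site plus a 15-nt flank, matching the 50-mer context window).
#' @return data.frame with `start`, `end`, `n_hits`; member hit starts in
#'   `attr(, "members")` (list of integer vectors). Intervals are
#'   disjoint and each member start lies inside its interval.
#' @export
findHotspots <- function(hit_starts, transcript_length = Inf,
                         link_dist = 50, upstream = 15, downstream = 35) {
  s <- sort(unique(as.integer(hit_starts)))
  if (length(s) < 2)
    return(structure(data.frame(start = integer(0), end = integer(0),
                                n_hits = integer(0)),
                     members = list()))
  grp <- cumsum(c(1L, as.integer(diff(s) > link_dist)))
  chains <- split(s, grp)
  chains <- chains[vapply(chains, length, 0L) >= 2]
  out <- data.frame(
    start = vapply(chains, function(v)
      as.integer(max(1, min(v) - upstream)), 0L),
    end = vapply(chains, function(v)
      as.integer(min(transcript_length, max(v) + downstream)), 0L),
    n_hits = vapply(chains, length, 0L))
  rownames(out) <- NULL
  structure(out, members = unname(chains))
}

#' Process a raw measurement table into efficacy records
#'
#' For each scaffold x assay: blank means are taken from blank wells,
#' untreated ratios from untreated wells, sample wells are normalized to
#' percent of untreated ([normalizePlate()]), replicates pass the Grubbs
#' filter ([grubbsFilter()]), summaries are capped at 100
#' ([summarizeRecord()]) and labels assigned ([classifyHit()]).
#'
#' @param measurements data.frame in the layout of
#'   [readMeasurementTable()] / [simulateScreen()].
#' @param thresholds [labelThresholds()].
#' @param grubbs_alpha Grubbs test level.
#' @return data.frame of efficacy records: `site_id`, `scaffold`,
#'   `assay`, `n_replicates`, `mean`, `sd`, `capped`,
#'   `outlier_removed`, `label`.
#' @export
processScreen <- function(measurements, thresholds = labelThresholds(),
                          grubbs_alpha = 0.2) {
  out <- list()
  for (assay in unique(measurements$assay)) {
    for (sc in unique(measurements$scaffold)) {
      sub <- measurements[measurements$assay == assay &
                          measurements$scaffold == sc, ]
      if (nrow(sub) == 0L) next
      blank <- sub[sub$well_role == "blank", ]
      blank_mean <- mean(blank$signal)
      norm_blank_mean <- mean(blank$norm_signal)
      unt <- sub[sub$well_role == "untreated", ]
      unt_ratio <- (unt$signal - blank_mean) /
        (unt$norm_signal - norm_blank_mean)
      smp <- sub[sub$well_role == "sample", ]
      for (sid in unique(smp$site_id)) {
        w <- smp[smp$site_id == sid, ]
        pct <- normalizePlate(w$signal, blank_mean, w$norm_signal,
                              norm_blank_mean, unt_ratio)
        qc <- grubbsFilter(pct, alpha = grubbs_alpha)
        sm <- summarizeRecord(qc$retained)
        out[[length(out) + 1L]] <- data.frame(
          site_id = sid, scaffold = sc, assay = assay,
          n_replicates = length(qc$retained),
          mean = sm$mean, sd = sm$sd, capped = sm$capped,
          outlier_removed = qc$flagged,
          label = classifyHit(sm$mean, thresholds))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
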