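# Nearest-neighbor stacking thermodynamics along target windows, and
# positional group comparisons: delta-delta-G profiles with per-position
# t-tests (BH-corrected) and nucleotide-frequency shifts with Fisher
# exact tests. Only helix-propagation (stacking) terms are used -- no
# initiation, terminal-AU or dangling-end corrections -- because the
# profiles are positional, one value per adjacent nucleotide pair.

#' Load a dinucleotide stacking energy table
#'
#' The package ships nearest-neighbor Watson-Crick helix-propagation
#' free energies at 37 C (kcal/mol) in
#' `inst/extdata/stacking_dg37.tsv`; any TSV with columns
#' `dinucleotide` and `dg37_kcal_mol` covering all 16 RNA dinucleotides
#' can be substituted.
#'
#' @param path TSV file; default is the shipped table.
#' @return named numeric vector of length 16.
#' @export
energyTable <- function(path = system.file("extdata", "stacking_dg37.tsv",
                                           package = "siRNAscreen")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  et <- stats::setNames(df$dg37_kcal_mol, df$dinucleotide)
  need <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
  missing <- setdiff(need, names(et))
  if (length(missing))
    stop("energy table missing dinucleotide(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(et[need]))) stop("energy table has non-finite values")
  et[need]
}

#' Positional stacking energy profile of a sequence
#'
#' Assigns a stacking free energy to each adjacent nucleotide pair
#' (1-2, 2-3, ..., (L-1)-L), indexed by the first position of the pair.
#' Pairs touching a `?` (isoform-discordant position) are missing.
#' The profile sums to the total stacking free energy of the window.
#'
#' @param seq RNA string over `A,C,G,U,?` of length >= 2.
#' @param table energy table from [energyTable()].
#' @return numeric vector of length `nchar(seq) - 1`; `NA` at missing
#'   pairs.
#' @export
stackingProfile <- function(seq, table = energyTable()) {
  seq <- rnaFromInput(seq)
  L <- nchar(seq)
  stopifnot(L >= 2)
  ch <- strsplit(seq, "")[[1]]
  if (any(ch == "N")) stop("N not allowed in stacking profiles")
  pairs <- paste0(ch[-L], ch[-1])
  out <- rep(NA_real_, L - 1L)
  ok <- !grepl("\\?", pairs)
  out[ok] <- table[pairs[ok]]
  unname(out)
}

#' Positional delta-delta-G comparison of two sequence groups
#'
#' For each group the mean stacking energy at each pair position is taken
#' over non-missing values; the difference of group means
#' (`ddg = mean_A - mean_B`) is reported per position together with a
#' per-position two-sample t-test and Benjamini-Hochberg correction
#' across positions. The comparison is antisymmetric under swapping the
#' groups.
#'
#' @param seqs_A,seqs_B character vectors of same-length sequences over
#'   `A,C,G,U,?`.
#' @param table energy table.
#' @param welch use the unequal-variance (Welch) t-test; `FALSE` pools
#'   variances.
#' @return data.frame with `position`, `mean_A`, `mean_B`, `ddg`,
#'   `p_raw`, `p_bh`; p-values are `NA` where a group has fewer than two
#'   non-missing values.
#' @export
groupDdg <- function(seqs_A, seqs_B, table = energyTable(),
                     welch = TRUE) {
  stopifnot(length(seqs_A) >= 1, length(seqs_B) >= 1)
  lens <- nchar(c(seqs_A, seqs_B))
  if (length(unique(lens)) != 1L)
    stop("all sequences must have the same length")
  profA <- do.call(rbind, lapply(seqs_A, stackingProfile, table = table))
  profB <- do.call(rbind, lapply(seqs_B, stackingProfile, table = table))
  P <- ncol(profA)
  res <- lapply(seq_len(P), function(i) {
    a <- profA[, i][!is.na(profA[, i])]
    b <- profB[, i][!is.na(profB[, i])]
    p <- if (length(a) < 2 || length(b) < 2) NA_real_
    else if (stats::sd(a) > 0 || stats::sd(b) > 0)
      stats::t.test(a, b, var.equal = !welch)$p.value
    else if (a[1] == b[1]) 1
    else NA_real_
    c(mean_A = mean(a), mean_B = mean(b), p_raw = p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(position = seq_len(P),
                    mean_A = res[, "mean_A"], mean_B = res[, "mean_B"],
                    ddg = res[, "mean_A"] - res[, "mean_B"],
                    p_raw = res[, "p_raw"])
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Positional nucleotide-frequency shifts between two groups
#'
#' Per position and base, the frequency difference
#' `freq_A - freq_B` over non-`?` observations, with a two-sided Fisher
#' exact p-value from the 2x2 table (base vs not-base, group A vs B).
#' Frequency differences at a position sum to zero across the four
#' bases.
#'
#' @param seqs_A,seqs_B character vectors of same-length sequences.
#' @return data.frame with `position`, `base`, `freq_A`, `freq_B`,
#'   `dfreq`, `p_fisher`.
#' @export
frequencyShift <- function(seqs_A, seqs_B) {
  lens <- nchar(c(seqs_A, seqs_B))
  if (length(unique(lens)) != 1L)
    stop("all sequences must have the same length")
  L <- lens[1]
  chA <- do.call(rbind, strsplit(vapply(seqs_A, rnaFromInput, "",
                                        USE.NAMES = FALSE), ""))
  chB <- do.call(rbind, strsplit(vapply(seqs_B, rnaFromInput, "",
                                        USE.NAMES = FALSE), ""))
  out <- list()
  for (i in seq_len(L)) {
    a <- chA[, i]; a <- a[a %in% RNA_BASES]
    b <- chB[, i]; b <- b[b %in% RNA_BASES]
    for (base in RNA_BASES) {
      ka <- sum(a == base); kb <- sum(b == base)
      p <- if (length(a) && length(b))
        stats::fisher.test(matrix(c(ka, length(a) - ka,
                                    kb, length(b) - kb), nrow = 2))$p.value
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        position = i, base = base,
        freq_A = if (length(a)) ka / length(a) else NA_real_,
        freq_B = if (length(b)) kb / length(b) else NA_real_,
        p_fisher = p)
    }
  }
  res <- do.call(rbind, out)
  res$dfreq <- res$freq_A - res$freq_B
  res[c("position", "base", "freq_A", "freq_B", "dfreq", "p_fisher")]
}
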