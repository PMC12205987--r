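# Target mRNA context: merged transcripts from isoform annotation, region
# assignment, isoform consensus and 50-mer windows, poly(A)-site calling
# from 3'-end tag tables, expressed/unexpressed site flags, translation
# efficiency and coverage normalization.

# map genomic positions to merged-transcript coordinates
genomicToTranscript <- function(blocks, pos) {
  starts <- IRanges::start(blocks)
  ends <- IRanges::end(blocks)
  offs <- cumsum(c(0L, IRanges::width(blocks)))[seq_along(starts)]
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(starts)) {
    inb <- pos >= starts[i] & pos <= ends[i]
    out[inb] <- offs[i] + pos[inb] - starts[i] + 1L
  }
  out
}

#' Merge isoform exon sets into one transcript
#'
#' Overlapping exons across isoforms are widened to their most extreme
#' start/end, the merged blocks are ordered 5'->3' and their sequences
#' concatenated into a single merged transcript. The operation is
#' idempotent and independent of isoform input order. Region annotations
#' present in the table are applied via [assignRegions()].
#'
#' @param annotation GTF-like data.frame ([readAnnotationTable()] layout)
#'   for one gene; rows of other genes are ignored when `gene_id` given.
#' @param genome_seq the reference sequence the coordinates index into
#'   (character or [Biostrings::RNAString]); for single-gene annotations
#'   this is typically the gene's locus sequence.
#' @param gene_id gene to merge (defaults to the table's first).
#' @return [MergedTranscript-class] with regions assigned when annotated.
#' @export
mergeIsoforms <- function(annotation, genome_seq, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- annotation$gene_id[1]
  ann <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no annotation rows for gene ", gene_id)
  if ("strand" %in% names(ann) && length(unique(ann$strand)) > 1L)
    stop("conflicting strands for gene ", gene_id)
  ex <- ann[ann$feature == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon rows for gene ", gene_id)
  blocks <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
  sq <- rnaFromInput(as.character(genome_seq), allow_ambiguous = FALSE)
  pieces <- substring(sq, IRanges::start(blocks), IRanges::end(blocks))
  mt <- MergedTranscript(gene_id, paste(pieces, collapse = ""),
                         blocks = blocks)
  assignRegions(mt, ann)
}

#' Assign 5'UTR/ORF/3'UTR extents on the merged transcript
#'
#' Each region's extent spans the most extreme annotated start/end across
#' isoforms, converted from genomic to merged-transcript coordinates.
#' A missing ORF annotation leaves regions unset with a warning.
#'
#' @param merged [MergedTranscript-class].
#' @param annotation GTF-like data.frame with region feature rows.
#' @return the transcript with its `regions` slot populated.
#' @export
assignRegions <- function(merged, annotation) {
  ann <- annotation[annotation$gene_id == geneId(merged), , drop = FALSE]
  feats <- c("five_prime_utr", "orf", "three_prime_utr")
  present <- intersect(feats, unique(ann$feature))
  if (!"orf" %in% present) {
    warning("no ORF annotation for ", geneId(merged),
            ": regions left unknown")
    return(merged)
  }
  st <- en <- integer(0)
  for (f in present) {
    rows <- ann[ann$feature == f, ]
    st <- c(st, genomicToTranscript(exonBlocks(merged), min(rows$start)))
    en <- c(en, genomicToTranscript(exonBlocks(merged), max(rows$end)))
  }
  if (anyNA(st) || anyNA(en))
    stop("region boundary outside merged exon blocks for ",
         geneId(merged))
  merged@regions <- stats::setNames(IRanges::IRanges(st, en), present)
  methods::validObject(merged)
  merged
}

#' Region of transcript positions
#'
#' Assigns positions to 5'UTR/ORF/3'UTR by containment, with ties at
#' shared boundaries resolved in 5'->3' priority (a site starting exactly
#' at the ORF/3'UTR boundary is ORF).
#'
#' @param merged [MergedTranscript-class] with regions assigned.
#' @param positions 1-based transcript positions (a site's start).
#' @return character vector of region names (or `"unknown"`).
#' @export
regionOfPosition <- function(merged, positions) {
  reg <- regionBounds(merged)
  out <- rep("unknown", length(positions))
  for (nm in rev(intersect(c("five_prime_utr", "orf", "three_prime_utr"),
                           names(reg)))) {
    r <- reg[nm]
    inr <- positions >= IRanges::start(r) & positions <= IRanges::end(r)
    out[inr] <- nm
  }
  out
}

#' Align isoform sequences onto merged-transcript coordinates
#'
#' @param annotation GTF-like data.frame with per-isoform exon rows.
#' @param isoform_seqs named character vector (or RNAStringSet) of
#'   isoform sequences, concatenated exons 5'->3'.
#' @param merged [MergedTranscript-class] of the same gene.
#' @return character matrix (isoform x merged position); `NA` where the
#'   isoform lacks the position.
#' @export
alignIsoforms <- function(annotation, isoform_seqs, merged) {
  ann <- annotation[annotation$gene_id == geneId(merged) &
                    annotation$feature == "exon", , drop = FALSE]
  isos <- unique(ann$isoform_id)
  L <- mergedLength(merged)
  mat <- matrix(NA_character_, nrow = length(isos), ncol = L,
                dimnames = list(isos, NULL))
  for (iso in isos) {
    ex <- ann[ann$isoform_id == iso, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    sq <- strsplit(as.character(isoform_seqs[[iso]]), "")[[1]]
    if (length(sq) != sum(ex$end - ex$start + 1L))
      stop("isoform ", iso, " sequence length does not match its exons")
    off <- 0L
    for (j in seq_len(nrow(ex))) {
      w <- ex$end[j] - ex$start[j] + 1L
      tpos <- genomicToTranscript(exonBlocks(merged),
                                  ex$start[j]:ex$end[j])
      mat[iso, tpos] <- sq[(off + 1L):(off + w)]
      off <- off + w
    }
  }
  mat
}

#' Consensus across expressed isoforms
#'
#' Positions where expressed isoforms (those carrying at least
#' `min_fraction` of gene expression) disagree are marked `"?"`;
#' positions covered by no expressed isoform are also `"?"`.
#'
#' @param merged [MergedTranscript-class].
#' @param aligned matrix from [alignIsoforms()].
#' @param fractions named per-isoform expression fractions.
#' @param min_fraction expression threshold for "prominently expressed".
#' @return the transcript with its consensus slot populated.
#' @export
consensusFromAligned <- function(merged, aligned, fractions,
                                 min_fraction = 0.05) {
  keep <- names(fractions)[fractions >= min_fraction]
  keep <- intersect(rownames(aligned), keep)
  if (length(keep) == 0L) stop("no isoform reaches min_fraction")
  sub <- aligned[keep, , drop = FALSE]
  cons <- apply(sub, 2, function(col) {
    v <- unique(col[!is.na(col)])
    if (length(v) == 1L) v else "?"
  })
  merged@consensus <- paste(cons, collapse = "")
  methods::validObject(merged)
  merged
}

#' Extract the 50-mer common region around a target site
#'
#' The window spans 15 nt on either side of the 20-mer target
#' (`[start - 15, start + 34]`), read from the transcript's consensus so
#' isoform-discordant positions appear as `"?"`. Windows truncated at
#' transcript ends are flagged.
#'
#' @param merged [MergedTranscript-class] with a consensus (see
#'   [consensusFromAligned()]); without one the merged sequence is used.
#' @param site_start 1-based start of the 20-nt target.
#' @param flank flank width in nt.
#' @param site_length target length in nt.
#' @param aligned optional [alignIsoforms()] matrix with attribute-free
#'   expressed rows only; when given, a site absent from every row is an
#'   error.
#' @return list with `window` (character, `?` at discordant positions),
#'   `start`, `end`, `truncated`.
#' @export
common50mer <- function(merged, site_start, flank = 15, site_length = 20,
                        aligned = NULL) {
  L <- mergedLength(merged)
  stopifnot(site_start >= 1, site_start + site_length - 1L <= L)
  if (!is.null(aligned)) {
    site_cols <- site_start:(site_start + site_length - 1L)
    if (all(is.na(aligned[, site_cols])))
      stop("site at ", site_start, " absent from all expressed isoforms")
  }
  cs <- consensusSeq(merged)
  src <- if (length(cs) == 1L && nzchar(cs)) cs
         else as.character(mergedSeq(merged))
  ws <- max(1L, site_start - flank)
  we <- min(L, site_start + site_length - 1L + flank)
  list(window = substring(src, ws, we), start = ws, end = we,
       truncated = (ws > site_start - flank) ||
                   (we < site_start + site_length - 1L + flank))
}

#' Call poly(A) sites from a 3'-end tag table
#'
#' Tag positions are consolidated greedily from the highest-count
#' position outward: a position within `window` nt of an already-founded
#' site merges into it, otherwise it founds a new site whose
#' representative is that (max-count) position. A consolidated site is
#' qualified when its merged tags represent at least `min_fraction` of
#' the gene's tags and at least one merged position carries a terminal 3'
#' adenosine run of `min_terminal_A` or more. With
#' `mode = "threshold_first"` only positions individually at or above
#' `min_fraction` are considered before consolidation.
#'
#' @param tag_table data.frame with `position`, `count`,
#'   `terminal_a_run` (and optionally `gene_id`).
#' @param min_fraction minimum fraction of gene tags.
#' @param window consolidation window in nt.
#' @param min_terminal_A minimum terminal adenosine run length.
#' @param mode consolidation order (see Details).
#' @return data.frame with `position` (representative), `count`
#'   (consolidated), `fraction`, `has_terminal_a`, `qualified`, sorted by
#'   position; empty input gives an empty result. Qualified-site
#'   fractions sum to at most 1.
#' @export
callPolyASites <- function(tag_table, min_fraction = 0.10, window = 20,
                           min_terminal_A = 4,
                           mode = c("merge_first", "threshold_first")) {
  mode <- match.arg(mode)
  empty <- data.frame(position = integer(0), count = integer(0),
                      fraction = numeric(0), has_terminal_a = logical(0),
                      qualified = logical(0))
  if (nrow(tag_table) == 0L) return(empty)
  total <- sum(tag_table$count)
  if (total == 0L) return(empty)
  tt <- tag_table
  if (mode == "threshold_first")
    tt <- tt[tt$count / total >= min_fraction, , drop = FALSE]
  if (nrow(tt) == 0L) return(empty)
  tt <- tt[order(-tt$count, tt$position), , drop = FALSE]
  reps <- integer(0)
  assign <- integer(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    p <- tt$position[i]
    near <- which(abs(reps - p) <= window)
    if (length(near)) {
      assign[i] <- near[1]
    } else {
      reps <- c(reps, p)
      assign[i] <- length(reps)
    }
  }
  out <- do.call(rbind, lapply(seq_along(reps), function(k) {
    m <- tt[assign == k, , drop = FALSE]
    cnt <- sum(m$count)
    data.frame(position = reps[k], count = cnt,
               fraction = cnt / total,
               has_terminal_a = any(m$terminal_a_run >= min_terminal_A))
  }))
  out$qualified <- out$fraction >= min_fraction & out$has_terminal_a
  if ("gene_id" %in% names(tag_table))
    out <- cbind(gene_id = tag_table$gene_id[1], out)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag panel sites that target unexpressed regions
#'
#' A site is unexpressed when (a) its 20-mer is absent from every isoform
#' carrying at least `min_fraction` of gene expression, or (b) its start
#' lies downstream of the 3'-most qualified poly(A) site. A site present
#' in all isoforms and upstream of all poly(A) sites is never flagged.
#'
#' @param site_starts 1-based site starts on the merged transcript.
#' @param aligned matrix from [alignIsoforms()].
#' @param fractions named per-isoform expression fractions.
#' @param qualified_pas positions of qualified poly(A) sites (possibly
#'   empty).
#' @param min_fraction expression threshold for "prominently expressed".
#' @param site_length site length in nt.
#' @return data.frame with `start`, `expressed`, `reason` (`NA`,
#'   `absent_isoforms` or `downstream_of_pas`).
#' @export
flagUnexpressedTargets <- function(site_starts, aligned, fractions,
                                   qualified_pas = integer(0),
                                   min_fraction = 0.05, site_length = 20) {
  keep <- names(fractions)[fractions >= min_fraction]
  keep <- intersect(rownames(aligned), keep)
  last_pas <- if (length(qualified_pas)) max(qualified_pas) else Inf
  res <- lapply(as.integer(site_starts), function(s) {
    cols <- s:(s + site_length - 1L)
    present <- any(apply(!is.na(aligned[keep, cols, drop = FALSE]), 1, all))
    if (!present) return(list(FALSE, "absent_isoforms"))
    if (s > last_pas) return(list(FALSE, "downstream_of_pas"))
    list(TRUE, NA_character_)
  })
  data.frame(start = as.integer(site_starts),
             expressed = vapply(res, function(r) r[[1]], TRUE),
             reason = vapply(res, function(r) r[[2]], ""))
}

#' Translation efficiency (ribosome density)
#'
#' @param ribo_tpm ribosome-profiling TPM.
#' @param rna_tpm RNA-seq TPM (> 0).
#' @return `ribo_tpm / rna_tpm`.
#' @export
ribosomeDensity <- function(ribo_tpm, rna_tpm) {
  if (any(rna_tpm <= 0)) stop("rna_tpm must be > 0")
  ribo_tpm / rna_tpm
}

#' Normalize per-base coverage by sequencing depth
#'
#' Divides each per-base count by the total mapped reads in millions.
#'
#' @param per_base_counts numeric counts.
#' @param total_mapped_reads total mapped reads (> 0).
#' @return normalized track (reads per million).
#' @export
normalizeCoverage <- function(per_base_counts, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  per_base_counts / (total_mapped_reads / 1e6)
}
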