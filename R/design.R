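# Target-site enumeration, filtering and the three panel-selection
# strategies. Coordinates are 1-based inclusive on the merged transcript;
# a site's start is its 5'-most target nucleotide, and the guide strand is
# the 20-nt reverse complement of the target.

#' Enumerate all candidate 20-nt target sites of a transcript
#'
#' @param transcript_seq merged transcript sequence (character or
#'   [Biostrings::RNAString]).
#' @param site_length site length in nt.
#' @param gene_id identifier used in `site_id`s.
#' @return data.frame with `gene_id`, `site_id`, `start`, `target_seq`,
#'   one row per possible site in 5'->3' order
#'   (`length - site_length + 1` rows); zero rows with a warning when the
#'   transcript is shorter than `site_length`.
#' @export
enumerateCandidates <- function(transcript_seq, site_length = 20,
                                gene_id = "gene") {
  sq <- rnaFromInput(as.character(transcript_seq), allow_ambiguous = FALSE)
  L <- nchar(sq)
  if (L < site_length) {
    warning("transcript shorter than site length (", L, " < ",
            site_length, " nt)")
    return(data.frame(gene_id = character(0), site_id = character(0),
                      start = integer(0), target_seq = character(0)))
  }
  starts <- seq_len(L - site_length + 1L)
  data.frame(gene_id = gene_id,
             site_id = sprintf("%s_%d", gene_id, starts),
             start = starts,
             target_seq = substring(sq, starts, starts + site_length - 1L))
}

#' Filter candidate sites by GC content, homopolymers and off-target
#' homology
#'
#' Rules, applied in fixed order with the first failing rule recorded as
#' the primary reason:
#' \enumerate{
#'   \item `gc_content`: GC fraction of the 20-mer >= 0.60 (so 12/20
#'     fails, 11/20 passes);
#'   \item `homopolymer`: the target contains `CCCC` or `GGGG`;
#'   \item `off_target_homology`: the 16-mer at target positions 4--19
#'     (complementary to guide positions 2--17) occurs exactly, in sense
#'     orientation, in any other gene's transcript.
#' }
#'
#' @param candidates data.frame from [enumerateCandidates()].
#' @param transcriptome sequences of \emph{other} genes (named character
#'   vector or [Biostrings::RNAStringSet]); `NULL` or empty skips the
#'   homology rule with a warning.
#' @param gc_max exclusive upper bound on allowed GC fraction.
#' @return list with `passed` (surviving candidate rows) and `report`
#'   (all candidates with `pass` flag and `reason` among
#'   `gc_content`, `homopolymer`, `off_target_homology`, or `NA`).
#' @export
filterCandidates <- function(candidates, transcriptome = NULL,
                             gc_max = 0.60) {
  if (is.null(transcriptome) || length(transcriptome) == 0L) {
    warning("empty transcriptome: off-target homology filter skipped")
    other <- character(0)
  } else {
    other <- as.character(transcriptome)
  }
  reason <- rep(NA_character_, nrow(candidates))
  gc <- vapply(candidates$target_seq, gcFraction, 0, USE.NAMES = FALSE)
  reason[is.na(reason) & gc >= gc_max] <- "gc_content"
  homo <- grepl("CCCC|GGGG", candidates$target_seq)
  reason[is.na(reason) & homo] <- "homopolymer"
  if (length(other)) {
    core <- substring(candidates$target_seq, 4L, 19L)
    hit <- vapply(core, function(k) any(grepl(k, other, fixed = TRUE)),
                  TRUE, USE.NAMES = FALSE)
    reason[is.na(reason) & hit] <- "off_target_homology"
  }
  report <- cbind(candidates,
                  data.frame(pass = is.na(reason), reason = reason))
  list(passed = candidates[is.na(reason), , drop = FALSE], report = report)
}

#' Select the primary ("original") screening panel
#'
#' From the filtered candidates, the eligible list is every `spacing`-th
#' remaining sequence plus every sequence containing the poly(A)-signal
#' motif `AAUAAA`. The panel takes `pas_quota` motif-containing sites and
#' fills the remainder with ORF/3'UTR sites from the spaced list in
#' transcript order.
#'
#' @param filtered surviving candidates (data.frame with `target_seq`,
#'   `start` and a `region` column).
#' @param panel_size total panel size.
#' @param pas_quota number of `AAUAAA`-containing sites to include.
#' @param spacing take every `spacing`-th remaining sequence.
#' @return data.frame panel with `contains_pas_motif` and
#'   `design_set = "original"`; fewer motif sites than the quota gives a
#'   warning and takes all available.
#' @export
selectOriginalPanel <- function(filtered, panel_size = 48, pas_quota = 5,
                                spacing = 50) {
  filtered$contains_pas_motif <- grepl("AAUAAA", filtered$target_seq,
                                       fixed = TRUE)
  pas_pool <- filtered[filtered$contains_pas_motif, , drop = FALSE]
  non_pas <- filtered[!filtered$contains_pas_motif, , drop = FALSE]
  spaced_idx <- seq_len(nrow(non_pas))[seq_len(nrow(non_pas)) %% spacing == 0]
  spaced <- non_pas[spaced_idx, , drop = FALSE]
  if ("region" %in% names(spaced))
    spaced <- spaced[spaced$region %in% c("orf", "three_prime_utr"), ,
                     drop = FALSE]
  n_pas <- min(pas_quota, nrow(pas_pool))
  if (n_pas < pas_quota)
    warning("only ", n_pas, " AAUAAA-containing candidates available (",
            pas_quota, " requested)")
  pick_pas <- pas_pool[seq_len(n_pas), , drop = FALSE]
  n_rest <- min(panel_size - n_pas, nrow(spaced))
  if (n_rest < panel_size - n_pas)
    warning("spaced list exhausted: panel has ", n_pas + n_rest,
            " of ", panel_size, " sites")
  pick_rest <- spaced[seq_len(n_rest), , drop = FALSE]
  panel <- rbind(pick_pas, pick_rest)
  panel <- panel[order(panel$start), , drop = FALSE]
  panel$design_set <- "original"
  rownames(panel) <- NULL
  panel
}

#' Candidate start positions for a "walk around hits" panel
#'
#' For each effective site start `s`, proposes new starts at
#' `s - offset_max, ..., s - step, s + step, ..., s + offset_max`
#' (spacing `step` nt), clips to the transcript, removes duplicates and
#' excludes the seeding hit starts themselves. The returned starts are
#' then filtered like any candidate list.
#'
#' @param hit_starts starts of sequences that demonstrated efficacy
#'   (by convention <= 40 percent residual expression in any scaffold).
#' @param transcript_length merged transcript length in nt.
#' @param offset_max maximum offset in nt.
#' @param step offset spacing in nt.
#' @param site_length site length (bounds clipping).
#' @return sorted integer vector of candidate starts.
#' @export
designWalk <- function(hit_starts, transcript_length,
                       offset_max = 10, step = 2, site_length = 20) {
  offs <- c(seq(-offset_max, -step, by = step),
            seq(step, offset_max, by = step))
  starts <- unique(as.vector(outer(as.integer(hit_starts), offs, `+`)))
  starts <- starts[starts >= 1L &
                   starts <= transcript_length - site_length + 1L]
  starts <- setdiff(starts, as.integer(hit_starts))
  sort(starts)
}

#' Select a 3'-UTR-selective panel upstream of the first poly(A) site
#'
#' Restricts filtered candidates to 3'UTR sites ending before the first
#' poly(A) site position, then keeps every other surviving sequence
#' (1st, 3rd, 5th, ...).
#'
#' @param filtered surviving candidates with `start` and `region` columns.
#' @param first_pas_position 1-based position of the first (5'-most)
#'   poly(A) site on the merged transcript.
#' @param site_length site length in nt.
#' @return data.frame panel with `design_set = "utr_selective"`; empty
#'   with a warning when no candidate fits the region.
#' @export
designUtrSelective <- function(filtered, first_pas_position,
                               site_length = 20) {
  sel <- filtered[filtered$region == "three_prime_utr" &
                  filtered$start + site_length - 1L < first_pas_position, ,
                  drop = FALSE]
  sel <- sel[order(sel$start), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no 3'UTR candidates before the first poly(A) site")
  } else {
    sel <- sel[seq(1L, nrow(sel), by = 2L), , drop = FALSE]
  }
  sel$design_set <- rep("utr_selective", nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Guide strand from a target sequence
#'
#' The guide (antisense) strand is the reverse complement of the 20-nt
#' target; applying the function twice returns the original target.
#'
#' @param target_seq 20-nt RNA target sequence.
#' @return 20-nt guide sequence (character).
#' @examples
#' guideFromTarget("AAAAAAAAAAAAAAAAAAAA")
#' @export
guideFromTarget <- function(target_seq) {
  revCompRna(target_seq)
}

#' Scaffold specifications
#'
#' The three duplex scaffolds screened: all carry 20-nt guide strands with
#' a 5'-phosphate and a 2'-F at guide position 20; passenger strands are
#' 20 nt (blunt) or 15 nt (asymmetric). Per-position modification codes
#' (`M` = 2'-O-methyl, `F` = 2'-fluoro) and phosphorothioate-linkage
#' positions are carried as annotation only -- they identify the scaffold
#' in downstream grouping and never alter sequence computations.
#'
#' @param name one of `"blunt_omef"`, `"asym_omef"`, `"asym_omerich"`.
#' @return list with `name`, `label`, `guide_length`, `passenger_length`,
#'   `guide_mods`, `passenger_mods`, `ps_positions`,
#'   `guide_5p_phosphate`.
#' @export
scaffoldSpec <- function(name = c("blunt_omef", "asym_omef",
                                  "asym_omerich")) {
  name <- match.arg(name)
  base <- switch(name,
    blunt_omef = list(label = "Blunt 2'-OMe/-F", passenger_length = 20L,
                      guide_f = c(2, 6, 10, 14, 16, 20)),
    asym_omef = list(label = "Asymmetric 2'-OMe/-F", passenger_length = 15L,
                     guide_f = c(2, 6, 10, 14, 16, 20)),
    asym_omerich = list(label = "Asymmetric 2'-OMe Rich",
                        passenger_length = 15L, guide_f = c(2, 14, 20)))
  gm <- rep("M", 20L); gm[base$guide_f] <- "F"
  pm <- rep("M", base$passenger_length)
  pm[intersect(c(5, 7, 9, 11), seq_len(base$passenger_length))] <-
    if (name == "asym_omerich") "M" else "F"
  list(name = name, label = base$label, guide_length = 20L,
       passenger_length = base$passenger_length,
       guide_mods = paste(gm, collapse = ""),
       passenger_mods = paste(pm, collapse = ""),
       ps_positions = list(guide = c(1L, 2L, 19L, 20L),
                           passenger = c(1L, 2L,
                                         base$passenger_length - 1L,
                                         base$passenger_length)),
       guide_5p_phosphate = TRUE)
}
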