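#' MergedTranscript: union-of-isoforms transcript model
#'
#' A `MergedTranscript` represents one gene's mRNA positions as a single
#' merged "transcript": the union of all expressed isoforms' exons, with
#' overlapping exons widened to their most extreme start/end, concatenated
#' 5'->3'. Region boundaries (5'UTR / ORF / 3'UTR) likewise span the most
#' extreme annotated extents across isoforms. An optional per-position
#' consensus string marks positions where expressed isoforms disagree
#' with `"?"`.
#'
#' @slot geneId single gene identifier.
#' @slot sequence [Biostrings::RNAString] of the merged transcript.
#' @slot blocks [IRanges::IRanges] of merged exon blocks in genomic
#'   coordinates (1-based inclusive), ordered 5'->3'.
#' @slot regions named [IRanges::IRanges] with entries `five_prime_utr`,
#'   `orf`, `three_prime_utr` in merged-transcript coordinates; entries may
#'   be absent when unannotated.
#' @slot consensus single character string, same length as `sequence`, over
#'   `A,C,G,U,?`; zero-length string when no consensus was computed.
#'
#' @seealso [mergeIsoforms()], [assignRegions()], [common50mer()]
#' @export
setClass("MergedTranscript",
  representation(
    geneId    = "character",
    sequence  = "RNAString",
    blocks    = "IRanges",
    regions   = "IRanges",
    consensus = "character"
  )
)

setValidity("MergedTranscript", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L)
    msg <- c(msg, "geneId must be a single identifier")
  if (sum(IRanges::width(object@blocks)) != length(object@sequence))
    msg <- c(msg, "sequence length must equal the summed exon block widths")
  if (length(object@blocks) > 1L) {
    s <- IRanges::start(object@blocks)
    e <- IRanges::end(object@blocks)
    if (any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exon blocks must be non-overlapping and ordered 5'->3'")
  }
  if (length(object@regions) > 0L) {
    if (is.null(names(object@regions)) ||
        !all(names(object@regions) %in%
             c("five_prime_utr", "orf", "three_prime_utr")))
      msg <- c(msg, "regions must be named five_prime_utr/orf/three_prime_utr")
    if (any(IRanges::start(object@regions) < 1L) ||
        any(IRanges::end(object@regions) > length(object@sequence)))
      msg <- c(msg, "regions must lie within the merged transcript")
  }
  cs <- object@consensus
  if (length(cs) != 1L && length(cs) != 0L)
    msg <- c(msg, "consensus must be a single string (or empty)")
  if (length(cs) == 1L && nzchar(cs) && nchar(cs) != length(object@sequence))
    msg <- c(msg, "consensus string must match the sequence length")
  if (length(msg)) msg else TRUE
})

#' Construct a MergedTranscript
#'
#' @param geneId gene identifier.
#' @param sequence merged transcript sequence ([Biostrings::RNAString] or
#'   character; `T` is transliterated to `U`).
#' @param blocks [IRanges::IRanges] of merged exon blocks (genomic,
#'   1-based inclusive). Defaults to one block covering the sequence.
#' @param regions named [IRanges::IRanges] of region extents in transcript
#'   coordinates (`five_prime_utr`, `orf`, `three_prime_utr`).
#' @param consensus optional per-position consensus string with `"?"` at
#'   isoform-discordant positions.
#' @return a [MergedTranscript-class] object.
#' @examples
#' mt <- MergedTranscript("G1", "AUGGCUAAUAAAGC")
#' mergedLength(mt)
#' @export
MergedTranscript <- function(geneId, sequence,
                             blocks = NULL, regions = NULL,
                             consensus = character(0)) {
  if (is.character(sequence)) sequence <- Biostrings::RNAString(rnaFromInput(sequence))
  if (is.null(blocks)) blocks <- IRanges::IRanges(1L, length(sequence))
  if (is.null(regions)) regions <- IRanges::IRanges()
  methods::new("MergedTranscript",
    geneId = as.character(geneId), sequence = sequence,
    blocks = blocks, regions = regions,
    consensus = as.character(consensus))
}

#' @describeIn MergedTranscript-class gene identifier accessor
#' @param object,x a `MergedTranscript`
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname MergedTranscript-class
#' @export
setMethod("geneId", "MergedTranscript", function(x) x@geneId)

#' @describeIn MergedTranscript-class merged sequence accessor
#' @export
setGeneric("mergedSeq", function(x) standardGeneric("mergedSeq"))

#' @rdname MergedTranscript-class
#' @export
setMethod("mergedSeq", "MergedTranscript", function(x) x@sequence)

#' @describeIn MergedTranscript-class merged exon blocks (genomic coords)
#' @export
setGeneric("exonBlocks", function(x) standardGeneric("exonBlocks"))

#' @rdname MergedTranscript-class
#' @export
setMethod("exonBlocks", "MergedTranscript", function(x) x@blocks)

#' @describeIn MergedTranscript-class region extents in transcript coords
#' @export
setGeneric("regionBounds", function(x) standardGeneric("regionBounds"))

#' @rdname MergedTranscript-class
#' @export
setMethod("regionBounds", "MergedTranscript", function(x) x@regions)

#' @describeIn MergedTranscript-class consensus string (may be empty)
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @rdname MergedTranscript-class
#' @export
setMethod("consensusSeq", "MergedTranscript", function(x) x@consensus)

#' @describeIn MergedTranscript-class transcript length in nt
#' @export
setGeneric("mergedLength", function(x) standardGeneric("mergedLength"))

#' @rdname MergedTranscript-class
#' @export
setMethod("mergedLength", "MergedTranscript", function(x) length(x@sequence))

setMethod("show", "MergedTranscript", function(object) {
  cat("MergedTranscript:", object@geneId, "\n")
  cat("  length:", length(object@sequence), "nt in",
      length(object@blocks), "merged exon block(s)\n")
  if (length(object@regions)) {
    for (nm in names(object@regions)) {
      r <- object@regions[nm]
      cat(sprintf("  %-15s [%d, %d]\n", nm,
                  IRanges::start(r), IRanges::end(r)))
    }
  }
  if (length(object@consensus) == 1L && nzchar(object@consensus)) {
    nq <- sum(strsplit(object@consensus, "")[[1]] == "?")
    cat("  consensus: ", nq, " discordant position(s)\n", sep = "")
  }
  invisible(object)
})
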