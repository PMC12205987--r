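# Readers and writers for the plain-text formats the pipeline touches.
# TSV with documented headers is the universal interchange; all positions
# are 1-based inclusive. BED-like exports are converted to 0-based
# half-open at this boundary only.

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and `T` transliterated to `U`, so DNA and RNA
#' FASTA are both accepted. Duplicate identifiers are an error.
#'
#' @param path FASTA file.
#' @return [Biostrings::RNAStringSet] keyed by identifier.
#' @export
readFastaRna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA: ", path)
    return(Biostrings::RNAStringSet())
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1])
  seqs <- vapply(as.character(raw), function(s) rnaFromInput(s), character(1))
  out <- Biostrings::RNAStringSet(unname(seqs))
  names(out) <- ids
  out
}

#' Write RNA sequences to FASTA
#' @param seqs named character vector or [Biostrings::RNAStringSet].
#' @param path output file.
#' @export
writeFastaRna <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# generic validated TSV reader: schema is a named list of validator
# functions returning TRUE or a reason string; malformed rows are reported
# with their file line numbers.
readCheckedTsv <- function(path, schema, integer_cols = character(0),
                           numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (cl in integer_cols) {
    v <- suppressWarnings(as.integer(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("non-integer '", cl, "' at line ", bad[1] + 1L, " of ", path)
    df[[cl]] <- v
  }
  for (cl in numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in names(schema)) {
    res <- schema[[cl]](df[[cl]])
    if (!isTRUE(res)) {
      bad <- attr(res, "rows")
      stop("invalid '", cl, "' at line ",
           if (length(bad)) bad[1] + 1L else "?", " of ", path, ": ",
           as.character(res))
    }
  }
  df
}

.checkThat <- function(ok, reason) {
  if (all(ok | is.na(ok))) TRUE
  else structure(reason, rows = which(!ok))
}

#' Read a 3'-end tag table
#'
#' Expected columns: `gene_id`, `position` (1-based, integer, >= 1),
#' `count` (>= 0), `terminal_a_run` (longest terminal 3' adenosine run
#' among tags at that position, >= 0).
#'
#' @param path TSV file.
#' @return data.frame with validated, typed columns.
#' @export
readTagTable <- function(path) {
  readCheckedTsv(path,
    schema = list(
      gene_id = function(x) .checkThat(nzchar(x), "empty gene_id"),
      position = function(x) .checkThat(x >= 1L, "position must be >= 1"),
      count = function(x) .checkThat(x >= 0, "negative count"),
      terminal_a_run = function(x) .checkThat(x >= 0, "negative A-run")
    ),
    integer_cols = c("position", "count", "terminal_a_run"))
}

#' Read a TPM table
#'
#' Expected columns: `gene_id`, `rna_tpm`, `ribo_tpm` (both >= 0, finite).
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readTpmTable <- function(path) {
  nn <- function(x) .checkThat(is.finite(x) & x >= 0, "TPM must be finite and >= 0")
  readCheckedTsv(path,
    schema = list(gene_id = function(x) .checkThat(nzchar(x), "empty gene_id"),
                  rna_tpm = nn, ribo_tpm = nn),
    numeric_cols = c("rna_tpm", "ribo_tpm"))
}

#' Read a replicate measurement table
#'
#' Expected columns: `site_id`, `scaffold`, `assay` (`native`/`reporter`),
#' `well_role` (`sample`/`untreated`/`blank`/`control`), `replicate`,
#' `signal` (raw target-channel signal) and `norm_signal`
#' (normalization-channel signal), both finite.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readMeasurementTable <- function(path) {
  readCheckedTsv(path,
    schema = list(
      site_id = function(x) .checkThat(nzchar(x), "empty site_id"),
      scaffold = function(x) .checkThat(nzchar(x), "empty scaffold"),
      assay = function(x) .checkThat(x %in% c("native", "reporter"),
                                     "assay must be native/reporter"),
      well_role = function(x) .checkThat(
        x %in% c("sample", "untreated", "blank", "control"),
        "unknown well_role"),
      replicate = function(x) .checkThat(x >= 1L, "replicate must be >= 1"),
      signal = function(x) .checkThat(is.finite(x), "non-finite signal"),
      norm_signal = function(x) .checkThat(is.finite(x),
                                           "non-finite signal")
    ),
    integer_cols = "replicate", numeric_cols = c("signal", "norm_signal"))
}

#' Read a GTF-like isoform annotation table
#'
#' Expected columns: `gene_id`, `isoform_id`, `feature` (one of `exon`,
#' `five_prime_utr`, `orf`, `three_prime_utr`), `start`, `end`
#' (1-based inclusive genomic coordinates, `start <= end`).
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readAnnotationTable <- function(path) {
  df <- readCheckedTsv(path,
    schema = list(
      gene_id = function(x) .checkThat(nzchar(x), "empty gene_id"),
      isoform_id = function(x) .checkThat(nzchar(x), "empty isoform_id"),
      feature = function(x) .checkThat(
        x %in% c("exon", "five_prime_utr", "orf", "three_prime_utr"),
        "unknown feature"),
      start = function(x) .checkThat(x >= 1L, "start must be >= 1"),
      end = function(x) .checkThat(x >= 1L, "end must be >= 1")
    ),
    integer_cols = c("start", "end"))
  bad <- which(df$start > df$end)
  if (length(bad)) stop("start > end at line ", bad[1] + 1L, " of ", path)
  df
}

#' Write a result table as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export poly(A) sites as a BED-like table
#'
#' Converts the package's 1-based inclusive representative positions to
#' BED's 0-based half-open single-base intervals.
#'
#' @param pas data.frame from [callPolyASites()] with a `gene_id` column.
#' @param path output file.
#' @export
writePasBed <- function(pas, path) {
  bed <- data.frame(
    chrom = pas$gene_id,
    chromStart = pas$position - 1L,
    chromEnd = pas$position,
    name = sprintf("pas_%d", seq_len(nrow(pas))),
    score = pas$count,
    fraction = pas$fraction,
    qualified = pas$qualified
  )
  writeTsv(bed, path)
}
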