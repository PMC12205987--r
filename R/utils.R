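# Small shared helpers: RNA string handling and argument checks.
# All coordinates in this package are 1-based inclusive unless a function
# documents otherwise (BED-like exports convert at the boundary).

RNA_BASES <- c("A", "C", "G", "U")

#' Coerce input text to an RNA sequence
#'
#' Uppercases and transliterates `T` to `U`. Characters outside
#' `A,C,G,U,?,N` raise an error naming the first offending position.
#'
#' @param x character scalar (DNA or RNA).
#' @param allow_ambiguous also allow `?` and `N` (consensus strings).
#' @return character scalar over the RNA alphabet.
#' @export
rnaFromInput <- function(x, allow_ambiguous = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  ok <- RNA_BASES
  if (allow_ambiguous) ok <- c(ok, "?", "N")
  ch <- strsplit(out, "")[[1]]
  bad <- which(!ch %in% ok)
  if (length(bad))
    stop("invalid RNA character '", ch[bad[1]], "' at position ", bad[1])
  out
}

#' Reverse complement of an RNA sequence
#'
#' @param x character scalar over `A,C,G,U`.
#' @return reverse complement as a character scalar.
#' @examples
#' revCompRna("AUGC")  # "GCAU"
#' @export
revCompRna <- function(x) {
  x <- rnaFromInput(x, allow_ambiguous = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(x)))
}

#' GC fraction of a sequence
#' @param x character scalar.
#' @return fraction of `G`/`C` characters in `[0, 1]`.
#' @export
gcFraction <- function(x) {
  ch <- strsplit(toupper(x), "")[[1]]
  mean(ch %in% c("G", "C"))
}

# seeded evaluation without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# derive a stream-specific child seed from a master seed (kept < 2^31)
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}
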