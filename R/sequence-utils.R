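#' @keywords internal
#' @import methods
"_PACKAGE"

## Internal string helpers. Junction sequences are short (tens of nt), so the
## reconstruction engine works on plain uppercase character vectors; Biostrings
## is used at the I/O boundary (FASTA) and for reverse complements of XStrings.

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T")

.checkDna <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (length(x) != 1L || is.na(x) || !is.character(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (!allowEmpty && !nzchar(x))
    stop(what, " must be non-empty", call. = FALSE)
  if (nzchar(x) && grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}: ", x, call. = FALSE)
  x
}

.complement <- function(x) chartr("ACGT", "TGCA", x)

.revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  paste(rev(strsplit(.complement(x), "", fixed = TRUE)[[1]]), collapse = "")
}

.chars <- function(x) if (nzchar(x)) strsplit(x, "", fixed = TRUE)[[1]] else character(0)

## round half away from zero (the convention used for table percentages;
## base round() rounds half to even)
.roundHalfUp <- function(x) {
  out <- floor(abs(x) + 0.5) * sign(x)
  out[x == 0] <- 0
  out
}

## run expr with a private RNG state seeded at `seed`, restoring the caller's
## stream afterwards (one substream per junction index relies on this)
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## deterministic substream derivation, kept inside 32-bit integer range
.subSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index)) %% 2147483587)
}
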