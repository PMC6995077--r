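# Internal sequence and interval helpers shared across modules.
# All coordinates package-wide are 0-based half-open (BED convention);
# conversion to 1-based happens only at the edge of human-readable output.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`; IUPAC degeneracy codes are handled.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# IUPAC code -> base set, e.g. W -> "AT"
iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    stop("invalid IUPAC code: ", code, call. = FALSE)
  }
  unname(map[[code]])
}

# Translate an IUPAC arm into a regex over {A,C,G,T}. N in the *pattern*
# matches any base, but the class is written [ACGT] so that N in the
# *sequence* never matches (spec'd genome-N semantics).
iupac_regex <- function(arm) {
  chars <- strsplit(arm, "", fixed = TRUE)[[1]]
  classes <- vapply(chars, function(ch) {
    bases <- iupac_bases(ch)
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1))
  paste0(classes, collapse = "")
}

# Does each character of `seq_chars[off + i]` fall in the base set of
# pattern position i?  Used by validation paths, not the scanner hot loop.
iupac_char_match <- function(pattern_char, seq_char) {
  grepl(seq_char, iupac_bases(pattern_char), fixed = TRUE)
}

assert_dna <- function(x, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(what, " contains characters outside {",
         paste(strsplit(alphabet, "")[[1]], collapse = ","), "}",
         call. = FALSE)
  }
  invisible(x)
}

# Validate an interval tibble against a genome (named character vector).
assert_intervals_resolve <- function(intervals, genome, what = "interval") {
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop(what, "s reference unknown contig(s): ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  lens <- nchar(genome)[intervals$chrom]
  bad <- which(intervals$start < 0 | intervals$end > lens |
                 intervals$start >= intervals$end)
  if (length(bad) > 0) {
    id <- if ("id" %in% names(intervals)) intervals$id[bad[1]] else bad[1]
    stop(what, " '", id, "' does not resolve against the genome ",
         "(out of contig bounds or empty)", call. = FALSE)
  }
  invisible(intervals)
}

# Extract genome subsequence for 0-based half-open coordinates.
subseq0 <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

# Vectorized version over parallel coordinate vectors.
subseq0_vec <- function(genome, chrom, start, end) {
  unname(substring(genome[chrom], start + 1L, end))
}

utils::globalVariables(".")
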