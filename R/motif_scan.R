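#' Compile a dyad motif pattern
#'
#' Parses a pattern string of the form `ARM1[N]{min,max}ARM2` — two IUPAC
#' arms separated by a variable-length unconstrained spacer — into a motif
#' pattern object. The packaged default, `"CWWG[N]{2,12}CWWG"`, is the p53
#' response-element dyad: two CWWG half-sites (W = A or T) separated by 2 to
#' 12 bp of any sequence. This dyad is its own reverse complement, which is
#' why single-strand scanning suffices for it (see [scan_peaks()]).
#'
#' @param pattern_string pattern of the form `ARM1[N]{a,b}ARM2`; a
#'   contiguous pattern is written with `{0,0}`.
#' @return object of class `motif_pattern` with fields `left_arm`,
#'   `right_arm`, `spacer_min`, `spacer_max`.
#' @examples
#' compile_pattern("CWWG[N]{2,12}CWWG")
#' @export
compile_pattern <- function(pattern_string = "CWWG[N]{2,12}CWWG") {
  m <- regmatches(pattern_string,
                  regexec("^([A-Za-z]+)\\[N\\]\\{([0-9]+),([0-9]+)\\}([A-Za-z]+)$",
                          pattern_string))[[1]]
  if (length(m) != 5) {
    stop("malformed motif pattern '", pattern_string,
         "': expected ARM1[N]{min,max}ARM2", call. = FALSE)
  }
  left <- toupper(m[2]); right <- toupper(m[5])
  smin <- as.integer(m[3]); smax <- as.integer(m[4])
  if (smin > smax) {
    stop("spacer_min (", smin, ") must be <= spacer_max (", smax, ")",
         call. = FALSE)
  }
  for (arm in c(left, right)) {
    for (ch in strsplit(arm, "")[[1]]) iupac_bases(ch)  # errors on bad code
  }
  structure(list(left_arm = left, right_arm = right,
                 spacer_min = smin, spacer_max = smax),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern: ", x$left_arm, "[N]{", x$spacer_min, ",", x$spacer_max,
      "}", x$right_arm, "\n", sep = "")
  invisible(x)
}

#' Scan a sequence for dyad motif matches
#'
#' Reports every `(offset, spacer_len)` pair at which the sequence matches
#' `left_arm`, then `spacer_len` unconstrained bases, then `right_arm` under
#' IUPAC semantics. `N` in the pattern matches any of A/C/G/T; `N` in the
#' sequence matches nothing, so windows touching ambiguous genome sequence
#' never yield hits. All combinations are reported — overlapping matches and
#' multiple spacer lengths at one offset are not collapsed.
#'
#' @param seq a single DNA string over `{A,C,G,T,N}`.
#' @param pattern a [compile_pattern()] object.
#' @return tibble with columns `offset` (0-based), `spacer_len`, `width`,
#'   sorted by offset then spacer length.
#' @export
scan_sequence <- function(seq, pattern = compile_pattern()) {
  stopifnot(inherits(pattern, "motif_pattern"))
  assert_dna(seq, "sequence")
  left_re <- iupac_regex(pattern$left_arm)
  right_re <- iupac_regex(pattern$right_arm)
  nl <- nchar(pattern$left_arm); nr <- nchar(pattern$right_arm)
  hits <- purrr::map(pattern$spacer_min:pattern$spacer_max, function(s) {
    # lookahead regex so overlapping matches are all reported
    re <- sprintf("(?=%s[ACGT]{%d}%s)", left_re, s, right_re)
    m <- gregexpr(re, seq, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble::tibble(offset = as.integer(m) - 1L, spacer_len = s,
                   width = nl + s + nr)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(offset = integer(), spacer_len = integer(),
                          width = integer()))
  }
  dplyr::arrange(out, .data$offset, .data$spacer_len)
}

#' Scan peaks for motif matches in genome coordinates
#'
#' Runs [scan_sequence()] on the plus-strand sequence of each peak and lifts
#' hits to genome coordinates. Motif ids are `"<peak_id>.<k>"`, numbering
#' hits 5' to 3' within each peak. For a self-reverse-complementary dyad
#' (the default p53 pattern) plus-strand scanning finds every site; set
#' `both_strands = TRUE` for non-palindromic patterns, which also scans the
#' reverse complement, mirrors coordinates, and drops duplicate intervals.
#'
#' Hits whose window contains `N` never match (see [scan_sequence()]); the
#' returned tibble carries attributes `motifless_peaks` (ids of peaks with
#' no hit) for bookkeeping.
#'
#' @param genome named character vector from [read_genome()].
#' @param peaks peak tibble from [read_bed()].
#' @param pattern a [compile_pattern()] object.
#' @param both_strands also scan the reverse complement (needed only for
#'   non-palindromic patterns).
#' @return tibble with columns `motif_id`, `peak_id`, `chrom`, `start`,
#'   `end`, `spacer_len` (0-based half-open genome coordinates).
#' @export
scan_peaks <- function(genome, peaks, pattern = compile_pattern(),
                       both_strands = FALSE) {
  assert_intervals_resolve(peaks, genome, "peak")
  per_peak <- purrr::map(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    seq <- subseq0(genome, p$chrom, p$start, p$end)
    hits <- scan_sequence(seq, pattern)
    if (both_strands) {
      rc_hits <- scan_sequence(revcomp(seq), pattern)
      if (nrow(rc_hits) > 0) {
        # mirror: offset o on revcomp of length L covers width w ->
        # plus-strand offset L - o - w
        L <- nchar(seq)
        rc_hits$offset <- L - rc_hits$offset - rc_hits$width
        hits <- dplyr::distinct(
          dplyr::arrange(dplyr::bind_rows(hits, rc_hits),
                         .data$offset, .data$spacer_len),
          .data$offset, .data$spacer_len, .keep_all = TRUE)
      }
    }
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(
      motif_id = paste0(p$id, ".", seq_len(nrow(hits))),
      peak_id = p$id,
      chrom = p$chrom,
      start = p$start + hits$offset,
      end = p$start + hits$offset + hits$width,
      spacer_len = hits$spacer_len)
  })
  out <- dplyr::bind_rows(per_peak)
  if (nrow(out) == 0) {
    out <- tibble::tibble(motif_id = character(), peak_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), spacer_len = integer())
  }
  attr(out, "motifless_peaks") <- setdiff(peaks$id, unique(out$peak_id))
  out
}

#' Optionally collapse overlapping motif hits
#'
#' Greedy left-to-right collapse within each peak: the leftmost hit wins,
#' ties at one offset resolved by the shortest spacer; any hit overlapping an
#' already-accepted one is dropped. Off by default in the pipeline — the
#' lossless full set is the primary representation.
#'
#' @param hits motif-hit tibble from [scan_peaks()].
#' @return collapsed tibble, same columns.
#' @export
collapse_motif_hits <- function(hits) {
  hits |>
    dplyr::arrange(.data$peak_id, .data$start, .data$spacer_len) |>
    dplyr::group_by(.data$peak_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- logical(nrow(df))
      last_end <- -1L
      for (i in seq_len(nrow(df))) {
        if (df$start[i] >= last_end) {
          keep[i] <- TRUE
          last_end <- df$end[i]
        }
      }
      df[keep, ]
    }) |>
    dplyr::ungroup()
}

#' Export motif hits as BED6
#'
#' `name` is the motif id and `score` the spacer length.
#'
#' @param hits motif-hit tibble.
#' @param path output path.
#' @export
write_motif_bed <- function(hits, path) {
  write_bed(dplyr::mutate(hits, id = .data$motif_id,
                          score = .data$spacer_len, strand = "."),
            path)
}
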