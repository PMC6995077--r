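#' Enumerate candidate sgRNAs around motif hits
#'
#' For every motif hit, finds every PAM occurrence on either strand whose
#' 3-bp PAM interval lies entirely within the motif interval extended by
#' `window` bp on each side, and emits one candidate guide per PAM site: the
#' 20-nt protospacer 5' of the PAM (guide-sense sequence; reverse complement
#' of the plus strand for minus-strand guides), the observed PAM, and the
#' blunt-cut position 3 bp 5' of the PAM (between protospacer bases 17 and
#' 18, recorded as the plus-strand coordinate of the base 5' of the cut).
#'
#' Candidates found from different motifs at the same `(locus, strand)` are
#' merged with the union of their motif ids. The guide is attributed to the
#' peak whose motif lies closest to the cut site (ties: lower peak id);
#' naming ([assign_guide_ids()]) uses the 5'-most motif. Protospacers
#' containing `N` are dropped and counted in the `dropped_n` attribute.
#'
#' With `anchor = "cut"` the window predicate applies to the cut position
#' instead of the PAM (alternative reading of a motif-proximity window).
#'
#' @param genome named character vector from [read_genome()].
#' @param motif_hits tibble from [scan_peaks()].
#' @param window bp added to each side of the motif; default 16.
#' @param pam_pattern IUPAC PAM, default `"NGG"` (SpCas9).
#' @param anchor `"pam"` (default) or `"cut"`: which feature must lie in the
#'   window.
#' @return tibble with columns `spacer`, `pam`, `chrom`, `start`, `end`,
#'   `strand`, `cut_pos`, `peak_id`, `motif_ids` (list-column), `id_motif`
#'   (5'-most motif, used for naming); sorted by locus.
#' @export
enumerate_guides <- function(genome, motif_hits, window = 16L,
                             pam_pattern = "NGG", anchor = c("pam", "cut")) {
  anchor <- match.arg(anchor)
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  if (nrow(motif_hits) == 0) {
    return(empty_guide_tbl())
  }
  assert_intervals_resolve(
    dplyr::mutate(motif_hits, id = .data$motif_id), genome, "motif")
  pam_len <- nchar(pam_pattern)
  plus_re <- sprintf("(?=%s)", iupac_regex(pam_pattern))
  minus_re <- sprintf("(?=%s)", iupac_regex(revcomp(pam_pattern)))

  dropped_n <- 0L
  cand <- purrr::map(seq_len(nrow(motif_hits)), function(i) {
    m <- motif_hits[i, ]
    L <- nchar(genome[[m$chrom]])
    win_start <- max(0L, m$start - window)
    win_end <- min(L, m$end + window)
    # for cut anchoring the PAM can sit up to 4 bp outside the window
    pad <- if (anchor == "cut") 4L else 0L
    reg_start <- max(0L, win_start - pad)
    reg_end <- min(L, win_end + pad + pam_len)
    region <- subseq0(genome, m$chrom, reg_start, reg_end)

    find <- function(re) {
      hit <- gregexpr(re, region, perl = TRUE)[[1]]
      if (hit[1] == -1) integer(0) else reg_start + as.integer(hit) - 1L
    }
    p_plus <- find(plus_re)
    p_minus <- find(minus_re)

    # window predicate on the anchoring feature
    if (anchor == "pam") {
      p_plus <- p_plus[p_plus >= win_start & p_plus + pam_len <= win_end]
      p_minus <- p_minus[p_minus >= win_start & p_minus + pam_len <= win_end]
    } else {
      cut_plus <- p_plus - 4L      # base 5' of the blunt cut, + strand guide
      cut_minus <- p_minus + pam_len + 2L
      p_plus <- p_plus[cut_plus >= win_start & cut_plus < win_end]
      p_minus <- p_minus[cut_minus >= win_start & cut_minus < win_end]
    }
    # protospacer fully on the contig
    p_plus <- p_plus[p_plus - 20L >= 0L]
    p_minus <- p_minus[p_minus + pam_len + 20L <= L]

    plus_tbl <- if (length(p_plus) > 0) {
      tibble::tibble(
        chrom = m$chrom, start = p_plus - 20L, end = p_plus, strand = "+",
        spacer = subseq0_vec(genome, rep(m$chrom, length(p_plus)),
                             p_plus - 20L, p_plus),
        pam = subseq0_vec(genome, rep(m$chrom, length(p_plus)),
                          p_plus, p_plus + pam_len),
        cut_pos = p_plus - 4L)
    }
    minus_tbl <- if (length(p_minus) > 0) {
      s <- p_minus + pam_len
      tibble::tibble(
        chrom = m$chrom, start = s, end = s + 20L, strand = "-",
        spacer = revcomp(subseq0_vec(genome, rep(m$chrom, length(s)),
                                     s, s + 20L)),
        pam = revcomp(subseq0_vec(genome, rep(m$chrom, length(p_minus)),
                                  p_minus, p_minus + pam_len)),
        cut_pos = s + 2L)
    }
    out <- dplyr::bind_rows(plus_tbl, minus_tbl)
    if (nrow(out) == 0) return(NULL)
    dplyr::mutate(out, motif_id = m$motif_id, peak_id = m$peak_id,
                  motif_start = m$start,
                  motif_dist = pmax(0L, m$start - .data$cut_pos,
                                    .data$cut_pos - (m$end - 1L)))
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) return(empty_guide_tbl())

  n_spacer <- grepl("N", cand$spacer, fixed = TRUE) |
    grepl("N", cand$pam, fixed = TRUE)
  dropped_n <- length(unique(paste(cand$chrom, cand$start,
                                   cand$strand)[n_spacer]))
  cand <- cand[!n_spacer, ]

  out <- cand |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand,
                    .data$spacer, .data$pam, .data$cut_pos) |>
    dplyr::summarise(
      motif_ids = list(.data$motif_id[order(.data$motif_start,
                                            .data$motif_id)]),
      id_motif = .data$motif_id[order(.data$motif_start,
                                      .data$motif_id)][1],
      peak_id = .data$peak_id[order(.data$motif_dist, .data$peak_id,
                                    .data$motif_start)][1],
      .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand) |>
    dplyr::select("spacer", "pam", "chrom", "start", "end", "strand",
                  "cut_pos", "peak_id", "motif_ids", "id_motif")
  attr(out, "dropped_n") <- dropped_n
  out
}

empty_guide_tbl <- function() {
  structure(
    tibble::tibble(spacer = character(), pam = character(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character(), cut_pos = integer(),
                   peak_id = character(), motif_ids = list(),
                   id_motif = character()),
    dropped_n = 0L)
}

#' Assign stable guide ids
#'
#' Ids follow the `"<peak>.<motif index>-<running index>"` convention: the
#' guide inherits the motif id of its 5'-most motif and guides of one motif
#' are numbered `-1, -2, ...` in coordinate order (chrom, start, strand).
#' The assignment is a pure function of the input, so identical designs get
#' identical ids across runs.
#'
#' @param guides tibble from [enumerate_guides()].
#' @return the same tibble with a `guide_id` column first and `category`
#'   `"peak"`.
#' @export
assign_guide_ids <- function(guides) {
  guides |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand) |>
    dplyr::group_by(.data$id_motif) |>
    dplyr::mutate(guide_id = paste0(.data$id_motif, "-",
                                    dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = "peak") |>
    dplyr::select("guide_id", "spacer", "pam", "chrom", "start", "end",
                  "strand", "cut_pos", "category", "peak_id", "motif_ids",
                  "id_motif")
}

#' Summarize a designed library
#'
#' Computes the design summaries used to report a peak-targeting library's
#' composition: guide counts per peak and per motif with their histograms,
#' how many peaks/motifs are targeted at all and by more than one guide, the
#' per-category composition (peak-targeting, intergenic controls,
#' non-targeting controls, ...), and — when a gene table is supplied — the
#' distance from every targeting guide's cut site to the nearest annotated
#' TSS.
#'
#' @param library library tibble (with `guide_id` and `category`).
#' @param peaks optional peak tibble; peaks absent from the library are then
#'   reported with zero guides.
#' @param motifs optional motif-hit tibble, likewise.
#' @param genes optional gene tibble from [read_gene_table()] for
#'   TSS-distance annotation.
#' @return object of class `library_summary`: list of tibbles
#'   (`composition`, `per_peak`, `per_motif`, `peak_histogram`,
#'   `motif_histogram`, `stats`, optional `tss_distances`).
#' @export
summarize_library <- function(library, peaks = NULL, motifs = NULL,
                              genes = NULL) {
  targeting <- dplyr::filter(library, .data$category == "peak")
  composition <- library |>
    dplyr::count(.data$category, name = "n_guides") |>
    dplyr::arrange(.data$category)

  per_peak <- targeting |> dplyr::count(.data$peak_id, name = "n_guides")
  if (!is.null(peaks)) {
    per_peak <- tibble::tibble(peak_id = peaks$id) |>
      dplyr::left_join(per_peak, by = "peak_id") |>
      dplyr::mutate(n_guides = dplyr::coalesce(.data$n_guides, 0L))
  }
  per_motif <- targeting |>
    dplyr::select("guide_id", "motif_ids") |>
    tidyr::unnest_longer("motif_ids", values_to = "motif_id") |>
    dplyr::count(.data$motif_id, name = "n_guides")
  if (!is.null(motifs)) {
    per_motif <- tibble::tibble(motif_id = motifs$motif_id) |>
      dplyr::left_join(per_motif, by = "motif_id") |>
      dplyr::mutate(n_guides = dplyr::coalesce(.data$n_guides, 0L))
  }
  hist_of <- function(tbl, what) {
    tbl |>
      dplyr::filter(.data$n_guides > 0) |>
      dplyr::count(.data$n_guides, name = what) |>
      dplyr::arrange(.data$n_guides)
  }
  stats <- tibble::tibble(
    n_guides = nrow(targeting),
    n_peaks_targeted = sum(per_peak$n_guides > 0),
    n_peaks_multi = sum(per_peak$n_guides >= 2),
    fraction_peaks_multi = ifelse(sum(per_peak$n_guides > 0) > 0,
                                  sum(per_peak$n_guides >= 2) /
                                    sum(per_peak$n_guides > 0), NA_real_),
    n_motifs_targeted = sum(per_motif$n_guides > 0),
    n_motifs_multi = sum(per_motif$n_guides >= 2))

  out <- list(composition = composition, per_peak = per_peak,
              per_motif = per_motif,
              peak_histogram = hist_of(per_peak, "n_peaks"),
              motif_histogram = hist_of(per_motif, "n_motifs"),
              stats = stats)
  if (!is.null(genes) && nrow(targeting) > 0) {
    out$tss_distances <- tss_distance(targeting, genes)
  }
  structure(out, class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  s <- x$stats
  cat("Library summary\n")
  cat("  targeting guides: ", s$n_guides, "\n", sep = "")
  cat("  peaks targeted:   ", s$n_peaks_targeted,
      " (", s$n_peaks_multi, " by >1 guide)\n", sep = "")
  cat("  motifs targeted:  ", s$n_motifs_targeted,
      " (", s$n_motifs_multi, " by >1 guide)\n", sep = "")
  cat("  composition:\n")
  for (i in seq_len(nrow(x$composition))) {
    cat("    ", format(x$composition$category[i], width = 22),
        x$composition$n_guides[i], "\n", sep = "")
  }
  invisible(x)
}
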