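#' Load a CFD penalty table
#'
#' The cutting frequency determination (CFD) score of a candidate off-target
#' site is the product, over spacer positions 1-20 (position 1 PAM-distal),
#' of a position- and base-pair-specific mismatch penalty, times a penalty
#' for the PAM's last two bases; Watson-Crick matches contribute 1.0 and a
#' canonical `GG` PAM contributes 1.0, so a fully tolerated site scores
#' exactly 1.
#'
#' The packaged default table (`cfd_penalties_synthetic.tsv`) is a
#' *synthetic* penalty matrix: it reproduces the structure and invariants of
#' the published CFD matrix (penalties in `[0,1]`, wobble-like mismatches
#' most tolerated, PAM-proximal positions least tolerant, a small set of
#' fully tolerated penalty-1 entries confined to PAM-distal positions) but
#' not its published numeric values. Any table in the same TSV format can be
#' supplied instead.
#'
#' At load time the table is checked: the positions carrying penalty-1
#' mismatch entries must number at most `max_mm_bound`, which guarantees
#' that a mismatch-bounded off-target search at that bound finds every
#' CFD = 1 site.
#'
#' @param path TSV with columns `kind` (mismatch/pam), `position`,
#'   `guide_base`, `site_base`, `pam2`, `penalty`.
#' @param max_mm_bound mismatch ceiling the search will use; default 3.
#' @return object of class `cfd_table`: list with `mismatch` (20 x 4 x 4
#'   array, guide base x site base) and `pam` (named numeric by 2-mer).
#' @export
load_cfd_table <- function(path = system.file("extdata",
                                              "cfd_penalties_synthetic.tsv",
                                              package = "peakscreen"),
                           max_mm_bound = 3L) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA"))
  bases <- c("A", "C", "G", "T")
  mism <- dplyr::filter(tbl, .data$kind == "mismatch")
  arr <- array(1.0, dim = c(20, 4, 4),
               dimnames = list(NULL, bases, bases))
  arr[cbind(mism$position, match(mism$guide_base, bases),
            match(mism$site_base, bases))] <- mism$penalty
  if (any(arr < 0 | arr > 1)) stop("CFD penalties must be in [0,1]",
                                   call. = FALSE)
  for (b in bases) {
    if (any(arr[, b, b] != 1.0)) {
      stop("CFD penalty for a Watson-Crick match must be 1.0", call. = FALSE)
    }
  }
  pam_rows <- dplyr::filter(tbl, .data$kind == "pam")
  pam <- stats::setNames(pam_rows$penalty, pam_rows$pam2)
  if (is.na(pam["GG"]) || pam[["GG"]] != 1.0) {
    stop("CFD PAM penalty for GG must be 1.0", call. = FALSE)
  }
  unit_positions <- unique(mism$position[mism$penalty == 1.0])
  if (length(unit_positions) > max_mm_bound) {
    stop("CFD table has penalty-1 mismatch entries at ",
         length(unit_positions), " positions; a search bounded at ",
         max_mm_bound, " mismatches would miss CFD = 1 sites", call. = FALSE)
  }
  structure(list(mismatch = arr, pam = pam,
                 n_unit_positions = length(unit_positions)),
            class = "cfd_table")
}

#' CFD off-target score
#'
#' Product over spacer positions of the mismatch penalty for the
#' (position, guide base, site base) triple, times the PAM 2-mer penalty.
#' Position 1 is the PAM-distal end of the protospacer.
#'
#' @param spacer 20-nt guide spacer (DNA alphabet).
#' @param site_seq 20-nt genomic site sequence(s), same orientation;
#'   vectorized.
#' @param pam 3-nt PAM(s) observed at the site; only the last two bases are
#'   scored.
#' @param table a [load_cfd_table()] object.
#' @return numeric vector of scores in `[0,1]`.
#' @export
cfd_score <- function(spacer, site_seq, pam, table = load_cfd_table()) {
  if (nchar(spacer) != 20) stop("spacer must be 20 nt", call. = FALSE)
  if (any(nchar(site_seq) != 20)) stop("site_seq must be 20 nt",
                                       call. = FALSE)
  if (any(nchar(pam) != 3)) stop("pam must be 3 nt", call. = FALSE)
  assert_dna(spacer, "spacer", allow_n = FALSE)
  assert_dna(site_seq, "site_seq", allow_n = FALSE)
  bases <- c("A", "C", "G", "T")
  g <- match(strsplit(spacer, "")[[1]], bases)
  n <- length(site_seq)
  site_mat <- matrix(match(unlist(strsplit(site_seq, "")), bases),
                     nrow = n, byrow = TRUE)
  pam2 <- substr(pam, 2, 3)
  pam_pen <- table$pam[pam2]
  if (any(is.na(pam_pen))) {
    stop("no PAM penalty for 2-mer '", pam2[which(is.na(pam_pen))[1]], "'",
         call. = FALSE)
  }
  scores <- vapply(seq_len(n), function(i) {
    prod(table$mismatch[cbind(1:20, g, site_mat[i, ])])
  }, numeric(1))
  unname(scores * pam_pen)
}

# ---- genome scanning core -------------------------------------------------

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

encode_genome <- function(genome) {
  enc <- lapply(unclass(genome), function(s) {
    unname(BASE_CODE[strsplit(s, "", fixed = TRUE)[[1]]])
  })
  # cache the reverse-complement encoding: minus-strand scans reuse it
  attr(enc, "rc") <- lapply(enc, function(e) {
    e_rc <- rev(5L - e)
    e_rc[e_rc == 5L] <- 0L
    e_rc
  })
  enc
}

# All sites on one encoded strand with <= max_mm mismatches to the spacer
# and an NGG/NAG PAM; compiled kernel (PAM-first with early mismatch exit).
scan_strand <- function(enc, sp_code, max_mm) {
  .scan_strand_cpp(enc, sp_code, as.integer(max_mm))
}

#' Find candidate off-target sites of a spacer
#'
#' Scans the whole genome, both strands, for sites with at most `max_mm`
#' mismatches to the spacer and a canonical (`NGG`) or alternative (`NAG`)
#' PAM, scores each with [cfd_score()] (the NAG penalty enters through the
#' PAM 2-mer), and labels each site's genomic context: inside a
#' protein-coding gene body, inside a targeted peak, or other noncoding.
#' The guide's own intended locus, when given, is excluded by coordinate
#' identity — never by sequence.
#'
#' @param genome named character vector, or a pre-encoded genome from the
#'   internal encoder (used by [filter_guides()] to amortize encoding).
#' @param spacer 20-nt guide spacer.
#' @param max_mm mismatch ceiling; default 3.
#' @param table a [load_cfd_table()] object.
#' @param genes optional gene tibble; coding gene bodies define the
#'   `coding_gene` context.
#' @param peaks optional targeted-peak tibble defining `targeted_peak`.
#' @param exclude_locus optional list/row with `chrom`, `start`, `strand` of
#'   the intended site.
#' @return tibble: `chrom`, `start`, `end`, `strand`, `site_seq`, `pam`,
#'   `n_mismatches`, `cfd`, `context`.
#' @export
find_offtargets <- function(genome, spacer, max_mm = 3L,
                            table = load_cfd_table(), genes = NULL,
                            peaks = NULL, exclude_locus = NULL) {
  if (nchar(spacer) != 20) stop("spacer must be 20 nt", call. = FALSE)
  if (is.list(genome) && !is.null(attr(genome, "seqs"))) {
    enc <- genome
    seqs <- attr(genome, "seqs")
  } else {
    enc <- encode_genome(genome)
    seqs <- unclass(genome)
  }
  sp_code <- unname(BASE_CODE[strsplit(spacer, "")[[1]]])

  per_contig <- purrr::map(names(enc), function(chrom) {
    e <- enc[[chrom]]
    L <- length(e)
    plus <- scan_strand(e, sp_code, max_mm)
    # minus strand: sites whose revcomp matches the spacer. Equivalent to
    # scanning the plus strand with the revcomp'd spacer and a CCN/CTN PAM
    # 5' of the 20-mer; implemented by scanning the reverse-complement code
    # (cached on the encoded genome).
    rc_cache <- attr(enc, "rc")
    e_rc <- if (!is.null(rc_cache)) rc_cache[[chrom]] else {
      tmp <- rev(5L - e)
      tmp[tmp == 5L] <- 0L
      tmp
    }
    minus <- scan_strand(e_rc, sp_code, max_mm)
    rows <- list()
    if (length(plus$pos) > 0) {
      rows$plus <- tibble::tibble(
        chrom = chrom, start = plus$pos, end = plus$pos + 20L, strand = "+",
        n_mismatches = plus$mm)
    }
    if (length(minus$pos) > 0) {
      start <- L - (minus$pos + 20L)
      rows$minus <- tibble::tibble(
        chrom = chrom, start = start, end = start + 20L, strand = "-",
        n_mismatches = minus$mm)
    }
    dplyr::bind_rows(rows)
  })
  sites <- dplyr::bind_rows(per_contig)
  if (nrow(sites) == 0) return(empty_offtarget_tbl())

  if (!is.null(exclude_locus)) {
    own <- sites$chrom == exclude_locus$chrom &
      sites$start == exclude_locus$start &
      sites$strand == exclude_locus$strand
    sites <- sites[!own, ]
  }
  if (nrow(sites) == 0) return(empty_offtarget_tbl())

  plus_seq <- subseq0_vec(seqs, sites$chrom, sites$start, sites$end)
  plus_pam <- subseq0_vec(seqs, sites$chrom,
                          ifelse(sites$strand == "+", sites$end,
                                 sites$start - 3L),
                          ifelse(sites$strand == "+", sites$end + 3L,
                                 sites$start))
  sites$site_seq <- ifelse(sites$strand == "+", plus_seq, revcomp(plus_seq))
  sites$pam <- ifelse(sites$strand == "+", plus_pam, revcomp(plus_pam))
  ok <- !grepl("N", sites$site_seq, fixed = TRUE) &
    !grepl("N", sites$pam, fixed = TRUE)
  sites <- sites[ok, ]
  if (nrow(sites) == 0) return(empty_offtarget_tbl())

  sites$cfd <- cfd_score(spacer, sites$site_seq, sites$pam, table)
  sites$context <- site_context(sites, genes, peaks)
  dplyr::arrange(sites[, c("chrom", "start", "end", "strand", "site_seq",
                           "pam", "n_mismatches", "cfd", "context")],
                 .data$chrom, .data$start, .data$strand)
}

empty_offtarget_tbl <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), site_seq = character(),
                 pam = character(), n_mismatches = integer(),
                 cfd = numeric(), context = character())
}

# context per site: coding_gene beats targeted_peak beats other_noncoding
site_context <- function(sites, genes, peaks) {
  ctx <- rep("other_noncoding", nrow(sites))
  overlaps_any <- function(tbl) {
    vapply(seq_len(nrow(sites)), function(i) {
      any(tbl$chrom == sites$chrom[i] & tbl$start < sites$end[i] &
            tbl$end > sites$start[i])
    }, logical(1))
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    ctx[overlaps_any(peaks)] <- "targeted_peak"
  }
  if (!is.null(genes)) {
    coding <- dplyr::filter(genes, .data$coding)
    if (nrow(coding) > 0) ctx[overlaps_any(coding)] <- "coding_gene"
  }
  ctx
}

#' Apply the library's off-target exclusion rules
#'
#' A guide is rejected when any fully tolerated off-target site
#' (CFD = 1, tested with tolerance `1e-9` on the product) falls inside a
#' protein-coding gene body (rule A), or when more than one such site lies
#' in unrelated noncoding sequence (rule B). By default a tolerated site
#' inside another *targeted* peak counts toward rule B (strict reading of
#' "unrelated"); `exempt_targeted_peaks = TRUE` exempts those sites.
#'
#' @param guides guide tibble (from [assign_guide_ids()] or the control
#'   makers); rows with `NA` loci (non-targeting controls) pass untouched.
#' @param genome named character vector.
#' @param genes gene tibble.
#' @param peaks targeted-peak tibble.
#' @param table a [load_cfd_table()] object.
#' @param max_mm off-target search mismatch ceiling.
#' @param exempt_targeted_peaks see Description.
#' @return list with elements `kept` (guide tibble) and `rejected` (guide
#'   tibble plus `rule` and a `sites` list-column of offending sites).
#' @export
filter_guides <- function(guides, genome, genes = NULL, peaks = NULL,
                          table = load_cfd_table(), max_mm = 3L,
                          exempt_targeted_peaks = FALSE) {
  if (nrow(guides) == 0) {
    return(list(kept = guides,
                rejected = dplyr::mutate(guides, rule = character(0),
                                         sites = list())))
  }
  enc <- encode_genome(genome)
  attr(enc, "seqs") <- unclass(genome)
  rule <- rep(NA_character_, nrow(guides))
  offending <- vector("list", nrow(guides))
  for (i in seq_len(nrow(guides))) {
    if (is.na(guides$start[i])) next  # non-targeting: no genomic locus
    ots <- find_offtargets(enc, guides$spacer[i], max_mm = max_mm,
                           table = table, genes = genes, peaks = peaks,
                           exclude_locus = guides[i, ])
    tolerated <- ots[ots$cfd >= 1 - 1e-9, ]
    if (nrow(tolerated) == 0) next
    if (any(tolerated$context == "coding_gene")) {
      rule[i] <- "A"
      offending[[i]] <- tolerated[tolerated$context == "coding_gene", ]
      next
    }
    countable <- if (exempt_targeted_peaks) {
      tolerated[tolerated$context == "other_noncoding", ]
    } else {
      tolerated[tolerated$context %in% c("other_noncoding",
                                         "targeted_peak"), ]
    }
    if (nrow(countable) > 1) {
      rule[i] <- "B"
      offending[[i]] <- countable
    }
  }
  rej <- !is.na(rule)
  rejected <- guides[rej, ]
  rejected$rule <- rule[rej]
  rejected$sites <- offending[rej]
  list(kept = guides[!rej, ], rejected = rejected)
}

#' Write the rejected-guides report
#'
#' One row per offending off-target site, with the rejection rule.
#'
#' @param rejected the `rejected` element of [filter_guides()].
#' @param path output TSV path.
#' @export
write_rejected_report <- function(rejected, path) {
  if (nrow(rejected) == 0) {
    readr::write_tsv(tibble::tibble(guide_id = character(),
                                    rule = character(), chrom = character(),
                                    start = integer(), end = integer(),
                                    strand = character(), cfd = numeric(),
                                    context = character()), path)
    return(invisible(path))
  }
  flat <- rejected |>
    dplyr::select(dplyr::any_of(c("guide_id", "spacer")), "rule", "sites") |>
    tidyr::unnest("sites")
  readr::write_tsv(flat, path)
  invisible(path)
}

# seed-scoped RNG so generators are pure functions of (input, seed)
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Design intergenic-targeting control guides
#'
#' Draws `n` guides at valid PAM sites whose protospacers lie at least
#' `min_gene_distance` bp from every gene body and outside every targeted
#' peak, and that pass [filter_guides()]. These control for the burden of
#' Cas9 recruitment/cutting at a functionless locus. Reproducible under
#' `rng_seed`.
#'
#' @param genome named character vector.
#' @param genes gene tibble.
#' @param peaks targeted-peak tibble.
#' @param n number of controls.
#' @param pam_pattern PAM, default `"NGG"`.
#' @param min_gene_distance bp; default 5000.
#' @param rng_seed integer seed.
#' @param table,max_mm passed to [filter_guides()].
#' @return guide tibble with `category = "intergenic_control"`.
#' @export
make_intergenic_controls <- function(genome, genes, peaks, n,
                                     pam_pattern = "NGG",
                                     min_gene_distance = 5000L,
                                     rng_seed = 1L,
                                     table = load_cfd_table(),
                                     max_mm = 3L) {
  if (n == 0) return(empty_control_tbl("intergenic_control"))
  cand <- enumerate_pam_sites(genome, pam_pattern)
  if (nrow(cand) > 0) {
    ok <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(genes))) {
      gap <- pmax(0L, genes$start[i] - cand$end, cand$start - genes$end[i])
      ok <- ok & !(cand$chrom == genes$chrom[i] & gap < min_gene_distance)
    }
    for (i in seq_len(nrow(peaks))) {
      overlap <- peaks$start[i] < cand$end & peaks$end[i] > cand$start
      ok <- ok & !(cand$chrom == peaks$chrom[i] & overlap)
    }
    cand <- cand[ok & !grepl("N", cand$spacer, fixed = TRUE), ]
  }
  if (nrow(cand) == 0) {
    stop("genome yields 0 intergenic PAM sites >= ", min_gene_distance,
         " bp from genes (", n, " requested)", call. = FALSE)
  }
  order_idx <- with_seed(rng_seed, sample.int(nrow(cand)))
  picked <- empty_control_tbl("intergenic_control")[0, ]
  taken <- 0L
  # off-target-filter candidates in batches; keep the first n that pass
  while (nrow(picked) < n && taken < length(order_idx)) {
    chunk_idx <- order_idx[(taken + 1L):min(length(order_idx),
                                            taken + max(2L * n, 50L))]
    taken <- taken + length(chunk_idx)
    trial <- dplyr::mutate(cand[chunk_idx, ],
                           category = "intergenic_control",
                           peak_id = NA_character_,
                           motif_ids = replicate(length(chunk_idx),
                                                 character(0),
                                                 simplify = FALSE))
    res <- filter_guides(trial, genome, genes = genes, peaks = peaks,
                         table = table, max_mm = max_mm)
    picked <- dplyr::bind_rows(picked, res$kept)
  }
  if (nrow(picked) < n) {
    stop("only ", nrow(picked), " of ", n,
         " requested intergenic controls could be designed", call. = FALSE)
  }
  picked <- picked[seq_len(n), ]
  dplyr::mutate(picked, guide_id = paste0("intergenic_", seq_len(n)),
                id_motif = NA_character_) |>
    dplyr::select("guide_id", "spacer", "pam", "chrom", "start", "end",
                  "strand", "cut_pos", "category", "peak_id", "motif_ids",
                  "id_motif")
}

# every PAM site on either strand genome-wide, as a guide-shaped tibble
enumerate_pam_sites <- function(genome, pam_pattern = "NGG") {
  pam_len <- nchar(pam_pattern)
  plus_re <- sprintf("(?=%s)", iupac_regex(pam_pattern))
  minus_re <- sprintf("(?=%s)", iupac_regex(revcomp(pam_pattern)))
  per_contig <- purrr::map(names(genome), function(chrom) {
    s <- genome[[chrom]]
    L <- nchar(s)
    find <- function(re) {
      hit <- gregexpr(re, s, perl = TRUE)[[1]]
      if (hit[1] == -1) integer(0) else as.integer(hit) - 1L
    }
    p_plus <- find(plus_re)
    p_plus <- p_plus[p_plus - 20L >= 0L & p_plus + pam_len <= L]
    p_minus <- find(minus_re)
    p_minus <- p_minus[p_minus + pam_len + 20L <= L]
    plus_tbl <- if (length(p_plus) > 0) {
      sp <- substring(s, p_plus - 19L, p_plus)
      pm <- substring(s, p_plus + 1L, p_plus + pam_len)
      tibble::tibble(chrom = chrom, start = p_plus - 20L, end = p_plus,
                     strand = "+", spacer = sp, pam = pm,
                     cut_pos = p_plus - 4L)
    }
    minus_tbl <- if (length(p_minus) > 0) {
      st <- p_minus + pam_len
      sp <- revcomp(substring(s, st + 1L, st + 20L))
      pm <- revcomp(substring(s, p_minus + 1L, p_minus + pam_len))
      tibble::tibble(chrom = chrom, start = st, end = st + 20L, strand = "-",
                     spacer = sp, pam = pm, cut_pos = st + 2L)
    }
    dplyr::bind_rows(plus_tbl, minus_tbl)
  })
  dplyr::bind_rows(per_contig)
}

empty_control_tbl <- function(category) {
  tibble::tibble(guide_id = character(), spacer = character(),
                 pam = character(), chrom = character(), start = integer(),
                 end = integer(), strand = character(), cut_pos = integer(),
                 category = character(), peak_id = character(),
                 motif_ids = list(), id_motif = character())
}

#' Design non-targeting control guides
#'
#' Draws random 20-mers and keeps those with no genomic site within
#' `max_mm_clearance` mismatches adjacent to an NGG/NAG PAM on either
#' strand. These guides load Cas9 but never recruit it to the genome; their
#' fold-change distribution anchors the null in [guide_significance()].
#'
#' @param genome named character vector.
#' @param n number of controls.
#' @param max_mm_clearance required mismatch clearance; default 2.
#' @param rng_seed integer seed.
#' @param max_attempts draw budget before giving up.
#' @return guide tibble with `category = "nontargeting_control"` and `NA`
#'   loci.
#' @export
make_nontargeting_controls <- function(genome, n, max_mm_clearance = 2L,
                                       rng_seed = 1L,
                                       max_attempts = max(1000L, 50L * n)) {
  if (n == 0) return(empty_control_tbl("nontargeting_control"))
  enc <- encode_genome(genome)
  attr(enc, "seqs") <- unclass(genome)
  bases <- c("A", "C", "G", "T")
  spacers <- with_seed(rng_seed, {
    found <- character(0)
    attempts <- 0L
    while (length(found) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      sp <- paste0(sample(bases, 20, replace = TRUE), collapse = "")
      hits <- find_offtargets(enc, sp, max_mm = max_mm_clearance,
                              table = NULL_CFD)
      if (nrow(hits) == 0 && !sp %in% found) found <- c(found, sp)
    }
    found
  })
  if (length(spacers) < n) {
    stop("could not find ", n, " non-targeting spacers with ",
         max_mm_clearance, "-mismatch clearance (found ", length(spacers),
         ")", call. = FALSE)
  }
  tibble::tibble(guide_id = paste0("nontargeting_", seq_len(n)),
                 spacer = spacers, pam = NA_character_,
                 chrom = NA_character_, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_,
                 cut_pos = NA_integer_, category = "nontargeting_control",
                 peak_id = NA_character_,
                 motif_ids = replicate(n, character(0), simplify = FALSE),
                 id_motif = NA_character_)
}

# trivial all-ones table for clearance searches where only site existence
# matters, not the score
NULL_CFD <- local({
  bases <- c("A", "C", "G", "T")
  structure(list(
    mismatch = array(1.0, dim = c(20, 4, 4),
                     dimnames = list(NULL, bases, bases)),
    pam = stats::setNames(rep(1.0, 16),
                          apply(expand.grid(bases, bases), 1, paste0,
                                collapse = ""))),
    class = "cfd_table")
})
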