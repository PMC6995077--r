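#' Count spacers in sequencing reads
#'
#' Translates reads into per-guide counts by extracting the 20-nt spacer
#' from each read and matching it exactly against the library. The spacer is
#' located either at a fixed 0-based `offset` or immediately after the first
#' occurrence of an `anchor` sequence (e.g. the vector sequence 5' of the
#' spacer). Reads whose anchor is absent or whose 20-mer matches no library
#' spacer are counted as unassigned; spacer sequences shared by more than
#' one library entry are counted to a shared ambiguity bin, never split.
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param library library tibble.
#' @param offset fixed 0-based position of the spacer in the read (used when
#'   `anchor` is `NULL`).
#' @param anchor optional anchor sequence; the spacer is read from the base
#'   after its first occurrence.
#' @return list with `counts` (tibble guide_id, count), `unassigned` (number
#'   of reads), `ambiguous` (number of reads matching shared spacers),
#'   `total` (reads seen).
#' @export
count_spacers <- function(fastq, library, offset = 0L, anchor = NULL) {
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) {
      stop("malformed FASTQ '", fastq, "': ", conditionMessage(e),
           call. = FALSE)
    })
  total <- length(reads)
  if (total > 0 && !is.null(anchor)) {
    pos <- regexpr(anchor, reads, fixed = TRUE)
    found <- pos > 0
    start <- as.integer(pos) + nchar(anchor)
    extracted <- ifelse(found & start + 19L <= nchar(reads),
                        substr(reads, start, start + 19L), NA_character_)
  } else if (total > 0) {
    extracted <- ifelse(offset + 20L <= nchar(reads),
                        substr(reads, offset + 1L, offset + 20L),
                        NA_character_)
  } else {
    extracted <- character(0)
  }
  spacer_n <- table(library$spacer)
  ambiguous_spacers <- names(spacer_n)[spacer_n > 1]
  unique_map <- library[!library$spacer %in% ambiguous_spacers, ]
  hit <- match(extracted, unique_map$spacer)
  is_amb <- !is.na(extracted) & extracted %in% ambiguous_spacers
  assigned <- !is.na(hit)
  tab <- table(factor(unique_map$guide_id[hit[assigned]],
                      levels = library$guide_id))
  counts <- tibble::tibble(guide_id = library$guide_id,
                           count = as.integer(tab[library$guide_id]))
  counts$count[is.na(counts$count)] <- 0L
  list(counts = counts,
       unassigned = sum(!assigned & !is_amb),
       ambiguous = sum(is_amb),
       total = total)
}

#' Median-ratio normalization of screen counts
#'
#' Size factors are the per-sample median of count ratios to the geometric
#' mean across samples (DESeq-style median-of-ratios), computed over guides
#' with nonzero counts in every sample. When fewer than 100 such guides
#' exist the method falls back to total-count scaling, recorded in the
#' `method_used` attribute.
#'
#' @param x a [screen_counts()] object.
#' @param method `"median_ratio"` (default) or `"total"`.
#' @return `x` with an added `normalized` tibble (guide_id + per-sample
#'   normalized counts) and `size_factors` named numeric.
#' @export
normalize_counts <- function(x, method = c("median_ratio", "total")) {
  method <- match.arg(method)
  mat <- as.matrix(x$counts[, -1])
  rownames(mat) <- x$counts$guide_id
  if (ncol(mat) < 2) stop("need >= 2 samples to normalize", call. = FALSE)
  if (any(colSums(mat) == 0)) {
    stop("sample '", colnames(mat)[colSums(mat) == 0][1],
         "' has all-zero counts", call. = FALSE)
  }
  method_used <- method
  if (method == "median_ratio") {
    nonzero <- rowSums(mat == 0) == 0
    if (sum(nonzero) < 100) {
      method_used <- "total"
    } else {
      sub <- mat[nonzero, , drop = FALSE]
      log_gm <- rowMeans(log(sub))
      sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_gm)))
    }
  }
  if (method_used == "total") {
    tot <- colSums(mat)
    sf <- tot / exp(mean(log(tot)))
  }
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1 for stability
  norm <- sweep(mat, 2, sf, "/")
  x$normalized <- tibble::as_tibble(cbind(x$counts[, "guide_id"],
                                          as.data.frame(norm)))
  x$size_factors <- sf
  attr(x$size_factors, "method_used") <- method_used
  x
}

#' Per-guide log2 fold changes versus the plasmid library
#'
#' For every condition sample, `lfc = log2((norm + pc) / (norm_pdna + pc))`
#' on normalized counts, with pseudocount `pc`; the per-guide mean over a
#' condition's replicates is the guide's summary fold change — abundance
#' change relative to the initial plasmid DNA pool.
#'
#' @param x a normalized [screen_counts()] object (see [normalize_counts()]).
#' @param pseudocount added to both numerator and denominator; default 0.5.
#' @return tibble: `guide_id`, `condition`, `replicate`, `sample`, `lfc`
#'   (long, one row per guide x replicate).
#' @export
guide_log2fc <- function(x, pseudocount = 0.5) {
  if (is.null(x$normalized)) x <- normalize_counts(x)
  norm <- x$normalized
  pdna_col <- x$samples$sample[x$samples$role == "pdna"]
  if (pseudocount <= 0) {
    if (any(as.matrix(norm[, -1]) == 0)) {
      stop("pseudocount must be > 0 when zero counts are present",
           call. = FALSE)
    }
  }
  ref <- norm[[pdna_col]]
  cond_samples <- x$samples[x$samples$role == "condition", ]
  purrr::map_dfr(seq_len(nrow(cond_samples)), function(i) {
    s <- cond_samples$sample[i]
    tibble::tibble(guide_id = norm$guide_id,
                   condition = cond_samples$condition[i],
                   replicate = cond_samples$replicate[i],
                   sample = s,
                   lfc = log2((norm[[s]] + pseudocount) /
                                (ref + pseudocount)))
  })
}

#' Summarize guide fold changes across replicates
#'
#' @param lfc long tibble from [guide_log2fc()].
#' @return tibble: guide_id, condition, n_replicates, mean_lfc.
#' @export
summarize_guide_lfc <- function(lfc) {
  lfc |>
    dplyr::group_by(.data$guide_id, .data$condition) |>
    dplyr::summarise(n_replicates = dplyr::n(),
                     mean_lfc = mean(.data$lfc), .groups = "drop")
}

#' Replicate concordance of guide fold changes
#'
#' Correlation of per-replicate log2 fold-change vectors for every replicate
#' pair within each condition. Pearson by default; Spearman available.
#' Zero-variance vectors are flagged (`undefined = TRUE`, `r = NA`) rather
#' than propagating NaN.
#'
#' @param lfc long tibble from [guide_log2fc()].
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble: condition, replicate_a, replicate_b, r, undefined.
#' @export
replicate_correlation <- function(lfc, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- tidyr::pivot_wider(
    lfc[, c("guide_id", "condition", "replicate", "lfc")],
    names_from = "replicate", values_from = "lfc")
  purrr::map_dfr(split(wide, wide$condition), function(w) {
    reps <- setdiff(names(w), c("guide_id", "condition"))
    if (length(reps) < 2) return(NULL)
    pairs <- utils::combn(reps, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      a <- w[[p[1]]]; b <- w[[p[2]]]
      undef <- stats::sd(a) == 0 || stats::sd(b) == 0
      tibble::tibble(condition = w$condition[1],
                     replicate_a = as.integer(p[1]),
                     replicate_b = as.integer(p[2]),
                     r = if (undef) NA_real_ else
                       stats::cor(a, b, method = method),
                     undefined = undef)
    })
  })
}

#' Empirical guide significance against non-targeting controls
#'
#' Two-sided empirical p-value of each targeting guide's mean fold change
#' against the non-targeting control distribution, with add-one smoothing:
#' `p = (1 + #{|control lfc| >= |observed lfc|}) / (1 + n_controls)`.
#' Benjamini-Hochberg adjustment is applied across all targeting guides
#' within each condition.
#'
#' @param guide_lfc tibble from [summarize_guide_lfc()].
#' @param library library tibble (supplies guide categories).
#' @return tibble of targeting guides: guide_id, condition, mean_lfc,
#'   empirical_p, fdr.
#' @export
guide_significance <- function(guide_lfc, library) {
  tagged <- dplyr::left_join(guide_lfc,
                             library[, c("guide_id", "category", "peak_id")],
                             by = "guide_id")
  ctrl <- dplyr::filter(tagged, .data$category == "nontargeting_control")
  if (nrow(ctrl) == 0) {
    stop("no non-targeting control guides in the library; cannot anchor ",
         "the null distribution", call. = FALSE)
  }
  targeting <- dplyr::filter(tagged, .data$category == "peak")
  purrr::map_dfr(split(targeting, targeting$condition), function(tg) {
    null_lfc <- ctrl$mean_lfc[ctrl$condition == tg$condition[1]]
    if (length(null_lfc) < 50) {
      warning("only ", length(null_lfc), " non-targeting controls for ",
              "condition '", tg$condition[1], "'; empirical p-values will ",
              "be coarse", call. = FALSE)
    }
    p <- empirical_p(tg$mean_lfc, null_lfc)
    tibble::tibble(guide_id = tg$guide_id, condition = tg$condition,
                   peak_id = tg$peak_id, mean_lfc = tg$mean_lfc,
                   empirical_p = p,
                   fdr = stats::p.adjust(p, method = "BH"))
  })
}

# two-sided add-one-smoothed empirical p of obs against null draws
empirical_p <- function(obs, null) {
  null_abs <- sort(abs(null))
  n <- length(null_abs)
  exceed <- n - findInterval(abs(obs) - 1e-12, null_abs)
  (1 + exceed) / (1 + n)
}

#' Aggregate guide statistics to peak level
#'
#' A peak's fold change is the exact median of its member guides' mean
#' fold changes. Significance is empirical: the observed median is compared
#' against `n_perm` medians of equal-size random draws from the
#' non-targeting control fold-change pool (two-sided, add-one smoothed),
#' with BH adjustment across peaks within each condition. Peaks losing all
#' guides upstream are absent (the count of such peaks is not a concern of
#' this function — design summaries report it).
#'
#' @param guide_stats tibble from [guide_significance()] (needs `peak_id`,
#'   `mean_lfc`, `condition`).
#' @param guide_lfc tibble from [summarize_guide_lfc()] (supplies the
#'   control pool).
#' @param library library tibble.
#' @param n_perm permutation draws per peak size; default 10000.
#' @param rng_seed integer seed for the permutation draws.
#' @param genes optional gene tibble; adds `tss_distance` from the peak
#'   midpoint when `peaks` is also given.
#' @param peaks optional peak tibble (midpoints for TSS distances).
#' @return tibble: peak_id, condition, n_guides, median_lfc, empirical_p,
#'   fdr, and tss_distance when annotatable.
#' @export
aggregate_peaks <- function(guide_stats, guide_lfc, library,
                            n_perm = 10000L, rng_seed = 1L, genes = NULL,
                            peaks = NULL) {
  ctrl_ids <- library$guide_id[library$category == "nontargeting_control"]
  out <- purrr::map_dfr(split(guide_stats, guide_stats$condition),
                        function(gs) {
    cond <- gs$condition[1]
    pool <- guide_lfc$mean_lfc[guide_lfc$condition == cond &
                                 guide_lfc$guide_id %in% ctrl_ids]
    if (length(pool) == 0) {
      stop("empty non-targeting control pool for condition '", cond, "'",
           call. = FALSE)
    }
    peak_tbl <- gs |>
      dplyr::group_by(.data$peak_id) |>
      dplyr::summarise(n_guides = dplyr::n(),
                       median_lfc = stats::median(.data$mean_lfc),
                       .groups = "drop")
    # one shared null per guide-count stratum
    p <- with_seed(rng_seed + match(cond, sort(unique(guide_stats$condition))),
                   {
      null_by_size <- lapply(
        stats::setNames(nm = sort(unique(peak_tbl$n_guides))),
        function(k) {
          draws <- matrix(sample(pool, as.integer(k) * n_perm,
                                 replace = TRUE), ncol = as.integer(k))
          sort(abs(row_medians(draws)))
        })
      vapply(seq_len(nrow(peak_tbl)), function(i) {
        null_abs <- null_by_size[[as.character(peak_tbl$n_guides[i])]]
        exceed <- length(null_abs) -
          findInterval(abs(peak_tbl$median_lfc[i]) - 1e-12, null_abs)
        (1 + exceed) / (1 + length(null_abs))
      }, numeric(1))
    })
    dplyr::mutate(peak_tbl, condition = cond, empirical_p = p,
                  fdr = stats::p.adjust(p, method = "BH"))
  })
  out <- out[, c("peak_id", "condition", "n_guides", "median_lfc",
                 "empirical_p", "fdr")]
  if (!is.null(genes) && !is.null(peaks)) {
    mid <- dplyr::mutate(peaks,
                         cut_pos = .data$start +
                           (.data$end - .data$start) %/% 2L,
                         peak_id = .data$id)
    d <- tss_distance(mid, genes)
    out <- dplyr::left_join(out,
                            d[, c("peak_id", "tss_distance")] |>
                              dplyr::rename(tss_distance2 = "tss_distance") |>
                              dplyr::distinct(.data$peak_id,
                                              .keep_all = TRUE),
                            by = "peak_id") |>
      dplyr::rename(tss_distance = "tss_distance2")
  }
  out
}

row_medians <- function(m) {
  apply(m, 1, stats::median)
}

#' Distance to the nearest annotated TSS
#'
#' For guides the anchor is the cut position; for peaks pass midpoints in a
#' `cut_pos` column. Distance is `min |anchor - tss|` over all TSSs on the
#' same contig, unsigned, 0 at a TSS. Items on contigs without genes get
#' `NA` with `tss_available = FALSE`.
#'
#' @param items tibble with `chrom` and `cut_pos` columns (plus any id
#'   columns, preserved).
#' @param genes gene tibble from [read_gene_table()].
#' @return `items` with `tss_distance`, `nearest_gene`, `tss_available`
#'   appended.
#' @export
tss_distance <- function(items, genes) {
  if (nrow(genes) == 0) stop("gene table is empty", call. = FALSE)
  out <- items
  out$tss_distance <- NA_integer_
  out$nearest_gene <- NA_character_
  for (chrom in unique(items$chrom)) {
    if (is.na(chrom)) next
    g <- genes[genes$chrom == chrom, ]
    idx <- which(items$chrom == chrom)
    if (nrow(g) == 0) next
    ord <- order(g$tss)
    tss_sorted <- g$tss[ord]
    gene_sorted <- g$gene_id[ord]
    pos <- items$cut_pos[idx]
    right <- findInterval(pos, tss_sorted) # index of tss <= pos (rightmost)
    left_d <- ifelse(right >= 1, pos - tss_sorted[pmax(right, 1)], NA)
    right_d <- ifelse(right < length(tss_sorted),
                      tss_sorted[pmin(right + 1, length(tss_sorted))] - pos,
                      NA)
    use_left <- !is.na(left_d) & (is.na(right_d) | left_d <= right_d)
    out$tss_distance[idx] <- as.integer(ifelse(use_left, left_d, right_d))
    out$nearest_gene[idx] <- ifelse(use_left,
                                    gene_sorted[pmax(right, 1)],
                                    gene_sorted[pmin(right + 1,
                                                     length(tss_sorted))])
  }
  out$tss_available <- !is.na(out$tss_distance)
  out
}

#' Classify items by TSS proximity
#'
#' Items at most `threshold` bp from the nearest TSS are `"proximal"`
#' (a distance of exactly the threshold counts as proximal), the rest
#' `"distal"`.
#'
#' @param distances tibble from [tss_distance()].
#' @param threshold bp; default 10 kb.
#' @return `distances` with a `tss_class` column.
#' @export
classify_tss_proximity <- function(distances, threshold = 10000L) {
  dplyr::mutate(distances,
                tss_class = dplyr::case_when(
                  !.data$tss_available ~ NA_character_,
                  .data$tss_distance <= threshold ~ "proximal",
                  TRUE ~ "distal"))
}

#' Analyze a pooled screen end to end
#'
#' Runs normalization, per-guide log2 fold changes versus the plasmid
#' library, replicate correlations, control-anchored guide significance,
#' and median peak aggregation with permutation significance; optionally
#' annotates TSS distances. Returns a `screen_fit` object with
#' broom-style [generics::tidy()] and [generics::glance()] methods.
#'
#' @param x a [screen_counts()] object.
#' @param library library tibble.
#' @param pseudocount passed to [guide_log2fc()].
#' @param n_perm,rng_seed passed to [aggregate_peaks()].
#' @param genes,peaks optional annotation for TSS distances.
#' @param cor_method passed to [replicate_correlation()].
#' @return object of class `screen_fit`.
#' @export
analyze_screen <- function(x, library, pseudocount = 0.5, n_perm = 10000L,
                           rng_seed = 1L, genes = NULL, peaks = NULL,
                           cor_method = "pearson") {
  x <- normalize_counts(x)
  lfc <- guide_log2fc(x, pseudocount = pseudocount)
  glfc <- summarize_guide_lfc(lfc)
  gs <- guide_significance(glfc, library)
  ps <- aggregate_peaks(gs, glfc, library, n_perm = n_perm,
                        rng_seed = rng_seed, genes = genes, peaks = peaks)
  rc <- replicate_correlation(lfc, method = cor_method)
  structure(list(counts = x, lfc = lfc, guide_lfc = glfc,
                 guide_stats = gs, peak_stats = ps,
                 replicate_cor = rc,
                 size_factors = x$size_factors),
            class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat("screen_fit\n")
  cat("  guides analyzed: ", length(unique(x$guide_lfc$guide_id)), "\n",
      sep = "")
  cat("  peaks analyzed:  ", length(unique(x$peak_stats$peak_id)), "\n",
      sep = "")
  for (cond in unique(x$peak_stats$condition)) {
    sig <- sum(x$peak_stats$fdr[x$peak_stats$condition == cond] < 0.05)
    cat("  ", cond, ": ", sig, " peaks at FDR < 0.05\n", sep = "")
  }
  invisible(x)
}

#' Tidy a screen fit
#'
#' @param x a `screen_fit`.
#' @param type `"peaks"` (default), `"guides"`, or `"replicates"`.
#' @param ... unused.
#' @return tibble of the requested statistics.
#' @method tidy screen_fit
#' @export
tidy.screen_fit <- function(x, type = c("peaks", "guides", "replicates"),
                            ...) {
  type <- match.arg(type)
  switch(type,
         peaks = x$peak_stats,
         guides = x$guide_stats,
         replicates = x$replicate_cor)
}

#' One-row summary of a screen fit
#'
#' @param x a `screen_fit`.
#' @param fdr_threshold significance threshold; default 0.05.
#' @param ... unused.
#' @return one-row tibble: guide and peak totals, hit counts, mean
#'   replicate correlation.
#' @method glance screen_fit
#' @export
glance.screen_fit <- function(x, fdr_threshold = 0.05, ...) {
  tibble::tibble(
    n_guides = length(unique(x$guide_lfc$guide_id)),
    n_peaks = length(unique(x$peak_stats$peak_id)),
    n_peaks_enriched = sum(x$peak_stats$fdr < fdr_threshold &
                             x$peak_stats$median_lfc > 0),
    n_peaks_depleted = sum(x$peak_stats$fdr < fdr_threshold &
                             x$peak_stats$median_lfc < 0),
    mean_replicate_r = mean(x$replicate_cor$r, na.rm = TRUE))
}

#' Write the analysis result tables
#'
#' Emits the guide-level, peak-level and replicate-correlation TSVs with
#' stable column names.
#'
#' @param fit a `screen_fit`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_screen_tables <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(guides = file.path(dir, "guide_stats.tsv"),
             peaks = file.path(dir, "peak_stats.tsv"),
             replicates = file.path(dir, "replicate_correlation.tsv"))
  wide_lfc <- tidyr::pivot_wider(
    fit$lfc[, c("guide_id", "condition", "replicate", "lfc")],
    names_from = c("condition", "replicate"), values_from = "lfc",
    names_glue = "lfc_{condition}_rep{replicate}")
  readr::write_tsv(dplyr::left_join(fit$guide_stats, wide_lfc,
                                    by = "guide_id"), paths["guides"])
  readr::write_tsv(fit$peak_stats, paths["peaks"])
  readr::write_tsv(fit$replicate_cor, paths["replicates"])
  invisible(paths)
}
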