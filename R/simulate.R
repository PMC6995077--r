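#' Simulation configuration
#'
#' Bundles the parameters of the synthetic screen. The defaults are the
#' study conditions the package's recovery properties are stated at: a
#' 200-peak landscape with 10 enriched and 10 depleted peaks at +/-1.5
#' log2 fold change, 4 guides per peak, 500 non-targeting controls,
#' biological triplicate, a mean depth of 500 reads per guide, and
#' negative-binomial counts with dispersion 0.1.
#'
#' @param genome_length total bp across contigs; default 6e5.
#' @param n_contigs number of contigs; default 2.
#' @param gc_content background GC fraction; default 0.41 (human-like).
#' @param n_peaks number of planted peaks; default 200.
#' @param peak_width bp; default 300.
#' @param motifs_per_peak vector of possible motif counts per peak, sampled
#'   uniformly; default `1:2`.
#' @param n_genes number of genes; default 40.
#' @param fraction_coding fraction of genes flagged protein-coding.
#' @param n_enriched_peaks,n_depleted_peaks peaks with planted effects.
#' @param effect_lfc planted effect magnitude in log2 units; default 1.5.
#' @param guides_per_peak guides per peak in [simulate_library()].
#' @param n_nontargeting non-targeting controls in [simulate_library()].
#' @param n_replicates replicates of the screened condition; default 3.
#' @param mean_depth mean reads per guide; default 500.
#' @param nb_dispersion negative-binomial dispersion; default 0.1.
#' @param rng_seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 600000L, n_contigs = 2L,
                       gc_content = 0.41, n_peaks = 200L, peak_width = 300L,
                       motifs_per_peak = 1:2, n_genes = 40L,
                       fraction_coding = 0.8, n_enriched_peaks = 10L,
                       n_depleted_peaks = 10L, effect_lfc = 1.5,
                       guides_per_peak = 4L, n_nontargeting = 500L,
                       n_replicates = 3L, mean_depth = 500,
                       nb_dispersion = 0.1, rng_seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs), gc_content = gc_content,
              n_peaks = as.integer(n_peaks),
              peak_width = as.integer(peak_width),
              motifs_per_peak = as.integer(motifs_per_peak),
              n_genes = as.integer(n_genes),
              fraction_coding = fraction_coding,
              n_enriched_peaks = as.integer(n_enriched_peaks),
              n_depleted_peaks = as.integer(n_depleted_peaks),
              effect_lfc = effect_lfc,
              guides_per_peak = as.integer(guides_per_peak),
              n_nontargeting = as.integer(n_nontargeting),
              n_replicates = as.integer(n_replicates),
              mean_depth = mean_depth, nb_dispersion = nb_dispersion,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$genome_length > 0, cfg$n_contigs > 0,
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$n_peaks >= 0, cfg$peak_width > 20,
            all(cfg$motifs_per_peak >= 0), cfg$n_genes >= 0,
            cfg$n_enriched_peaks + cfg$n_depleted_peaks <= cfg$n_peaks,
            is.finite(cfg$effect_lfc), cfg$n_replicates >= 1,
            cfg$mean_depth > 0, cfg$nb_dispersion >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with planted peaks, motifs and genes
#'
#' Background sequence is i.i.d. at the configured GC content. Peaks are
#' placed without overlap in the proximal 40% of each contig; each
#' peak is seeded with dyad motifs drawn from the default pattern (CWWG
#' half-sites, W uniform over A/T, spacer length uniform over 2-12).
#' Genes are placed in two strata so TSS-distance classes exist: half have
#' their TSS within 10 kb of a peak ("proximal") and half sit in the distal
#' tail of the contig, more than 100 kb from every peak. A subset of peaks
#' carries planted enrichment/depletion effects.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `peaks` (tibble),
#'   `genes` (tibble), `truth` (list: `motifs` tibble of planted motif
#'   coordinates, `peak_effects` tibble with `true_lfc`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  contig_len <- rep(cfg$genome_length %/% cfg$n_contigs, cfg$n_contigs)
  contig_len[1] <- contig_len[1] + cfg$genome_length %% cfg$n_contigs
  contig_names <- paste0("chr", seq_len(cfg$n_contigs))
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  genome <- stats::setNames(vapply(contig_len, function(L) {
    paste0(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1)), contig_names)

  # peaks: non-overlapping, confined to [1 kb, 60% of contig]
  peaks_per_contig <- table(factor(
    rep(seq_len(cfg$n_contigs), length.out = cfg$n_peaks),
    levels = seq_len(cfg$n_contigs)))
  peak_rows <- list()
  for (ci in seq_len(cfg$n_contigs)) {
    k <- as.integer(peaks_per_contig[ci])
    if (k == 0) next
    L <- contig_len[ci]
    lo <- 1000L
    hi <- as.integer(0.4 * L) - cfg$peak_width
    if (hi <= lo || (hi - lo) < k * (cfg$peak_width + 50L)) {
      stop("cannot place ", k, " non-overlapping peaks of width ",
           cfg$peak_width, " on a ", L, " bp contig", call. = FALSE)
    }
    # slot-based placement guarantees no overlap
    slot <- (hi - lo) %/% k
    offs <- sample.int(max(slot - cfg$peak_width, 1L), k, replace = TRUE)
    starts <- lo + (seq_len(k) - 1L) * slot + offs
    peak_rows[[ci]] <- tibble::tibble(chrom = contig_names[ci],
                                      start = starts,
                                      end = starts + cfg$peak_width)
  }
  peaks <- dplyr::bind_rows(peak_rows)
  if (nrow(peaks) > 0) {
    peaks$id <- paste0("peak_", seq_len(nrow(peaks)))
    peaks$strand <- "."
    peaks <- peaks[, c("chrom", "start", "end", "id", "strand")]
  } else {
    peaks <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), id = character(),
                            strand = character())
  }

  # plant motifs inside peaks
  motif_rows <- list()
  for (i in seq_len(nrow(peaks))) {
    mpp <- cfg$motifs_per_peak
    k <- if (length(mpp) == 1L) mpp else sample(mpp, 1)
    if (k == 0) next
    placed <- place_motifs_in_peak(genome[[peaks$chrom[i]]], peaks[i, ], k)
    genome[[peaks$chrom[i]]] <- placed$seq
    motif_rows[[i]] <- placed$motifs
  }
  motifs <- dplyr::bind_rows(motif_rows)
  if (nrow(motifs) == 0) {
    motifs <- tibble::tibble(peak_id = character(), chrom = character(),
                             start = integer(), end = integer(),
                             spacer_len = integer())
  }

  genes <- simulate_genes(cfg, contig_names, contig_len, peaks)

  effect_idx <- sample.int(nrow(peaks),
                           cfg$n_enriched_peaks + cfg$n_depleted_peaks)
  true_lfc <- stats::setNames(rep(0, nrow(peaks)), peaks$id)
  true_lfc[effect_idx[seq_len(cfg$n_enriched_peaks)]] <- cfg$effect_lfc
  if (cfg$n_depleted_peaks > 0) {
    true_lfc[effect_idx[cfg$n_enriched_peaks +
                          seq_len(cfg$n_depleted_peaks)]] <- -cfg$effect_lfc
  }
  truth <- list(motifs = motifs,
                peak_effects = tibble::tibble(peak_id = peaks$id,
                                              true_lfc = unname(true_lfc)))
  list(genome = structure(genome, class = "genome"), peaks = peaks,
       genes = genes, truth = truth)
}

# overwrite background with k non-overlapping dyad motifs; W ~ U{A,T},
# spacer length ~ U{2..12}, spacer bases uniform ACGT
place_motifs_in_peak <- function(seq, peak, k) {
  width <- peak$end - peak$start
  spacer_len <- sample(2:12, k, replace = TRUE)
  motif_len <- 8L + spacer_len
  # lay motifs in disjoint slots of the peak
  slot <- width %/% k
  if (slot < max(motif_len) + 2L) {
    stop("peak too narrow for ", k, " motifs", call. = FALSE)
  }
  offs <- vapply(seq_len(k), function(j) {
    sample.int(slot - motif_len[j] - 1L, 1)
  }, integer(1))
  starts <- peak$start + (seq_len(k) - 1L) * slot + offs
  arm <- function() paste0("C", paste0(sample(c("A", "T"), 2, replace = TRUE),
                                       collapse = ""), "G")
  for (j in seq_len(k)) {
    motif_seq <- paste0(arm(),
                        paste0(sample(c("A", "C", "G", "T"), spacer_len[j],
                                      replace = TRUE), collapse = ""),
                        arm())
    substr(seq, starts[j] + 1L, starts[j] + motif_len[j]) <- motif_seq
  }
  list(seq = seq,
       motifs = tibble::tibble(peak_id = peak$id, chrom = peak$chrom,
                               start = starts, end = starts + motif_len,
                               spacer_len = spacer_len))
}

simulate_genes <- function(cfg, contig_names, contig_len, peaks) {
  if (cfg$n_genes == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), coding = logical(),
                          tss = integer()))
  }
  gene_width <- 5000L
  n_prox <- if (nrow(peaks) == 0) 0L else cfg$n_genes %/% 2L
  rows <- list()
  # proximal: TSS 2-8 kb downstream of a random peak, body pointing away
  if (n_prox > 0 && nrow(peaks) > 0) {
    anchor <- peaks[sample.int(nrow(peaks), n_prox, replace = TRUE), ]
    offset <- sample(2000:8000, n_prox, replace = TRUE)
    tss <- anchor$end + offset
    rows$prox <- tibble::tibble(gene_id = paste0("gene_prox_", seq_len(n_prox)),
                                chrom = anchor$chrom, start = tss,
                                end = tss + gene_width, strand = "+")
  }
  # distal: in the contig tail, > 100 kb from every peak
  n_dist <- cfg$n_genes - n_prox
  if (n_dist > 0) {
    ci <- rep(seq_along(contig_names), length.out = n_dist)
    tail_lo <- vapply(seq_along(contig_names), function(i) {
      pk <- peaks[peaks$chrom == contig_names[i], ]
      max_pk_end <- if (nrow(pk) > 0) max(pk$end) else 0L
      as.integer(max_pk_end + 100001L)
    }, integer(1))
    tail_hi <- contig_len - gene_width - 100L
    if (any(tail_lo[unique(ci)] >= tail_hi[unique(ci)])) {
      stop("contigs too short to place distal genes > 100 kb from peaks",
           call. = FALSE)
    }
    start <- vapply(seq_len(n_dist), function(j) {
      i <- ci[j]
      as.integer(sample(seq(tail_lo[i], tail_hi[i]), 1))
    }, integer(1))
    rows$dist <- tibble::tibble(gene_id = paste0("gene_dist_", seq_len(n_dist)),
                                chrom = contig_names[ci], start = start,
                                end = start + gene_width,
                                strand = sample(c("+", "-"), n_dist,
                                                replace = TRUE))
  }
  genes <- dplyr::bind_rows(rows)
  genes$coding <- seq_len(nrow(genes)) <= round(cfg$fraction_coding *
                                                  nrow(genes))
  genes$coding <- sample(genes$coding)  # shuffle which genes are coding
  dplyr::mutate(genes,
                tss = dplyr::if_else(.data$strand == "+", .data$start,
                                     .data$end - 1L))
}

#' Build a direct guide library from simulation truth
#'
#' Constructs the library used by the count-level recovery analyses without
#' running the design pipeline: exactly `guides_per_peak` guides per peak
#' (synthetic spacers, attributed to the peak's first planted motif) plus
#' `n_nontargeting` non-targeting controls.
#'
#' @param sim output of [simulate_genome()] (only `peaks` and `truth` are
#'   used).
#' @param config a [sim_config()].
#' @return library tibble.
#' @export
simulate_library <- function(sim, config = sim_config()) {
  with_seed(config$rng_seed + 1L, {
    peaks <- sim$peaks
    bases <- c("A", "C", "G", "T")
    n_target <- nrow(peaks) * config$guides_per_peak
    n_total <- n_target + config$n_nontargeting
    spacers <- unique(vapply(seq_len(n_total + 100L), function(i) {
      paste0(sample(bases, 20, replace = TRUE), collapse = "")
    }, character(1)))[seq_len(n_total)]
    target <- tibble::tibble(
      guide_id = paste0(rep(peaks$id, each = config$guides_per_peak), ".1-",
                        rep(seq_len(config$guides_per_peak),
                            nrow(peaks))),
      spacer = spacers[seq_len(n_target)],
      pam = "AGG",
      chrom = rep(peaks$chrom, each = config$guides_per_peak),
      start = rep(peaks$start, each = config$guides_per_peak) +
        10L * rep(seq_len(config$guides_per_peak), nrow(peaks)),
      strand = "+",
      category = "peak",
      peak_id = rep(peaks$id, each = config$guides_per_peak))
    target$end <- target$start + 20L
    target$cut_pos <- target$end - 4L
    target$motif_ids <- as.list(paste0(target$peak_id, ".1"))
    target$id_motif <- paste0(target$peak_id, ".1")
    ntc <- make_synthetic_ntc(spacers[n_target + seq_len(config$n_nontargeting)])
    dplyr::bind_rows(target[, LIBRARY_COLUMNS_FULL], ntc)
  })
}

LIBRARY_COLUMNS_FULL <- c("guide_id", "spacer", "pam", "chrom", "start",
                          "end", "strand", "cut_pos", "category", "peak_id",
                          "motif_ids", "id_motif")

make_synthetic_ntc <- function(spacers) {
  n <- length(spacers)
  tibble::tibble(guide_id = paste0("nontargeting_", seq_len(n)),
                 spacer = spacers, pam = NA_character_,
                 chrom = NA_character_, start = NA_integer_,
                 end = NA_integer_, strand = NA_character_,
                 cut_pos = NA_integer_,
                 category = "nontargeting_control",
                 peak_id = NA_character_,
                 motif_ids = replicate(n, character(0), simplify = FALSE),
                 id_motif = NA_character_)
}

#' Simulate screen counts with known ground truth
#'
#' Per-guide plasmid (pDNA) abundance is log-normal (sdlog 0.5) scaled to
#' `mean_depth`; a guide's expected abundance in the screened condition is
#' the pDNA mean times `2^(true_lfc * efficiency)`, where the peak-level
#' `true_lfc` comes from the simulation truth and per-guide efficiency
#' multipliers are Beta(2,1) draws (guides vary in potency). Counts are
#' negative binomial with the configured dispersion (Poisson in the
#' dispersion-zero limit). Non-targeting controls have true fold change 0.
#'
#' @param library library tibble (e.g. [simulate_library()] or a designed
#'   library).
#' @param truth `truth` element of [simulate_genome()] (uses
#'   `peak_effects`).
#' @param config a [sim_config()].
#' @param condition name for the screened condition; default `"screen"`.
#' @return a [screen_counts()] object; per-guide expectations are attached
#'   as attribute `guide_truth` (tibble guide_id, true_lfc, efficiency).
#' @export
simulate_counts <- function(library, truth, config = sim_config(),
                            condition = "screen") {
  if (config$mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  with_seed(config$rng_seed + 2L, {
    n <- nrow(library)
    effects <- stats::setNames(truth$peak_effects$true_lfc,
                               truth$peak_effects$peak_id)
    peak_lfc <- ifelse(is.na(library$peak_id), 0,
                       effects[library$peak_id])
    peak_lfc[is.na(peak_lfc)] <- 0
    efficiency <- ifelse(library$category == "peak",
                         stats::rbeta(n, 2, 1), 1)
    true_lfc <- peak_lfc * efficiency
    pdna_mu <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
    pdna_mu <- pdna_mu / mean(pdna_mu) * config$mean_depth
    rnb <- function(mu) {
      if (config$nb_dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    cols <- list(guide_id = library$guide_id,
                 pdna = as.integer(rnb(pdna_mu)))
    cond_mu <- pdna_mu * 2 ^ true_lfc
    for (r in seq_len(config$n_replicates)) {
      cols[[paste0(condition, "_rep", r)]] <- as.integer(rnb(cond_mu))
    }
    counts <- tibble::as_tibble(cols)
    out <- screen_counts(counts, pdna = "pdna")
    attr(out, "guide_truth") <- tibble::tibble(guide_id = library$guide_id,
                                               true_lfc = true_lfc,
                                               efficiency = efficiency)
    out
  })
}

#' Simulate sequencing reads from a count vector
#'
#' Emits exactly `count` reads per guide, each read `prefix + anchor +
#' spacer + suffix`, optionally corrupted with uniform per-base errors, and
#' writes a FASTQ file. The per-guide manifest is returned for bookkeeping.
#'
#' @param counts tibble with `guide_id` and `count` (e.g. one column of a
#'   [screen_counts()] object).
#' @param library library tibble (spacer lookup).
#' @param path output FASTQ path.
#' @param anchor vector sequence placed immediately 5' of the spacer.
#' @param prefix_len random bases before the anchor.
#' @param suffix_len random bases after the spacer.
#' @param error_rate per-base substitution probability; default 0.
#' @param rng_seed integer seed.
#' @return tibble manifest (guide_id, n_reads), invisibly; the FASTQ is
#'   written to `path`.
#' @export
simulate_reads <- function(counts, library, path, anchor = "ACCG",
                           prefix_len = 5L, suffix_len = 5L,
                           error_rate = 0, rng_seed = 1L) {
  spacer <- stats::setNames(library$spacer, library$guide_id)
  unknown <- setdiff(counts$guide_id, names(spacer))
  if (length(unknown) > 0) {
    stop("counts reference guides absent from library: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  with_seed(rng_seed, {
    n_reads <- sum(counts$count)
    bases <- c("A", "C", "G", "T")
    # flanking bases exclude the anchor's first base so the first anchor
    # occurrence in every read is the planted one
    flank_bases <- setdiff(bases, substr(anchor, 1, 1))
    if (n_reads == 0) {
      readr::write_lines(character(0), path)
      return(invisible(tibble::tibble(guide_id = counts$guide_id,
                                      n_reads = counts$count)))
    }
    gid <- rep(counts$guide_id, counts$count)
    pre <- vapply(seq_len(n_reads), function(i) {
      paste0(sample(flank_bases, prefix_len, replace = TRUE), collapse = "")
    }, character(1))
    suf <- vapply(seq_len(n_reads), function(i) {
      paste0(sample(bases, suffix_len, replace = TRUE), collapse = "")
    }, character(1))
    reads <- paste0(pre, anchor, spacer[gid], suf)
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1]]
        hit <- stats::runif(length(ch)) < error_rate
        ch[hit] <- sample(bases, sum(hit), replace = TRUE)
        paste0(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    qual <- strrep("I", nchar(reads))
    fq <- character(4L * n_reads)
    fq[seq(1, length(fq), 4)] <- paste0("@read_", seq_len(n_reads), "_", gid)
    fq[seq(2, length(fq), 4)] <- reads
    fq[seq(3, length(fq), 4)] <- "+"
    fq[seq(4, length(fq), 4)] <- qual
    readr::write_lines(fq, path)
    invisible(tibble::tibble(guide_id = counts$guide_id,
                             n_reads = counts$count))
  })
}
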