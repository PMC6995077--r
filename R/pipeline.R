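# Orchestration layer: each run_* function wires a pipeline stage from
# files to files, and writes a manifest (config, input checksums, package
# version) so any run is reproducible from its manifest alone. These are
# the functions the exec/peakscreen command-line script dispatches to.

write_manifest <- function(out_dir, subcommand, config, inputs) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  manifest <- list(tool = "peakscreen",
                   version = as.character(utils::packageVersion("peakscreen")),
                   subcommand = subcommand,
                   config = config,
                   input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a complete synthetic fixture directory
#'
#' Writes a simulated genome (FASTA), peaks (BED), genes (TSV), ground
#' truth (TSVs), a direct library (TSV) and simulated screen counts (TSV)
#' plus a manifest, all derived from one [sim_config()].
#'
#' @param out_dir output directory (created).
#' @param config a [sim_config()].
#' @return tibble of files written, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  library <- simulate_library(sim, config)
  counts <- simulate_counts(library, sim$truth, config)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             peaks = file.path(out_dir, "peaks.bed"),
             genes = file.path(out_dir, "genes.tsv"),
             truth_motifs = file.path(out_dir, "truth_motifs.tsv"),
             truth_effects = file.path(out_dir, "truth_peak_effects.tsv"),
             library = file.path(out_dir, "library.tsv"),
             counts = file.path(out_dir, "counts.tsv"))
  write_genome(sim$genome, paths["genome"])
  write_bed(sim$peaks, paths["peaks"])
  write_gene_table(sim$genes, paths["genes"])
  readr::write_tsv(sim$truth$motifs, paths["truth_motifs"])
  readr::write_tsv(sim$truth$peak_effects, paths["truth_effects"])
  write_library(library, paths["library"])
  write_count_table(counts, paths["counts"])
  write_manifest(out_dir, "simulate", unclass(config), list())
  invisible(tibble::tibble(file = names(paths), path = unname(paths)))
}

#' Design a peak-targeting library from files
#'
#' Composes the design pipeline: motif scan in peaks, PAM-window guide
#' enumeration, off-target filtering (rules A and B), and control
#' construction; writes the library TSV, the rejected-guides report, the
#' design summary, and a manifest.
#'
#' @param genome_path FASTA.
#' @param peaks_path BED of targeted peaks.
#' @param out_dir output directory (created).
#' @param genes_path optional gene TSV (needed for rule A and TSS summary).
#' @param pattern motif pattern string; default `"CWWG[N]{2,12}CWWG"`.
#' @param window PAM window, bp; default 16.
#' @param pam_pattern default `"NGG"`.
#' @param n_intergenic,n_nontargeting control counts; defaults 500 + 500.
#' @param min_gene_distance for intergenic controls; default 5000.
#' @param max_mm off-target search ceiling; default 3.
#' @param cfd_path optional CFD table TSV; packaged synthetic table used
#'   when `NULL`.
#' @param rng_seed integer seed (controls only; design is deterministic).
#' @return tibble of files written, invisibly.
#' @export
run_design <- function(genome_path, peaks_path, out_dir, genes_path = NULL,
                       pattern = "CWWG[N]{2,12}CWWG", window = 16L,
                       pam_pattern = "NGG", n_intergenic = 500L,
                       n_nontargeting = 500L, min_gene_distance = 5000L,
                       max_mm = 3L, cfd_path = NULL, rng_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome(genome_path)
  peaks <- read_bed(peaks_path)
  genes <- if (!is.null(genes_path)) read_gene_table(genes_path) else NULL
  cfd <- if (is.null(cfd_path)) load_cfd_table(max_mm_bound = max_mm)
         else load_cfd_table(cfd_path, max_mm_bound = max_mm)

  hits <- scan_peaks(genome, peaks, compile_pattern(pattern))
  guides <- assign_guide_ids(
    enumerate_guides(genome, hits, window = window,
                     pam_pattern = pam_pattern))
  filtered <- filter_guides(guides, genome, genes = genes, peaks = peaks,
                            table = cfd, max_mm = max_mm)
  intergenic <- if (n_intergenic > 0) {
    make_intergenic_controls(genome, genes = genes, peaks = peaks,
                             n = n_intergenic, pam_pattern = pam_pattern,
                             min_gene_distance = min_gene_distance,
                             rng_seed = rng_seed, table = cfd,
                             max_mm = max_mm)
  } else empty_control_tbl("intergenic_control")
  ntc <- make_nontargeting_controls(genome, n = n_nontargeting,
                                    rng_seed = rng_seed)
  library <- dplyr::bind_rows(filtered$kept, intergenic, ntc)

  paths <- c(library = file.path(out_dir, "library.tsv"),
             rejected = file.path(out_dir, "rejected_guides.tsv"),
             summary = file.path(out_dir, "design_summary.tsv"),
             log = file.path(out_dir, "design_log.txt"))
  write_library(library[, LIBRARY_COLUMNS], paths["library"])
  write_rejected_report(filtered$rejected, paths["rejected"])
  summ <- summarize_library(library, peaks = peaks, motifs = hits,
                            genes = genes)
  readr::write_tsv(summ$stats, paths["summary"])
  log_lines <- c(
    sprintf("peaks scanned: %d", nrow(peaks)),
    sprintf("motif hits: %d", nrow(hits)),
    sprintf("motifless peaks: %d", length(attr(hits, "motifless_peaks"))),
    sprintf("candidate guides: %d", nrow(guides)),
    sprintf("guides dropped for N in spacer: %d",
            attr(guides, "dropped_n") %||% 0L),
    sprintf("guides rejected rule A: %d",
            sum(filtered$rejected$rule == "A")),
    sprintf("guides rejected rule B: %d",
            sum(filtered$rejected$rule == "B")),
    sprintf("guides kept: %d", nrow(filtered$kept)),
    sprintf("intergenic controls: %d", nrow(intergenic)),
    sprintf("non-targeting controls: %d", nrow(ntc)))
  readr::write_lines(log_lines, paths["log"])
  write_manifest(out_dir, "design",
                 list(pattern = pattern, window = window,
                      pam_pattern = pam_pattern,
                      n_intergenic = n_intergenic,
                      n_nontargeting = n_nontargeting,
                      min_gene_distance = min_gene_distance,
                      max_mm = max_mm, rng_seed = rng_seed),
                 list(genome = genome_path, peaks = peaks_path))
  invisible(tibble::tibble(file = names(paths), path = unname(paths)))
}

#' Analyze a screen from files
#'
#' Reads a count table (or counts a FASTQ against the library first), runs
#' the full statistical pipeline ([analyze_screen()]), and writes the
#' guide-level, peak-level and replicate-correlation TSVs plus a manifest.
#'
#' @param counts_path count TSV, or `NULL` when `fastq_paths` is given.
#' @param library_path library TSV.
#' @param out_dir output directory (created).
#' @param fastq_paths named character vector of FASTQ paths (names become
#'   sample names) counted with [count_spacers()]; used when `counts_path`
#'   is `NULL`.
#' @param pdna name of the pDNA sample/column; default `"pdna"`.
#' @param genes_path,peaks_path optional annotation for TSS distances.
#' @param pseudocount,n_perm,rng_seed,cor_method analysis parameters.
#' @param anchor spacer anchor for FASTQ counting.
#' @return the `screen_fit`, invisibly; tables land in `out_dir`.
#' @export
run_analyze <- function(counts_path, library_path, out_dir,
                        fastq_paths = NULL, pdna = "pdna",
                        genes_path = NULL, peaks_path = NULL,
                        pseudocount = 0.5, n_perm = 10000L, rng_seed = 1L,
                        cor_method = "pearson", anchor = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  library <- read_library(library_path)
  if (is.null(counts_path)) {
    if (is.null(fastq_paths) || is.null(names(fastq_paths))) {
      stop("either counts_path or named fastq_paths must be given",
           call. = FALSE)
    }
    cols <- purrr::map(fastq_paths, function(fq) {
      count_spacers(fq, library, anchor = anchor)$counts$count
    })
    counts <- tibble::as_tibble(c(list(guide_id = library$guide_id), cols))
    x <- screen_counts(counts, pdna = pdna, library = library)
  } else {
    x <- read_count_table(counts_path, pdna = pdna, library = library)
  }
  genes <- if (!is.null(genes_path)) read_gene_table(genes_path) else NULL
  peaks <- if (!is.null(peaks_path)) read_bed(peaks_path) else NULL
  fit <- analyze_screen(x, library, pseudocount = pseudocount,
                        n_perm = n_perm, rng_seed = rng_seed,
                        genes = genes, peaks = peaks,
                        cor_method = cor_method)
  write_screen_tables(fit, out_dir)
  write_manifest(out_dir, "analyze",
                 list(pdna = pdna, pseudocount = pseudocount,
                      n_perm = n_perm, rng_seed = rng_seed,
                      cor_method = cor_method),
                 c(list(library = library_path),
                   if (!is.null(counts_path)) list(counts = counts_path)))
  invisible(fit)
}
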