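#' Read a genome from FASTA
#'
#' Parses a (possibly gzipped) FASTA file into a named character vector of
#' uppercase DNA sequences, one element per contig. Lowercase is uppercased,
#' `U` is converted to `T`, and any character outside `{A,C,G,T,N}` is an
#' error. Contig names must be unique and records non-empty.
#'
#' The parser is deliberately line-aware so that malformed input is reported
#' with the offending line number, which matters for hand-edited fixtures.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return named character vector of contig sequences; class `"genome"`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- lines != ""           # blank lines tolerated, numbering preserved
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0 || !startsWith(lines[1], ">")) {
    stop("FASTA parse error at line 1: expected header '>'", call. = FALSE)
  }
  header_idx <- which(startsWith(lines, ">"))
  names_raw <- sub("^>", "", lines[header_idx])
  contig_names <- sub("\\s.*$", "", names_raw)
  if (any(contig_names == "")) {
    bad <- line_no[header_idx[which(contig_names == "")[1]]]
    stop("FASTA parse error at line ", bad, ": empty header", call. = FALSE)
  }
  dup <- contig_names[duplicated(contig_names)]
  if (length(dup) > 0) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  block_end <- c(header_idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(header_idx), function(i) {
    from <- header_idx[i] + 1L
    to <- block_end[i]
    if (from > to) return("")
    paste0(lines[from:to], collapse = "")
  }, character(1))
  empty <- which(seqs == "")
  if (length(empty) > 0) {
    stop("FASTA parse error at line ", line_no[header_idx[empty[1]]],
         ": empty record '", contig_names[empty[1]], "'", call. = FALSE)
  }
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("contig '", contig_names[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(stats::setNames(seqs, contig_names), class = "genome")
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' Reads BED3/4/6 into a tibble of 0-based half-open intervals with columns
#' `chrom`, `start`, `end`, `id`, `strand`. Column 4 supplies `id` and
#' column 6 `strand` when present; intervals without a name are labelled
#' `peak_<n>` in file order, and missing strand is `"."`.
#'
#' @param path path to a BED file (plain or gzip).
#' @param id_prefix prefix for auto-assigned ids of unnamed intervals.
#' @return tibble with columns chrom, start, end, id, strand.
#' @export
read_bed <- function(path, id_prefix = "peak") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[lines != "" & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), id = character(),
                          strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("BED line ", which(ncol < 3)[1], " has fewer than 3 columns",
         call. = FALSE)
  }
  getf <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  start_chr <- getf(2); end_chr <- getf(3)
  if (any(!grepl("^-?[0-9]+$", start_chr)) || any(!grepl("^-?[0-9]+$", end_chr))) {
    stop("non-integer coordinate in BED file ", path, call. = FALSE)
  }
  start <- as.integer(start_chr); end <- as.integer(end_chr)
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop("BED line ", i, ": start (", start[i], ") must be < end (", end[i],
         ")", call. = FALSE)
  }
  if (any(start < 0)) stop("negative coordinate in BED file", call. = FALSE)
  id <- getf(4)
  auto <- is.na(id) | id == "" | id == "."
  id[auto] <- paste0(id_prefix, "_", seq_along(id))[auto]
  strand <- getf(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  out <- tibble::tibble(chrom = getf(1), start = start, end = end,
                        id = id, strand = strand)
  if (anyDuplicated(out$id)) {
    stop("duplicate interval id(s) in BED: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write intervals as BED
#'
#' Emits BED6 (`chrom start end id score strand`); the `score` column is the
#' optional `score` column of `x` (0 when absent).
#'
#' @param x tibble with chrom/start/end and optionally id, strand, score.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  id <- if ("id" %in% names(x)) x$id else paste0("feature_", seq_len(nrow(x)))
  strand <- if ("strand" %in% names(x)) x$strand else "."
  score <- if ("score" %in% names(x)) x$score else 0L
  out <- data.frame(x$chrom, x$start, x$end, id, score, strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `coding` (logical). The TSS is derived from the strand: `start` for `+`
#' genes and `end - 1` for `-` genes (0-based), and returned as a `tss`
#' column.
#'
#' @param path path to the TSV.
#' @return tibble with columns gene_id, chrom, start, end, strand, coding, tss.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character(),
                           coding = readr::col_logical()))
  required <- c("gene_id", "chrom", "start", "end", "strand", "coding")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!tbl$strand %in% c("+", "-"))) {
    bad <- tbl$strand[!tbl$strand %in% c("+", "-")][1]
    stop("unknown strand '", bad, "' in gene table (must be + or -)",
         call. = FALSE)
  }
  if (any(tbl$start >= tbl$end)) stop("gene with start >= end", call. = FALSE)
  dplyr::mutate(tbl,
                tss = dplyr::if_else(.data$strand == "+", .data$start,
                                     .data$end - 1L))
}

#' @rdname read_gene_table
#' @param genes gene tibble as returned by [read_gene_table()].
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes[, c("gene_id", "chrom", "start", "end", "strand",
                             "coding")], path)
  invisible(path)
}

# Fixed column order for library tables; motif_ids serialized comma-separated.
LIBRARY_COLUMNS <- c("guide_id", "spacer", "pam", "chrom", "start", "end",
                     "strand", "cut_pos", "category", "peak_id", "motif_ids")

GUIDE_CATEGORIES <- c("peak", "intergenic_control", "nontargeting_control",
                      "gene", "gene_control")

#' Read and write sgRNA library tables
#'
#' A library table is a TSV with one row per guide and the fixed columns
#' `guide_id, spacer, pam, chrom, start, end, strand, cut_pos, category,
#' peak_id, motif_ids` (the last comma-separated; empty for controls).
#' Coordinates are 0-based half-open protospacer loci; non-targeting
#' controls carry `NA` coordinates.
#'
#' @param path path to the TSV.
#' @return tibble with the library columns; `motif_ids` is a list-column of
#'   character vectors.
#' @export
read_library <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           guide_id = readr::col_character(),
                           spacer = readr::col_character(),
                           pam = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character(),
                           cut_pos = readr::col_integer(),
                           category = readr::col_character(),
                           peak_id = readr::col_character(),
                           motif_ids = readr::col_character()))
  missing <- setdiff(LIBRARY_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    stop("library table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_library(dplyr::mutate(
    tbl,
    motif_ids = purrr::map(.data$motif_ids, function(x) {
      if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
    })))
}

#' @rdname read_library
#' @param library library tibble.
#' @export
write_library <- function(library, path) {
  validate_library(library)
  flat <- dplyr::mutate(
    library,
    motif_ids = vapply(.data$motif_ids, paste0, character(1), collapse = ","))
  readr::write_tsv(flat[, LIBRARY_COLUMNS], path)
  invisible(path)
}

validate_library <- function(library) {
  if (anyDuplicated(library$guide_id)) {
    stop("duplicate guide_id in library: ",
         paste(utils::head(unique(
           library$guide_id[duplicated(library$guide_id)]), 3),
           collapse = ", "), call. = FALSE)
  }
  if (any(nchar(library$spacer) != 20L)) {
    stop("library spacers must be 20 nt", call. = FALSE)
  }
  bad <- setdiff(unique(library$category), GUIDE_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown guide category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  library
}

#' Read an sgRNA count table
#'
#' Reads a TSV whose first column is `guide_id` and remaining columns are
#' non-negative integer read counts, one per sample, and assembles a
#' [screen_counts()] object with the given plasmid-library reference column.
#'
#' @param path path to the count TSV.
#' @param pdna name of the plasmid DNA (pDNA) reference column.
#' @param sample_info optional tibble (`sample`, `condition`, `replicate`)
#'   describing the non-pDNA samples; derived from column names when absent.
#' @param library optional library tibble; count rows whose `guide_id` is not
#'   in the library trigger a warning listing the unmatched ids.
#' @return a `screen_counts` object.
#' @export
read_count_table <- function(path, pdna, sample_info = NULL, library = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tbl)[1] != "guide_id") {
    names(tbl)[1] <- "guide_id"
  }
  count_cols <- names(tbl)[-1]
  for (cc in count_cols) {
    v <- tbl[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("column '", cc, "' contains negative or non-integer counts",
           call. = FALSE)
    }
    tbl[[cc]] <- as.integer(v)
  }
  screen_counts(tbl, pdna = pdna, sample_info = sample_info,
                library = library)
}

#' Screen count container
#'
#' Bundles a guide-by-sample count tibble with its sample sheet. Exactly one
#' sample has role `"pdna"` (the plasmid library the screen started from);
#' every other sample belongs to a condition and replicate. When
#' `sample_info` is not supplied, conditions are parsed from column names of
#' the form `<condition>_rep<k>` (or `<condition>_r<k>`); names without a
#' replicate suffix become single-replicate conditions.
#'
#' @param counts tibble with `guide_id` plus one integer column per sample.
#' @param pdna name of the pDNA column.
#' @param sample_info optional tibble with columns sample, condition,
#'   replicate for the non-pDNA samples.
#' @param library optional library tibble used to reconcile guide ids.
#' @return object of class `screen_counts` with elements `counts` (tibble)
#'   and `samples` (tibble: sample, role, condition, replicate).
#' @export
screen_counts <- function(counts, pdna, sample_info = NULL, library = NULL) {
  counts <- tibble::as_tibble(counts)
  samples <- setdiff(names(counts), "guide_id")
  if (!pdna %in% samples) {
    stop("pDNA column '", pdna, "' not found in count table", call. = FALSE)
  }
  if (anyDuplicated(counts$guide_id)) {
    stop("duplicate guide_id in count table", call. = FALSE)
  }
  others <- setdiff(samples, pdna)
  if (is.null(sample_info)) {
    cond <- sub("_r(ep)?[0-9]+$", "", others)
    rep <- suppressWarnings(as.integer(sub("^.*_r(ep)?([0-9]+)$", "\\2",
                                           others)))
    rep[is.na(rep)] <- 1L
    sample_info <- tibble::tibble(sample = others, condition = cond,
                                  replicate = rep)
  } else {
    sample_info <- tibble::as_tibble(sample_info)
    missing <- setdiff(others, sample_info$sample)
    if (length(missing) > 0) {
      stop("sample_info missing sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sample_info <- sample_info[match(others, sample_info$sample), ]
  }
  sheet <- dplyr::bind_rows(
    tibble::tibble(sample = pdna, role = "pdna", condition = NA_character_,
                   replicate = NA_integer_),
    dplyr::mutate(sample_info, role = "condition")[, c("sample", "role",
                                                       "condition",
                                                       "replicate")])
  if (!is.null(library)) {
    unmatched <- setdiff(counts$guide_id, library$guide_id)
    if (length(unmatched) > 0) {
      warning(length(unmatched), " guide id(s) in counts absent from ",
              "library: ", paste(utils::head(unmatched, 5), collapse = ", "),
              if (length(unmatched) > 5) ", ..." else "", call. = FALSE)
    }
  }
  structure(list(counts = counts, samples = sheet), class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts: ", nrow(x$counts), " guides x ",
      nrow(x$samples), " samples\n", sep = "")
  cat("  pDNA: ", x$samples$sample[x$samples$role == "pdna"], "\n", sep = "")
  conds <- dplyr::count(x$samples[x$samples$role == "condition", ],
                        .data$condition)
  for (i in seq_len(nrow(conds))) {
    cat("  ", conds$condition[i], ": ", conds$n[i], " replicate(s)\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname read_count_table
#' @param x a `screen_counts` object.
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x$counts, path)
  invisible(path)
}
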