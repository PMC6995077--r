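make_lib <- function(spacers, categories = NULL, peak_ids = NULL) {
  n <- length(spacers)
  tibble::tibble(
    guide_id = paste0("g", seq_len(n)), spacer = spacers,
    category = categories %||% rep("peak", n),
    peak_id = peak_ids %||% rep("p1", n),
    motif_ids = replicate(n, character(0), simplify = FALSE))
}

test_that("spacer counting assigns exact matches and conserves reads", {
  set.seed(1)
  spacers <- vapply(1:4, function(i) random_dna(20), character(1))
  lib <- make_lib(c(spacers, spacers[4]))   # g4/g5 share a spacer
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(paste0("TTTTT", "ACCG", spacers[1], "GGAAA"),  # g1
             paste0("AA", "ACCG", spacers[2], "CCTTTTTT"),  # g2
             paste0("CC", "ACCG", sub("^.", "N", spacers[3]), "AA"), # mism
             paste0("GG", "ACCG", spacers[4], "TT"),        # ambiguous
             paste0("GGGG", spacers[1], "TTTTTTTT"))        # no anchor
  writeLines(as.vector(rbind(paste0("@r", 1:5), reads, "+",
                             strrep("I", nchar(reads)))), fq)
  res <- count_spacers(fq, lib, anchor = "ACCG")
  expect_identical(res$counts$count[res$counts$guide_id == "g1"], 1L)
  expect_identical(res$counts$count[res$counts$guide_id == "g2"], 1L)
  expect_identical(res$counts$count[res$counts$guide_id == "g3"], 0L)
  expect_identical(res$ambiguous, 1L)
  expect_identical(res$unassigned, 2L)
  # conservation: assigned + unassigned + ambiguous = total
  expect_identical(sum(res$counts$count) + res$unassigned + res$ambiguous,
                   res$total)

  writeLines(c("@r1", "ACGT", "MALFORMED"), fq)
  expect_error(count_spacers(fq, lib), "malformed FASTQ")
})

test_that("fixed-offset extraction works without an anchor", {
  set.seed(2)
  sp <- random_dna(20)
  lib <- make_lib(sp)
  fq <- withr::local_tempfile(fileext = ".fastq")
  read <- paste0("ACGTA", sp, "TT")
  writeLines(c("@r1", read, "+", strrep("I", nchar(read))), fq)
  expect_identical(count_spacers(fq, lib, offset = 5L)$counts$count, 1L)
  expect_identical(count_spacers(fq, lib, offset = 4L)$counts$count, 0L)
})

test_that("median-ratio size factors behave under symmetry and scaling", {
  set.seed(3)
  base <- as.integer(rnbinom(300, mu = 200, size = 10) + 1L)
  x <- screen_counts(tibble::tibble(guide_id = paste0("g", 1:300),
                                    pdna = base, s_rep1 = base,
                                    s_rep2 = 2L * base), pdna = "pdna")
  nx <- normalize_counts(x)
  sf <- nx$size_factors
  expect_equal(unname(sf["pdna"]), unname(sf["s_rep1"]))
  expect_equal(unname(sf["s_rep2"] / sf["s_rep1"]), 2)
  # normalized medians of ratios ~ 1 by construction
  norm <- as.matrix(nx$normalized[, -1])
  gm <- exp(rowMeans(log(norm)))
  expect_equal(apply(norm, 2, function(cc) median(cc / gm)),
               c(pdna = 1, s_rep1 = 1, s_rep2 = 1), tolerance = 1e-6)
})

test_that("normalization falls back to totals when few guides are shared", {
  x <- screen_counts(tibble::tibble(guide_id = paste0("g", 1:50),
                                    pdna = rep(c(10L, 0L), 25),
                                    s_rep1 = rep(c(0L, 10L), 25)),
                     pdna = "pdna")
  nx <- normalize_counts(x)
  expect_identical(attr(nx$size_factors, "method_used"), "total")

  x0 <- screen_counts(tibble::tibble(guide_id = "g1", pdna = 0L,
                                     s_rep1 = 0L), pdna = "pdna")
  expect_error(normalize_counts(x0), "all-zero")
})

test_that("median-ratio factors agree with the DESeq reference", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  mat <- matrix(rnbinom(400 * 3, mu = 300, size = 5) + 1L, ncol = 3,
                dimnames = list(paste0("g", 1:400),
                                c("pdna", "s_rep1", "s_rep2")))
  x <- screen_counts(tibble::as_tibble(cbind(
    tibble::tibble(guide_id = rownames(mat)), as.data.frame(mat))),
    pdna = "pdna")
  sf <- normalize_counts(x)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("log2 fold changes vs pDNA follow their closed form", {
  base <- rep(50L, 200)
  counts <- tibble::tibble(guide_id = paste0("g", 1:200), pdna = base,
                           s_rep1 = base)
  counts$pdna[1] <- 25L
  counts$s_rep1[1] <- 100L
  x <- normalize_counts(screen_counts(counts, pdna = "pdna"))
  expect_equal(unname(x$size_factors), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  lfc <- guide_log2fc(x, pseudocount = 0)
  expect_equal(lfc$lfc[lfc$guide_id == "g1"], 2)       # log2(100/25)
  expect_equal(lfc$lfc[lfc$guide_id == "g2"], 0)       # identical counts

  # pseudocount shrinks low-count fold changes, leaves high counts alone
  counts2 <- tibble::tibble(guide_id = c("lo", "hi", paste0("f", 1:150)),
                            pdna = c(2L, 20000L, rep(100L, 150)),
                            s_rep1 = c(8L, 80000L, rep(100L, 150)))
  x2 <- normalize_counts(screen_counts(counts2, pdna = "pdna"), "total")
  l_small <- guide_log2fc(x2, pseudocount = 0.5)
  l_big <- guide_log2fc(x2, pseudocount = 1)
  sf2 <- x2$size_factors
  lo_small <- l_small$lfc[l_small$guide_id == "lo"]
  lo_big <- l_big$lfc[l_big$guide_id == "lo"]
  expect_lt(abs(lo_big), abs(lo_small))
  hi_diff <- abs(l_big$lfc[l_big$guide_id == "hi"] -
                   l_small$lfc[l_small$guide_id == "hi"])
  expect_lt(hi_diff, 1e-3)

  counts3 <- tibble::tibble(guide_id = c("a", paste0("f", 1:150)),
                            pdna = c(0L, rep(10L, 150)),
                            s_rep1 = c(5L, rep(10L, 150)))
  x3 <- normalize_counts(screen_counts(counts3, pdna = "pdna"), "total")
  expect_error(guide_log2fc(x3, pseudocount = 0), "pseudocount")
})

test_that("replicate correlations hit the exact limiting cases", {
  lfc <- tibble::tibble(guide_id = rep(paste0("g", 1:10), 2),
                        condition = "c",
                        replicate = rep(1:2, each = 10),
                        sample = rep(c("r1", "r2"), each = 10),
                        lfc = c(1:10, 1:10))
  expect_equal(replicate_correlation(lfc)$r, 1)
  lfc$lfc[11:20] <- -(1:10)
  expect_equal(replicate_correlation(lfc)$r, -1)
  lfc$lfc[11:20] <- 0
  rc <- replicate_correlation(lfc)
  expect_true(rc$undefined)
  expect_true(is.na(rc$r))

  # independent replicates decorrelate
  set.seed(5)
  null_r <- replicate(10, {
    l <- tibble::tibble(guide_id = rep(paste0("g", 1:1000), 2),
                        condition = "c", replicate = rep(1:2, each = 1000),
                        sample = rep(c("r1", "r2"), each = 1000),
                        lfc = rnorm(2000))
    replicate_correlation(l)$r
  })
  expect_lt(max(abs(null_r)), 0.1)

  # spearman is invariant to monotone transforms
  l2 <- tibble::tibble(guide_id = rep(paste0("g", 1:50), 2),
                       condition = "c", replicate = rep(1:2, each = 50),
                       sample = rep(c("r1", "r2"), each = 50),
                       lfc = c(1:50, exp(1:50 / 10)))
  expect_equal(replicate_correlation(l2, method = "spearman")$r, 1)
})

test_that("empirical p-values follow the add-one smoothing formula", {
  ctrl_lfc <- c(seq(-0.5, 0.5, length.out = 999))
  glfc <- tibble::tibble(
    guide_id = c(paste0("t", 1:3), paste0("n", 1:999)),
    condition = "c", n_replicates = 3L,
    mean_lfc = c(0, 5, 0.25, ctrl_lfc))
  lib <- make_lib(vapply(1:1002, function(i) random_dna(20), character(1)),
                  categories = c(rep("peak", 3),
                                 rep("nontargeting_control", 999)),
                  peak_ids = c("p1", "p2", "p3", rep(NA, 999)))
  lib$guide_id <- glfc$guide_id
  gs <- guide_significance(glfc, lib)
  # more extreme than all 999 controls -> 1/1000
  expect_equal(gs$empirical_p[gs$guide_id == "t2"], 1 / 1000)
  # dead center of a symmetric null -> p ~ 1
  expect_gt(gs$empirical_p[gs$guide_id == "t1"], 0.99)
  # direct formula check
  expected <- (1 + sum(abs(ctrl_lfc) >= 0.25)) / (1 + 999)
  expect_equal(gs$empirical_p[gs$guide_id == "t3"], expected)

  expect_error(guide_significance(glfc[1:3, ], lib[1:3, ]), "non-targeting")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(6)
  for (i in 1:200) {
    p <- runif(sample(3:60, 1))
    expect_equal(p.adjust(p, method = "BH"), naive_bh(p))
  }
})

test_that("peak aggregation uses the exact median and a permutation null", {
  set.seed(7)
  n_ctrl <- 200
  ctrl_sp <- vapply(1:n_ctrl, function(i) random_dna(20), character(1))
  lib <- dplyr::bind_rows(
    make_lib(vapply(1:3, function(i) random_dna(20), character(1)),
             peak_ids = rep("pk", 3)),
    make_lib(ctrl_sp, categories = rep("nontargeting_control", n_ctrl),
             peak_ids = rep(NA_character_, n_ctrl)))
  lib$guide_id <- paste0("u", seq_len(nrow(lib)))
  glfc <- tibble::tibble(guide_id = lib$guide_id, condition = "c",
                         n_replicates = 3L,
                         mean_lfc = c(-1, 0, 3, rnorm(n_ctrl, 0, 0.3)))
  gs <- tibble::tibble(guide_id = lib$guide_id[1:3], condition = "c",
                       peak_id = "pk", mean_lfc = c(-1, 0, 3),
                       empirical_p = NA_real_, fdr = NA_real_)
  ps <- aggregate_peaks(gs, glfc, lib, n_perm = 2000, rng_seed = 17)
  expect_identical(ps$median_lfc, 0)        # median of (-1, 0, 3)
  expect_identical(ps$n_guides, 3L)
  expect_gt(ps$empirical_p, 0.5)            # null-centred peak
  expect_true(ps$empirical_p > 0 && ps$empirical_p <= 1)

  # reproducible under the seed
  ps2 <- aggregate_peaks(gs, glfc, lib, n_perm = 2000, rng_seed = 17)
  expect_identical(ps, ps2)
})

test_that("TSS distances are unsigned nearest distances with flags", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                          start = c(400L, 1900L), end = c(1000L, 2500L),
                          strand = c("+", "+"), coding = TRUE,
                          tss = c(400L, 1900L))
  items <- tibble::tibble(id = c("x", "y", "z"),
                          chrom = c("c1", "c1", "c2"),
                          cut_pos = c(1000L, 400L, 50L))
  d <- tss_distance(items, genes)
  expect_identical(d$tss_distance, c(600L, 0L, NA_integer_))
  expect_identical(d$tss_available, c(TRUE, TRUE, FALSE))
  expect_identical(d$nearest_gene[1], "a")
  expect_error(tss_distance(items, genes[0, ]), "empty")

  cls <- classify_tss_proximity(
    tibble::tibble(tss_distance = c(10000L, 10001L, NA),
                   tss_available = c(TRUE, TRUE, FALSE)))
  expect_identical(cls$tss_class, c("proximal", "distal", NA))
})
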