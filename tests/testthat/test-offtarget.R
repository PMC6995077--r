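cfd <- load_cfd_table()

test_that("the CFD table satisfies its structural invariants", {
  expect_true(all(cfd$mismatch >= 0 & cfd$mismatch <= 1))
  for (b in c("A", "C", "G", "T")) {
    expect_true(all(cfd$mismatch[, b, b] == 1))
  }
  expect_identical(unname(cfd$pam["GG"]), 1.0)
  expect_true(all(cfd$pam >= 0 & cfd$pam <= 1))
  # a 3-mismatch search bound provably contains all CFD = 1 sites
  expect_lte(cfd$n_unit_positions, 3L)
})

test_that("CFD scores are penalty products with unit matches", {
  spacer <- strrep("ACGT", 5)
  expect_identical(cfd_score(spacer, spacer, "TGG", cfd), 1.0)

  # one mismatch at position 1 equals the raw table entry
  raw <- readr::read_tsv(system.file("extdata",
                                     "cfd_penalties_synthetic.tsv",
                                     package = "peakscreen"),
                         show_col_types = FALSE, na = c("", "NA"))
  site <- spacer
  substr(site, 1, 1) <- "C"   # guide A vs site C at position 1
  entry <- raw$penalty[raw$kind == "mismatch" & raw$position == 1 &
                         raw$guide_base == "A" & raw$site_base == "C"]
  expect_equal(cfd_score(spacer, site, "AGG", cfd), entry)

  # second mismatch can only decrease the product
  site2 <- site
  substr(site2, 10, 10) <- "A"  # guide C vs site A at position 10
  expect_lte(cfd_score(spacer, site2, "AGG", cfd),
             cfd_score(spacer, site, "AGG", cfd))

  # NAG PAM discounts by the AG penalty
  expect_equal(cfd_score(spacer, spacer, "TAG", cfd),
               unname(cfd$pam["AG"]))

  expect_error(cfd_score(strrep("A", 19), spacer, "AGG", cfd), "20 nt")
})

test_that("appending mismatches never increases the CFD score", {
  set.seed(11)
  for (i in 1:50) {
    spacer <- random_dna(20)
    site <- spacer
    mism_pos <- sample(20, 4)
    prev <- 1.0
    for (p in mism_pos) {
      b <- substr(site, p, p)
      substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
      cur <- cfd_score(spacer, site, "GGG", cfd)
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("a second perfect copy is found as a CFD = 1 off-target", {
  set.seed(21)
  spacer <- random_dna(20)
  background <- random_dna(4000)
  seq <- plant(background, paste0(spacer, "AGG"), 500)
  seq <- plant(seq, paste0(spacer, "TGG"), 2500)
  g <- as_genome(c1 = seq)
  ots <- find_offtargets(g, spacer, table = cfd,
                         exclude_locus = list(chrom = "c1", start = 500L,
                                              strand = "+"))
  perfect <- ots[ots$n_mismatches == 0, ]
  expect_identical(perfect$start, 2500L)
  expect_identical(perfect$cfd, 1.0)

  # the same scan with no planted second copy finds no perfect site
  g2 <- as_genome(c1 = plant(background, paste0(spacer, "AGG"), 500))
  ots2 <- find_offtargets(g2, spacer, table = cfd,
                          exclude_locus = list(chrom = "c1", start = 500L,
                                               strand = "+"))
  expect_identical(nrow(ots2[ots2$n_mismatches == 0, ]), 0L)
})

test_that("a planted one-mismatch site scores exactly its table entry", {
  set.seed(31)
  spacer <- random_dna(20)
  site <- spacer
  substr(site, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(site, 5, 5))[1]
  g <- as_genome(c1 = plant(random_dna(2000), paste0(site, "CGG"), 900))
  ots <- find_offtargets(g, spacer, table = cfd)
  hit <- ots[ots$start == 900L & ots$strand == "+", ]
  expect_identical(hit$n_mismatches, 1L)
  expect_equal(hit$cfd,
               cfd$mismatch[5, substr(spacer, 5, 5), substr(site, 5, 5)])
})

test_that("the genome scan equals brute force on random genomes", {
  set.seed(41)
  for (i in 1:3) {
    g <- as_genome(cA = random_dna(12000), cB = random_dna(8000))
    spacer <- substr(g[["cA"]], 3001, 3020)   # a real genomic 20-mer
    got <- find_offtargets(g, spacer, max_mm = 3L, table = cfd)
    want <- naive_offtargets(g, spacer, max_mm = 3L)
    expect_identical(got[, c("chrom", "start", "strand", "site_seq", "pam",
                             "n_mismatches")],
                     want)
  }
})

# hand-constructed genome exercising both exclusion rules
rules_fixture <- function() {
  set.seed(51)
  spacer <- random_dna(20)
  background <- random_dna(30000)
  seq <- plant(background, paste0(spacer, "AGG"), 1000)    # intended site
  seq <- plant(seq, paste0(spacer, "TGG"), 10000)          # in coding gene
  seq <- plant(seq, paste0(spacer, "GGG"), 20000)          # intergenic
  seq <- plant(seq, paste0(spacer, "AGG"), 25000)          # intergenic
  g <- as_genome(c1 = seq)
  genes <- tibble::tibble(gene_id = "tp53", chrom = "c1", start = 9000L,
                          end = 12000L, strand = "+", coding = TRUE,
                          tss = 9000L)
  peaks <- tibble::tibble(chrom = "c1", start = 900L, end = 1200L,
                          id = "pk", strand = ".")
  guide <- tibble::tibble(guide_id = "pk.1-1", spacer = spacer, pam = "AGG",
                          chrom = "c1", start = 1000L, end = 1020L,
                          strand = "+", cut_pos = 1016L, category = "peak",
                          peak_id = "pk", motif_ids = list("pk.1"),
                          id_motif = "pk.1")
  list(g = g, genes = genes, peaks = peaks, guide = guide, spacer = spacer,
       background = background)
}

test_that("rule A rejects guides with a tolerated site in a coding gene", {
  f <- rules_fixture()
  res <- filter_guides(f$guide, f$g, genes = f$genes, peaks = f$peaks,
                       table = cfd)
  expect_identical(nrow(res$kept), 0L)
  expect_identical(res$rejected$rule, "A")
  expect_true(any(res$rejected$sites[[1]]$context == "coding_gene"))
})

test_that("rule B rejects only >1 tolerated site in unrelated noncoding", {
  f <- rules_fixture()
  # remove the coding-gene copy: two intergenic perfect sites remain -> B
  seq <- plant(f$background, paste0(f$spacer, "AGG"), 1000)
  seq <- plant(seq, paste0(f$spacer, "GGG"), 20000)
  seq <- plant(seq, paste0(f$spacer, "AGG"), 25000)
  g <- as_genome(c1 = seq)
  res <- filter_guides(f$guide, g, genes = f$genes, peaks = f$peaks,
                       table = cfd)
  expect_identical(res$rejected$rule, "B")
  expect_identical(nrow(res$rejected$sites[[1]]), 2L)

  # with a single intergenic copy the guide is kept
  seq1 <- plant(f$background, paste0(f$spacer, "AGG"), 1000)
  seq1 <- plant(seq1, paste0(f$spacer, "GGG"), 20000)
  g1 <- as_genome(c1 = seq1)
  res1 <- filter_guides(f$guide, g1, genes = f$genes, peaks = f$peaks,
                        table = cfd)
  expect_identical(nrow(res1$kept), 1L)
  expect_identical(nrow(res1$rejected), 0L)
})

test_that("guide filtering is order-independent", {
  set.seed(61)
  g <- as_genome(c1 = random_dna(20000))
  peaks <- tibble::tibble(chrom = "c1", start = c(2000L, 8000L),
                          end = c(2400L, 8400L), id = c("a", "b"),
                          strand = ".")
  hits <- scan_peaks(g, peaks)
  guides <- assign_guide_ids(enumerate_guides(g, hits))
  expect_gt(nrow(guides), 2)
  res1 <- filter_guides(guides, g, peaks = peaks, table = cfd)
  perm <- sample(nrow(guides))
  res2 <- filter_guides(guides[perm, ], g, peaks = peaks, table = cfd)
  expect_setequal(res1$kept$guide_id, res2$kept$guide_id)
  expect_setequal(res1$rejected$guide_id, res2$rejected$guide_id)
})

test_that("intergenic controls sit far from genes, off peaks, and replay", {
  set.seed(71)
  g <- as_genome(c1 = random_dna(40000))
  genes <- tibble::tibble(gene_id = "g1", chrom = "c1", start = 30000L,
                          end = 35000L, strand = "+", coding = TRUE,
                          tss = 30000L)
  peaks <- tibble::tibble(chrom = "c1", start = 1000L, end = 1400L,
                          id = "pk", strand = ".")
  expect_identical(nrow(make_intergenic_controls(g, genes, peaks, n = 0)),
                   0L)
  ctrl <- make_intergenic_controls(g, genes, peaks, n = 6,
                                   min_gene_distance = 2000L, rng_seed = 9)
  expect_identical(nrow(ctrl), 6L)
  expect_identical(unique(ctrl$category), "intergenic_control")
  for (i in seq_len(nrow(ctrl))) {
    gap <- max(0L, genes$start - ctrl$end[i], ctrl$start[i] - genes$end)
    expect_gte(gap, 2000L)
    expect_false(peaks$start < ctrl$end[i] && peaks$end > ctrl$start[i])
  }
  again <- make_intergenic_controls(g, genes, peaks, n = 6,
                                    min_gene_distance = 2000L, rng_seed = 9)
  expect_identical(ctrl, again)
})

test_that("non-targeting controls verify their mismatch clearance", {
  set.seed(81)
  g <- as_genome(c1 = random_dna(15000))
  expect_identical(nrow(make_nontargeting_controls(g, n = 0)), 0L)
  ntc <- make_nontargeting_controls(g, n = 8, rng_seed = 13)
  expect_identical(nrow(ntc), 8L)
  expect_true(all(is.na(ntc$start)))
  for (sp in ntc$spacer) {
    hits <- find_offtargets(g, sp, max_mm = 2L, table = cfd)
    expect_identical(nrow(hits), 0L)
  }
  again <- make_nontargeting_controls(g, n = 8, rng_seed = 13)
  expect_identical(ntc$spacer, again$spacer)
})
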