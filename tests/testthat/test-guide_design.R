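# Deterministic toy locus: an all-A/T background cannot contain an NGG PAM,
# so every PAM present is one we planted.
toy_design <- function() {
  background <- paste0(strrep("AT", 150))
  seq <- plant(background, "CATGAACATG", 100)   # motif at [100, 110)
  seq <- plant(seq, "AGG", 115)                 # PAM 5 bp right of the motif
  g <- as_genome(c1 = seq)
  peaks <- tibble::tibble(chrom = "c1", start = 60L, end = 160L,
                          id = "2319", strand = ".")
  hits <- scan_peaks(g, peaks)
  list(genome = g, peaks = peaks, hits = hits)
}

test_that("a single planted PAM near the motif yields exactly one guide", {
  d <- toy_design()
  expect_identical(nrow(d$hits), 1L)
  guides <- enumerate_guides(d$genome, d$hits)
  expect_identical(nrow(guides), 1L)
  expect_identical(guides$strand, "+")
  expect_identical(guides$end, 115L)            # protospacer abuts the PAM
  expect_identical(guides$pam, "AGG")
  expect_identical(guides$motif_ids[[1]], "2319.1")
  expect_identical(guides$cut_pos, 111L)        # 3 bp 5' of the PAM

  # pure A/T contig: no NGG possible
  at_only <- as_genome(c1 = strrep("AT", 200))
  hits <- d$hits
  expect_identical(nrow(enumerate_guides(at_only, hits)), 0L)
})

test_that("the PAM window boundary is inclusive at motif.end + window - 3", {
  background <- strrep("AT", 200)
  motif_at <- 100L
  seq0 <- plant(background, "CATGAACATG", motif_at)
  motif_end <- motif_at + 10L
  for (window in c(16L, 7L)) {
    # PAM starting exactly at motif_end + window - 3: the 3-bp PAM's last
    # base is the last base inside the window -> included
    pin <- plant(seq0, "AGG", motif_end + window - 3L)
    g_in <- as_genome(c1 = pin)
    peaks <- tibble::tibble(chrom = "c1", start = 60L, end = 250L,
                            id = "pk", strand = ".")
    hits <- scan_peaks(g_in, peaks)
    expect_identical(nrow(enumerate_guides(g_in, hits, window = window)), 1L)

    # one bp further: excluded
    pout <- plant(seq0, "AGG", motif_end + window - 2L)
    g_out <- as_genome(c1 = pout)
    hits <- scan_peaks(g_out, peaks)
    expect_identical(nrow(enumerate_guides(g_out, hits, window = window)), 0L)
  }
  expect_error(enumerate_guides(toy_design()$genome, toy_design()$hits,
                                window = -1), "window")
})

test_that("enumeration equals brute force on random contigs", {
  set.seed(303)
  for (i in 1:6) {
    g <- as_genome(c1 = random_dna(5000))
    peaks <- tibble::tibble(chrom = "c1", start = 1000L, end = 1400L,
                            id = "pk", strand = ".")
    hits <- scan_peaks(g, peaks)
    if (nrow(hits) == 0) next
    got <- enumerate_guides(g, hits)
    attr(got, "dropped_n") <- NULL
    want <- naive_guides(g, hits)
    expect_identical(got[, c("chrom", "start", "end", "strand", "spacer")],
                     want[, c("chrom", "start", "end", "strand", "spacer")])
  }
})

test_that("guide sequences re-extract exactly from the genome", {
  set.seed(404)
  g <- as_genome(c1 = random_dna(8000))
  peaks <- tibble::tibble(chrom = "c1", start = c(500L, 4000L),
                          end = c(1500L, 5000L), id = c("a", "b"),
                          strand = ".")
  hits <- scan_peaks(g, peaks)
  guides <- enumerate_guides(g, hits)
  expect_gt(nrow(guides), 0)
  for (i in seq_len(nrow(guides))) {
    locus <- substr(g[[guides$chrom[i]]], guides$start[i] + 1L,
                    guides$end[i])
    if (guides$strand[i] == "+") {
      pam <- substr(g[[guides$chrom[i]]], guides$end[i] + 1L,
                    guides$end[i] + 3L)
      expect_identical(locus, guides$spacer[i])
    } else {
      pam <- rc_str(substr(g[[guides$chrom[i]]], guides$start[i] - 2L,
                           guides$start[i]))
      expect_identical(rc_str(locus), guides$spacer[i])
    }
    expect_identical(pam, guides$pam[i])
  }
})

test_that("widening the window only adds guides", {
  set.seed(505)
  g <- as_genome(c1 = plant(random_dna(6000), "CATGAACATG", 2300))
  peaks <- tibble::tibble(chrom = "c1", start = 2000L, end = 2600L,
                          id = "pk", strand = ".")
  hits <- scan_peaks(g, peaks)
  expect_gt(nrow(hits), 0)
  key <- function(tbl) paste(tbl$chrom, tbl$start, tbl$strand)
  prev <- character(0)
  for (w in c(0L, 4L, 8L, 16L, 24L)) {
    cur <- key(enumerate_guides(g, hits, window = w))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("guide ids follow the <peak>.<motif>-<k> convention", {
  background <- strrep("AT", 200)
  seq <- plant(background, "CATGAACATG", 100)
  seq <- plant(seq, "AGG", 115)
  seq <- plant(seq, "AGG", 120)
  g <- as_genome(c1 = seq)
  peaks <- tibble::tibble(chrom = "c1", start = 60L, end = 200L,
                          id = "2319", strand = ".")
  guides <- assign_guide_ids(enumerate_guides(g, scan_peaks(g, peaks)))
  expect_identical(guides$guide_id, c("2319.1-1", "2319.1-2"))
  expect_true(!is.unsorted(guides$start))
  expect_identical(unique(guides$category), "peak")
})

test_that("a guide shared by two motifs is named for the 5'-most motif", {
  background <- strrep("AT", 300)
  # two motifs 20 bp apart; one PAM between them inside both 16-bp windows
  seq <- plant(background, "CATGAACATG", 100)
  seq <- plant(seq, "CATGAACATG", 130)
  seq <- plant(seq, "AGG", 119)
  g <- as_genome(c1 = seq)
  peaks <- tibble::tibble(chrom = "c1", start = 60L, end = 250L,
                          id = "pk", strand = ".")
  hits <- scan_peaks(g, peaks)
  expect_identical(nrow(hits), 2L)
  guides <- enumerate_guides(g, hits)
  shared <- guides[lengths(guides$motif_ids) == 2, ]
  expect_identical(nrow(shared), 1L)
  expect_identical(shared$id_motif, "pk.1")
  expect_setequal(shared$motif_ids[[1]], c("pk.1", "pk.2"))
})

test_that("library summaries count guides per peak and per motif", {
  lib <- tibble::tibble(
    guide_id = paste0("g", 1:6),
    spacer = vapply(1:6, function(i) random_dna(20), character(1)),
    category = c(rep("peak", 4), "intergenic_control",
                 "nontargeting_control"),
    peak_id = c("p1", "p1", "p1", "p2", NA, NA),
    motif_ids = list("p1.1", "p1.1", "p1.2", "p2.1", character(0),
                     character(0)))
  s <- summarize_library(lib)
  expect_identical(s$stats$n_guides, 4L)
  expect_identical(s$stats$n_peaks_targeted, 2L)
  expect_identical(s$stats$n_peaks_multi, 1L)
  expect_identical(s$peak_histogram$n_guides, c(1L, 3L))
  expect_identical(s$peak_histogram$n_peaks, c(1L, 1L))
  expect_identical(s$composition$n_guides[s$composition$category == "peak"],
                   4L)
  # histogram totals conserve the guide count
  expect_identical(sum(s$peak_histogram$n_guides * s$peak_histogram$n_peaks),
                   s$stats$n_guides)

  empty <- summarize_library(lib[0, ])
  expect_identical(empty$stats$n_guides, 0L)
  expect_identical(nrow(empty$peak_histogram), 0L)
})
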