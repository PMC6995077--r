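# Independent oracles and fixture builders. Oracles are deliberately naive
# (double loops, direct definitions) and share no code with the package's
# implementation paths.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# naive double-loop dyad matcher: every offset x spacer length, explicit
# per-character IUPAC check; N in the sequence matches nothing
naive_scan <- function(seq, left = "CWWG", right = "CWWG",
                       smin = 2L, smax = 12L) {
  chars <- strsplit(seq, "")[[1]]
  lp <- strsplit(left, "")[[1]]
  rp <- strsplit(right, "")[[1]]
  nl <- length(lp); nr <- length(rp)
  n <- length(chars)
  out <- list()
  for (off in seq_len(n) - 1L) {
    left_ok <- TRUE
    for (j in seq_len(nl)) {
      ch <- chars[off + j]
      if (is.na(ch) || !(ch %in% IUPAC_SETS[[lp[j]]])) {
        left_ok <- FALSE
        break
      }
    }
    if (!left_ok) next
    for (s in smin:smax) {
      if (off + nl + s + nr > n) break
      ok <- TRUE
      for (j in seq_len(s)) {   # spacer: any base, but never N
        if (!chars[off + nl + j] %in% c("A", "C", "G", "T")) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        for (j in seq_len(nr)) {
          ch <- chars[off + nl + s + j]
          if (!(ch %in% IUPAC_SETS[[rp[j]]])) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) out[[length(out) + 1L]] <- c(off, s)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(offset = integer(), spacer_len = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(offset = as.integer(m[, 1]), spacer_len = as.integer(m[, 2]))
}

# brute-force guide enumeration: every position and strand of every contig,
# PAM matched literally, window predicate applied per motif
naive_guides <- function(genome, motif_hits, window = 16L) {
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    for (p in 0:(L - 3L)) {
      pam_plus <- substr(s, p + 1L, p + 3L)
      plus_ok <- substr(pam_plus, 2, 3) == "GG" &&
        !grepl("N", pam_plus, fixed = TRUE)
      pam_minus_raw <- pam_plus
      minus_ok <- substr(pam_minus_raw, 1, 2) == "CC" &&
        !grepl("N", pam_minus_raw, fixed = TRUE)
      for (i in seq_len(nrow(motif_hits))) {
        m <- motif_hits[i, ]
        if (m$chrom != chrom) next
        if (p < m$start - window || p + 3L > m$end + window) next
        if (plus_ok && p - 20L >= 0L) {
          spacer <- substr(s, p - 19L, p)
          if (!grepl("N", spacer, fixed = TRUE)) {
            rows[[length(rows) + 1L]] <-
              tibble::tibble(chrom = chrom, start = p - 20L, end = p,
                             strand = "+", spacer = spacer,
                             motif_id = m$motif_id)
          }
        }
        if (minus_ok && p + 23L <= L) {
          spacer <- rc_str(substr(s, p + 4L, p + 23L))
          if (!grepl("N", spacer, fixed = TRUE)) {
            rows[[length(rows) + 1L]] <-
              tibble::tibble(chrom = chrom, start = p + 3L, end = p + 23L,
                             strand = "-", spacer = spacer,
                             motif_id = m$motif_id)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          spacer = character(), motif_id = character()))
  }
  dplyr::distinct(dplyr::bind_rows(rows), .data$chrom, .data$start,
                  .data$strand, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

# string reverse complement without touching package internals
rc_str <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force off-target scan: substring every window, count mismatches
naive_offtargets <- function(genome, spacer, max_mm = 3L) {
  sp <- strsplit(spacer, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < 23) next
    for (p in 0:(L - 23L)) {
      for (strand in c("+", "-")) {
        if (strand == "+") {
          site <- substr(s, p + 1L, p + 20L)
          pam <- substr(s, p + 21L, p + 23L)
          start <- p
        } else {
          seg <- substr(s, p + 1L, p + 23L)
          rcseg <- rc_str(seg)
          site <- substr(rcseg, 1, 20)
          pam <- substr(rcseg, 21, 23)
          start <- p + 3L
        }
        if (!substr(pam, 3, 3) == "G") next
        if (!substr(pam, 2, 2) %in% c("G", "A")) next
        if (grepl("N", site, fixed = TRUE) || grepl("N", pam, fixed = TRUE))
          next
        st <- strsplit(site, "")[[1]]
        mm <- sum(st != sp)
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(chrom = chrom, start = start,
                           strand = strand, site_seq = site, pam = pam,
                           n_mismatches = mm)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character(), site_seq = character(),
                          pam = character(), n_mismatches = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start,
                 .data$strand)
}

# textbook BH step-up: sort ascending, p_(i) * n / i, cumulative min from
# the largest rank down, mapped back to input order
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}

as_genome <- function(...) {
  structure(c(...), class = "genome")
}

# drop a subsequence into a background string at a 0-based offset
plant <- function(background, insert, at) {
  substr(background, at + 1L, at + nchar(insert)) <- insert
  background
}
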