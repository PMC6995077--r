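# Builds inst/extdata/cfd_penalties_synthetic.tsv: a synthetic CFD-style
# penalty table (position- and base-pair-specific mismatch penalties plus
# PAM 2-mer penalties). Structurally faithful to the published CFD matrix
# shape -- matches score 1.0, GG PAM scores 1.0, all penalties in [0,1],
# a few fully tolerated (penalty = 1) wobble-like mismatches confined to
# PAM-distal positions -- but the numeric values are synthetic.
bases <- c("A", "C", "G", "T")
pair_tol <- c("G>T" = 0.90, "T>G" = 0.85, "G>A" = 0.55, "A>G" = 0.50,
              "T>C" = 0.50, "C>T" = 0.45, "A>C" = 0.30, "C>A" = 0.30,
              "A>T" = 0.25, "T>A" = 0.25, "C>G" = 0.15, "G>C" = 0.15)
rows <- expand.grid(position = 1:20, guide_base = bases, site_base = bases,
                    stringsAsFactors = FALSE)
rows <- rows[rows$guide_base != rows$site_base, ]
pf <- function(p) 1 - 0.85 * (p - 1) / 19       # PAM-proximal least tolerated
key <- paste0(rows$guide_base, ">", rows$site_base)
rows$penalty <- round(pair_tol[key] * pf(rows$position), 4)
# wobble-like pairs fully tolerated at the PAM-distal edge => CFD can be 1
# with up to three mismatches (unit entries confined to positions 1-3)
unit <- (rows$position == 1 & key %in% c("G>T", "T>G")) |
        (rows$position == 2 & key == "G>T") |
        (rows$position == 3 & key == "T>G")
rows$penalty[unit] <- 1.0
mism <- data.frame(kind = "mismatch", position = rows$position,
                   guide_base = rows$guide_base, site_base = rows$site_base,
                   pam2 = NA, penalty = rows$penalty)
pam2 <- c(GG = 1.0, AG = 0.26, GA = 0.07, TG = 0.04, GT = 0.02, CG = 0.02)
all2 <- apply(expand.grid(bases, bases), 1, paste0, collapse = "")
pamrows <- data.frame(kind = "pam", position = NA, guide_base = NA,
                      site_base = NA, pam2 = all2,
                      penalty = ifelse(all2 %in% names(pam2), pam2[all2], 0))
out <- rbind(mism, pamrows)
out <- out[order(out$kind, out$position, out$guide_base, out$site_base, out$pam2), ]
write.table(out, "inst/extdata/cfd_penalties_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
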