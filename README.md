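# peakscreen

Pooled CRISPR screens can probe the *noncoding* genome: instead of knocking
out genes, sgRNAs are aimed at transcription-factor binding sites inside
ChIP-Seq peaks, and guides whose targets matter for a phenotype (e.g.
proliferation under DNA damage) enrich or deplete over the course of the
screen. `peakscreen` implements both halves of that workflow for
desk-scale, fully reproducible use:

**Design.** Given a genome (FASTA), a set of TF ChIP-Seq peaks (BED) and a
degenerate dyad consensus — the packaged default is the p53 response
element `CWWG[N]{2,12}CWWG` (two CWWG half-sites, W = A/T, separated by a
2–12 bp spacer) — the design stage:

1. finds every motif match inside every peak (all offsets, all spacer
   lengths, both strands implicitly for this self-reverse-complementary
   dyad);
2. enumerates every sgRNA whose 3-bp `NGG` PAM lies within ±16 bp of a
   motif (20-nt protospacer, SpCas9 geometry, blunt cut between
   protospacer bases 17 and 18);
3. removes guides with fully tolerated off-target sites, scored by CFD
   (cutting frequency determination — the product of position- and
   base-pair-specific mismatch penalties times a PAM penalty): a guide is
   excluded if any CFD = 1 site falls inside a protein-coding gene
   (rule A) or if more than one CFD = 1 site lies in unrelated noncoding
   sequence (rule B);
4. adds intergenic-targeting and non-targeting control guides.

**Analysis.** Given screen readouts (FASTQ reads or an sgRNA × sample count
table with a plasmid-library reference column), the analysis stage counts
spacers by exact 20-mer extraction, computes median-ratio size factors,
per-guide log2 fold changes versus the plasmid DNA pool
(`lfc = log2((n_s + 0.5)/(n_pDNA + 0.5))` on normalized counts), replicate
correlations, control-anchored empirical guide p-values, and peak-level
calls: a peak's statistic is the **median** of its guides' mean fold
changes, tested against medians of equal-size random draws from the
non-targeting control pool (two-sided, add-one smoothed), with
Benjamini–Hochberg FDR across peaks. Peaks are annotated with the distance
from their midpoint to the nearest annotated TSS, the usual
proximal/distal (≤/> 10 kb) stratification of regulatory elements.

A synthetic-data module simulates genomes with planted peaks, motifs,
two TSS-distance strata of genes, libraries, negative-binomial screen
counts with known planted effects, and FASTQ reads — so every stage is
testable end to end with no downloads. The packaged CFD penalty table is
a *synthetic* stand-in with the published matrix's structure and
invariants (see `?load_cfd_table`); drop in a real table via its TSV
format for production use.

## Worked example

```r
library(peakscreen)

# simulate a small screen with known ground truth
cfg <- sim_config(genome_length = 300000, n_contigs = 1, n_peaks = 30,
                  n_genes = 10, n_enriched_peaks = 3, n_depleted_peaks = 3,
                  rng_seed = 42)
sim <- simulate_genome(cfg)

# design: scan peaks for the p53 dyad, enumerate PAM-proximal guides,
# drop guides with tolerated off-targets
hits <- scan_peaks(sim$genome, sim$peaks)
guides <- assign_guide_ids(enumerate_guides(sim$genome, hits))
kept <- filter_guides(guides, sim$genome, genes = sim$genes,
                      peaks = sim$peaks)$kept
summarize_library(kept, peaks = sim$peaks, motifs = hits)
#> Library summary
#>   targeting guides: 229
#>   peaks targeted:   30 (30 by >1 guide)
#>   motifs targeted:  67 (62 by >1 guide)

# analyze a simulated screen against the library's plasmid pool
lib <- simulate_library(sim, cfg)
counts <- simulate_counts(lib, sim$truth, cfg)
fit <- analyze_screen(counts, lib, rng_seed = 42)
glance(fit)
#> # A tibble: 1 × 5
#>   n_guides n_peaks n_peaks_enriched n_peaks_depleted mean_replicate_r
#> 1      620      30                2                2            0.565
head(dplyr::arrange(tidy(fit), fdr), 4)
#>   peak_id condition n_guides median_lfc empirical_p     fdr
#> 1 peak_25 screen           4     -1.46    0.0001000 0.00150
#> 2 peak_26 screen           4     -1.34    0.0001000 0.00150
#> 3 peak_21 screen           4      0.909   0.00350   0.0262
#> 4 peak_30 screen           4      0.919   0.00320   0.0262
```

The four peaks called at FDR < 0.05 are planted effects (the simulation
planted three enriched and three depleted at ±1.5 log2FC; guide potency
varies, so not every planted peak clears the threshold at this small
scale). `tidy(fit, "guides")` returns guide-level statistics,
`tidy(fit, "replicates")` the replicate correlations, and
`autoplot(fit)`, `plot_replicate_scatter(fit)`, `plot_tss_distance()`
the standard figures.

A command-line front end covering simulate/design/analyze installs to
`exec/peakscreen`; every run writes a `manifest.json` with the full
configuration and input checksums.

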