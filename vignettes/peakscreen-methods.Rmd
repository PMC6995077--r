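---
title: "Designing and analyzing peak-targeting CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing peak-targeting CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscreen)
```

`peakscreen` turns transcription-factor ChIP-Seq peaks into a pooled
CRISPR library and turns the screen's sequencing readout into peak-level
enrichment/depletion calls. This vignette is the package's account of the
method: the model at each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were
genuinely open.

All coordinates in the package are 0-based half-open (the BED convention),
everywhere: peaks, motifs, protospacers, cut sites, gene bodies, TSSs. A
single convention removes the usual off-by-one drift between stages;
1-based positions appear only in human-readable output.

## Motif scanning

A binding-site consensus is modelled as a dyad: two IUPAC arms separated
by an unconstrained spacer of variable length,
`ARM1[N]{min,max}ARM2`. The packaged default is the p53 response element,
`CWWG[N]{2,12}CWWG` — two CWWG half-sites (W = A or T) separated by 2 to
12 bp. `scan_sequence()` reports *every* `(offset, spacer length)`
combination that matches; overlapping matches and multiple spacer lengths
at one offset are all retained, because collapsing loses information and
any collapse convention is arbitrary. A greedy collapse
(`collapse_motif_hits()`: leftmost wins, ties to the shortest spacer) is
available but off by default.

Two semantics matter and are fixed by tests:

* `N` in the *pattern* matches any of A/C/G/T; `N` in the *genome* matches
  nothing. Guides are never designed against unknown sequence.
* Scanning is single-strand (+). The default dyad is its own reverse
  complement, so plus-strand scanning finds every site; the hit set's
  invariance under reverse complement is asserted property-style in the
  test suite. For non-palindromic patterns `scan_peaks(both_strands =
  TRUE)` scans the reverse complement, mirrors coordinates, and drops
  duplicate intervals.

Motif ids are `"<peak id>.<k>"`, numbering hits 5'→3' within each peak, so
identical inputs always produce identical labels.

## Guide enumeration

For SpCas9 the target is a 20-nt protospacer followed by an `NGG` PAM.
`enumerate_guides()` emits one candidate per PAM occurrence (both strands)
whose 3-bp PAM interval lies entirely within the motif interval extended
by `window` bp on each side. The default window is 16 bp, the
motif-proximal distance within which an sgRNA can be expected to disturb
factor binding or recruit effectors to the element.

The window could plausibly anchor on the PAM, the protospacer, or the cut
site; the PAM-anchored reading is the default because the PAM is the
fixed, sequence-defined anchor of target recognition, and a cut-anchored
mode (`anchor = "cut"`) is provided. The cut position is recorded as the
plus-strand coordinate of the base 5' of the blunt cut, 3 bp 5' of the
PAM (between protospacer bases 17 and 18) — standard SpCas9 geometry,
needed later for TSS distances.

Candidates found from different motifs at one `(locus, strand)` are merged
with the union of motif ids; the guide is *named* after its 5'-most motif
(`assign_guide_ids()`, ids like `2319.1-1`) and *attributed* for
aggregation to the peak whose motif lies closest to the cut site (ties to
the lower peak id), because peak-level aggregation needs a partition of
guides. Duplicate spacer sequences arising at different loci are retained
at design time — a second perfect site is exactly what the off-target
filter is for — keeping design and filtering concerns separate.

No on-target efficacy score is applied. Efficacy rules were trained on
coding knockouts and do not transfer to regulatory elements; the library
deliberately keeps every candidate and lets guide-to-guide variability be
handled statistically (median aggregation, below).

## Off-target filtering

Off-target propensity is scored with CFD: the product over spacer
positions 1–20 (position 1 PAM-distal) of a position- and
base-pair-specific mismatch penalty, times a penalty on the PAM's last
two bases. A Watson–Crick match contributes 1.0 and a canonical `GG` PAM
contributes 1.0, so a *fully tolerated* site scores exactly 1.

The packaged penalty table is **synthetic** — the published matrix is not
redistributable here — but structurally faithful: penalties in [0, 1],
wobble-like pairs most tolerated, PAM-proximal positions least tolerant,
`NAG` discounted, and a small set of fully tolerated (penalty = 1)
entries confined to PAM-distal positions 1–3. Every scoring and filtering
path is table-driven, so the real matrix drops in as a TSV
(`load_cfd_table()`).

Two exclusion rules are applied, with "CFD = 1" tested at tolerance 1e-9
on the product:

* **Rule A** — any tolerated site inside a protein-coding gene *body*
  rejects the guide. Gene bodies, not exons: a cut anywhere in a coding
  gene can disrupt it, and the conservative reading costs little.
* **Rule B** — more than one tolerated site in *unrelated noncoding*
  sequence rejects the guide. "Unrelated" defaults to the strict reading:
  a tolerated site inside another targeted peak also counts (a switch
  exempts it), since a second hit in a different element confounds
  attribution either way.

The search enumerates `NGG` and `NAG` sites with at most `max_mm = 3`
mismatches. The ceiling is not arbitrary: at load time the table is
checked to carry penalty-1 mismatch entries at no more positions than the
ceiling, which *proves* the bounded search contains every CFD = 1 site.
The scan itself is a direct mismatch-counting sweep (a small C++ kernel;
both strands via the reverse-complemented encoding) — no external aligner,
so the scan is bit-exactly testable against a brute-force oracle, which
the suite does on multi-hundred-kilobase genomes.

Controls mirror the screened library's two null classes: intergenic
controls target PAM sites at least `min_gene_distance` (default 5 kb)
from every gene body and outside every targeted peak, and pass the same
off-target filter; non-targeting controls are random 20-mers re-verified
to have no genomic site within 2 mismatches of any `NGG`/`NAG` PAM. Both
are pure functions of their RNG seed.

## Screen statistics

The analysis contract is: log2 fold change relative to the plasmid DNA
library, median aggregation per peak, BH FDR. The machinery behind the
p-values is a deliberately simple, fully specified control-anchored
empirical statistic — not a reimplementation of any screen-analysis
tool's internal model — so every number it produces is reproducible from
this document:

1. **Counting.** The 20-nt spacer is extracted from each read (fixed
   offset or vector-anchor search) and matched *exactly* against the
   library. Mismatched reads are unassigned; spacers shared by two
   library entries count to a shared ambiguity bin rather than being
   split. Assigned + unassigned + ambiguous = total, asserted.
2. **Normalization.** DESeq-style median-of-ratios size factors over
   guides with nonzero counts in all samples; if fewer than 100 such
   guides exist the estimator is unstable and the method falls back to
   total-count scaling (recorded in the result). Cross-checked against
   `DESeq2::estimateSizeFactorsForMatrix` in the tests.
3. **Fold change.** `lfc = log2((n + c)/(n_pDNA + c))` per replicate on
   normalized counts with pseudocount `c = 0.5`; the pDNA pool is the
   sole reference, with the guide's mean over replicates as its summary.
   The pseudocount keeps zero counts finite while vanishing for
   well-covered guides.
4. **Guide significance.** Two-sided empirical p against the
   non-targeting control fold-change distribution with add-one smoothing,
   `p = (1 + #{|ctrl| ≥ |obs|}) / (1 + n_ctrl)` — never zero, exact under
   the null. Fewer than 50 controls triggers a warning (the resolution of
   p is 1/(n+1)).
5. **Peak aggregation.** A peak's statistic is the exact median of its
   guides' mean fold changes — the median tolerates the strong
   guide-to-guide potency variation these libraries show, where a mean
   would be dragged by one dead or one outlier guide. Its p-value
   compares the observed median against `n_perm = 10,000` medians of
   equal-size draws from the control pool (one shared null per peak-size
   stratum, so the cost is per stratum, not per peak), two-sided,
   add-one smoothed; BH across peaks within each condition.
6. **Annotation.** Distances from guide cut sites or peak midpoints to
   the nearest annotated TSS, unsigned, with items on gene-less contigs
   flagged rather than set infinite; the proximal/distal split uses a
   10-kb threshold, with exactly 10 kb counting as proximal.

Replicate concordance is Pearson correlation of per-replicate fold-change
vectors (Spearman available); zero-variance inputs are flagged
`undefined` rather than propagating NaN. A note on the median: the
aggregation here is the plain median over *all* member guides; tools that
compute "alpha-median" fold changes restrict to the strongest guides
first, and no such alpha threshold is applied here.

## The synthetic-data generator

`simulate_genome()` emulates the features the pipeline's correctness
depends on: i.i.d. background sequence at GC 0.41 (human-like),
non-overlapping peaks (default 200 peaks of 300 bp — ChIP-Seq-scale
intervals), 1–2 planted dyad motifs per peak drawn uniformly over spacer
lengths 2–12 with W ∈ {A, T}, and genes in two strata — TSS within 10 kb
of a peak versus more than 100 kb away — so TSS-distance classifications
have both classes to find. `simulate_counts()` models pDNA abundance as
log-normal (sdlog 0.5) scaled to a mean depth of 500 reads per guide,
screen abundance as `pDNA_mean × 2^(true lfc × efficiency)`, and counts
as negative binomial with dispersion 0.1 (Poisson in the zero-dispersion
limit, asserted distributionally in the tests). Per-guide efficiency
multipliers are Beta(2, 1) draws: guides targeting the same element
genuinely vary in potency, and recovery tests run against efficiencies of
1 would flatter the method. Defaults plant 10 enriched and 10 depleted
peaks at ±1.5 log2FC among 200, screened in triplicate — the package's
reference study conditions. All generators are pure functions of
`(config, seed)`.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: PCR amplification bias and jackpotting,
position effects and chromatin context, guide-specific cutting biases
beyond a scalar multiplier, copy-number artifacts, correlated effects
between adjacent elements sharing a regulatory target, and real motif
composition (planted motifs sit in i.i.d. background rather than in the
sequence context of true binding sites).

Under those reference conditions the recovery ceiling is set by the
efficiency model: a peak's realized effect is the median of four
Beta(2, 1)-attenuated guides (≈ 0.6 × 1.5 ≈ 0.9 log2 units) against a
control-pool noise of ≈ 0.53 log2 units at depth 500 and dispersion 0.1.
The acceptance script measures the resulting sensitivity and false
discovery proportion at BH FDR < 0.05 rather than assuming them; the
false discovery proportion is controlled comfortably, while sensitivity
sits near two-thirds — the honest cost of potency variation at this
depth, not a tuning target.

## Numerical choices and degenerate inputs

* Empirical p-values use `findInterval` on the sorted absolute null with
  a 1e-12 tie shift so that ties count as "at least as extreme".
* CFD equality with 1 is tested at 1e-9 on the product; penalties are
  read as written, never renormalized.
* Median-of-ratios uses log-space means for the geometric mean; size
  factors are rescaled to geometric mean 1.
* Degenerate inputs fail loudly and early: empty intervals, start ≥ end,
  unknown strands, negative or non-integer counts, all-zero samples,
  missing pDNA columns, peaks outside contig bounds, pseudocount 0 with
  zero counts. Guides or windows touching `N` are dropped and counted,
  never silently scored.
* Tie-breaks are total and documented: guide ids in coordinate order,
  peak attribution by cut-to-motif distance then lower peak id, greedy
  motif collapse leftmost-then-shortest.

## Scale of the packaged checks

The test suite and acceptance script are sized for a single CPU at desk
scale, as the package's own reference problem sizes: oracle equivalence
of the scanner on 1,000 random sequences up to 2 kb; guide enumeration
against brute force on 5-kb contigs; off-target scans against brute force
on a 200-kb two-contig genome; BH against the textbook step-up on 10,000
random p-vectors; and end-to-end recovery over 20 simulated screens at
the reference conditions (~1,300 guides × 4 samples each). Larger genomes
work unchanged — the scan kernel is linear in genome length — but the
oracles, which are deliberately naive, are what bounds test-time input
sizes.

## Known limitations

* The CFD table shipped is synthetic; absolute CFD values (and therefore
  which marginal sites count as "tolerated") will differ from the
  published matrix, though every CFD = 1 decision path is exercised
  identically. Supply the real table for production design.
* Off-target search ignores DNA/RNA bulges and chromatin accessibility;
  the mismatch ceiling of 3 is provably sufficient only for CFD = 1
  sites, not for ranking lower-scoring sites.
* The empirical statistic requires a healthy non-targeting control set;
  with few controls, p-value resolution is coarse and peak permutation
  nulls degrade.
* Guide efficiency is a scalar multiplier; no sequence-based efficacy
  model is applied by design.
* The spacer counter is exact-match only; reads with sequencing errors in
  the 20-mer are unassigned rather than rescued, which undercounts at
  high error rates (quantified by `simulate_reads(error_rate = ...)`).
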