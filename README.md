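# enhancertopo

Integrative analysis of enhancer chromatin state and genome architecture in
a conditional-knockout versus control design, with a synthetic-data module
that plants known structure so every stage can be validated against ground
truth.

The package is aimed at epigenomics analysts working with the combination of
ChIP-seq peak calls (a chromatin remodeler or transcription factor plus
H3K4me3 / H3K4me1 / H3K27ac / RNAPII), ATAC-seq, Hi-C derived loop and
contact-domain lists, and RNA-seq differential expression — the typical
multi-assay design used to ask whether a remodeler activates enhancers and
whether those enhancers' target genes (constrained by topologically
associating domains, TADs) respond in the same direction.

## What it computes

**Regulatory-element classification.** Peaks reproducible in ≥ 2 replicates
are merged; each element is assigned exactly one chromatin state by peak
overlap with promoter precedence:

- overlaps H3K4me3 → *promoter*
- else overlaps H3K4me1 ∧ H3K27ac → *active enhancer*
- else overlaps H3K4me1 → *poised enhancer*
- else → *other*

with ATAC overlap giving accessibility and CHD7/RNAPII overlap giving
occupancy strata. Temporal transitions (early-specific, constitutively
active, late-gained, unchanged-poised) come from a differential H3K27ac
comparison between timepoints.

**Differential signal.** Per-region replicate counts are CPM-normalised;
log₂ fold-change uses pseudocount 0.5 and significance is a two-sided Welch
t-test on log₂ CPM with Benjamini–Hochberg FDR < 0.05 — a transparent
replicate-level stand-in for count-model callers, not a reimplementation of
them.

**Genome architecture.** Contact domains merge when both borders agree
within 20 kb; loop lists from the two conditions merge when both anchor
midpoints agree within 10 kb; a domain is a *loop domain* when a loop's
anchors sit within 25 kb of its two borders, otherwise a *compartmental
domain*. Observed/expected (O/E) uses the per-diagonal mean; intradomain
contact change is log₂(mean O/E in knockout / mean O/E in control) over
intradomain bin pairs, which is invariant to uniform matrix rescaling. A/B
compartments are the leading eigenvector of the Pearson correlation matrix
of the O/E columns, with the global sign oriented so positive bins correlate
with H3K4me3 peak density (A = euchromatic).

**Enhancer–gene linking and concordance.** An element links to the single
nearest gene whose TSS lies within 100 kb of the element midpoint *and*
inside the same TAD (or to genes via enhancer–promoter loops, defined as
loops with an enhancer in one anchor and a promoter in the other). Among
significantly changed enhancers, a link is *concordant* when
sign(Δenhancer) = sign(Δgene); strata (remodeler-bound vs unbound) are
compared with a one-sided Pearson χ² test (df = 1, no continuity
correction), and dose–response is summarised by Pearson correlation and
magnitude-tertile group tests.

**Cross-species overlap.** Target sets mapped by the same nearest-gene rule
are restricted to one-to-one orthologs and tested with the upper-tail
hypergeometric probability P[X ≥ k] for an overlap of k genes between sets
of size K and n in a universe of N.

**Division orientation.** Mitotic division-plane angles (degrees from the
pial surface, axial, folded to [0°, 90°]) are classified
horizontal/oblique/vertical at 30°/60°, summarised as vertical:horizontal
ratios (pooled and per-animal mean ± s.e.m.), densities per 100 µm², and
rose-plot histograms.

Every quantity has a generator counterpart in `sim_config()` /
`simulate_*()` that plants it (negative-binomial counts with planted
fold-changes, power-law contact decay with planted domains, checkerboard
compartments and border loops, per-stratum concordance, a planted ortholog
overlap, von Mises division angles), so recovery can be checked end to end.

## Worked example

```r
library(enhancertopo)

cfg <- sim_config(seed = 1, n_elements = 2000, chrom_sizes = c(chr1 = 2e7))
sim <- simulate_peaks_and_counts(cfg)

marks <- lapply(sim$peaks, reproducible_peaks, min_support = 2)
atlas <- sim$truth[, c("chrom", "start", "end", "element_id")]
atlas$name <- atlas$element_id
elements <- classify_elements(atlas, marks$atac, marks$k4me3,
                              marks$k4me1, marks$k27ac)
elements <- annotate_occupancy(elements, marks$rnapii, marks$chd7)$elements
class_proportions(elements)
#> # A tibble: 4 × 3
#>   state               n fraction
#> 1 promoter          460    0.23
#> 2 active_enhancer   552    0.276
#> 3 poised_enhancer   745    0.372
#> 4 other             243    0.122

diffs <- differential_regions(sim$atac_counts$ctrl, sim$atac_counts$ko)
direction_fractions(diffs, subset = elements$state == "active_enhancer" &
                                     elements$chd7_bound)
#>   direction     n fraction
#> 1 down         42    0.894
#> 2 up            5    0.106

arch <- simulate_architecture(cfg)
lk <- simulate_expression_links(cfg, sim$truth, arch$domains)
conc <- concordance_table(lk$links, diffs, lk$genes)
chi2_2x2(conc, sided = "one")
#> Pearson chi-squared (df = 1, one-sided): X2 = 12.69, p = 0.0001837
```

The classification fractions recover the planted class mix (the defaults
plant 24.2 / 29.0 / 36.3 / 10.5%; at n = 2000 the sample fractions above are
within binomial noise of those rates). The direction split shows the
planted predominance of accessibility loss at bound active enhancers, and
the concordance table shows bound enhancers more often changing in the same
direction as their TAD-linked gene than unbound ones (79.6% vs 55.9%), with
the one-sided χ² confirming the difference.

The same analyses run end to end from files with

```sh
Rscript scripts/enhancertopo.R all --seed 1 --out results/run1
```

which writes each stage's tables (TSV) and summaries (JSON) and is
byte-reproducible for a fixed seed.

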