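---
title: "Methods: models, parameters and design choices in enhancertopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in enhancertopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and rules, the parameters that matter (with units and defaults),
what the synthetic-data generators do and do not emulate, the numerical
choices, and the places where the design was genuinely open and a choice
had to be made.

## The analysis problem

The package targets a recurring multi-assay design in developmental
epigenomics: a chromatin regulator is conditionally knocked out, and the
analyst has (i) replicate peak calls for the regulator itself and for
chromatin marks — H3K4me3 (promoters), H3K4me1 (enhancer priming), H3K27ac
(enhancer activity), RNAPII — plus ATAC accessibility, in knockout and
control; (ii) Hi-C-derived contact matrices, loop lists and contact-domain
(TAD) lists per condition; (iii) RNA-seq fold-changes per gene; and, in the
motivating biology, (iv) mitotic division-orientation measurements in
tissue sections. The questions are mechanistic: does the regulator sit at
accessible enhancers, does its loss deactivate them, does genome
architecture change, and do the genes topologically linked to affected
enhancers respond in the same direction?

## Element classification

Elements are classified by peak overlap (at least 1 bp shared, with a
configurable minimum-overlap parameter), with promoter precedence:
H3K4me3 overlap wins over any enhancer-mark combination; H3K4me1 with
H3K27ac is an active enhancer; H3K4me1 alone a poised enhancer; anything
else "other". Two open points were decided here:

* **Co-marked sites.** Peak sets overlap in practice; a site carrying
  H3K4me3 together with both enhancer marks is called a promoter because
  H3K4me3 is the promoter-defining mark. The alternative (active enhancer
  wins) changes only sites in the intersection, and the rule is isolated in
  one `case_when()` so it is easy to audit.
* **Peak overlap vs signal thresholds.** Classification uses binary peak
  overlap, not quantitative signal. Field practice varies; peak overlap is
  reproducible from deposited peak lists and requires no signal tracks.

Replicate reproducibility follows the "present in at least two samples"
convention: pooled peaks are clustered by ≥ 1 bp overlap and a cluster is
kept when it contains peaks from at least `min_support = 2` distinct
replicates; the reported interval is the union over cluster members.
Lowering `min_support` can only add peaks (monotonicity, enforced by a
test).

Temporal states combine the early-timepoint class with a differential
H3K27ac comparison between timepoints: early-active elements that
significantly lose acetylation are early-specific; early-poised elements
that significantly gain it are late-gained. "Significant" means FDR < 0.05
from the package's own differential test, since the classification source
names no test for this comparison.

## Differential signal

`differential_regions()` is deliberately simple: CPM normalisation per
replicate, log2 fold-change of mean CPM with pseudocount 0.5, a two-sided
Welch t-test on log2(CPM + 0.5) per region, Benjamini–Hochberg adjustment
across regions, and direction = sign of the fold-change for regions with
FDR below `alpha = 0.05`. It is documented as a transparent stand-in for
negative-binomial count callers, adequate for synthetic data with planted
effects — not a reimplementation of them, and not intended for production
differential calling on real counts. Known consequences, visible in the
test suite:

* With 3 replicates per arm power against a planted |log2FC| = 2 is
  moderate; the calibration checks therefore use 6 replicates per arm for
  power and 3 for null calibration.
* CPM normalisation absorbs composition shifts: if most regions move in one
  direction, fold-changes are biased toward zero. Generator-recovery tests
  that need raw effect sizes compute them from raw count means.

The Welch statistic is computed row-wise in vectorised form (hundreds of
simulations by a thousand regions would be slow through `t.test()` one
region at a time); a test pins the vectorised results to `stats::t.test`
and `bh_fdr()` to `stats::p.adjust(..., "BH")`.

## Genome architecture

**Merging.** Contact domains merge when *both* corresponding borders lie
within `border_tol = 20` kb; merging on a single border would chain
unrelated neighbours. The merge runs to a fixpoint and is idempotent. Loop
lists from two conditions merge when both left and right anchor midpoints
agree within `anchor_tol = 10` kb; midpoints are used because caller
anchors are fixed-width bins, making midpoints resolution-stable. Merge
conflicts are resolved greedily by smallest combined anchor distance; an
exhaustive oracle confirms the greedy choice on random small instances.

**Loop domains.** A domain is a loop domain when one loop has its left
anchor midpoint within `tol = 25` kb of the domain's left border and its
right anchor midpoint within 25 kb of the right border; all other domains
are compartmental. The two classes partition the input by construction.

**Observed/expected.** Expected contact at separation *d* is the mean over
all diagonal-*d* entries restricted to covered bins (bins with any
off-diagonal signal) — the standard distance-decay expectation. Intradomain
contact change is log2 of the ratio of mean O/E over intradomain bin pairs
(i < j), knockout over control. Mean versus sum over pairs is immaterial:
the pair count is condition-independent and cancels (asserted by a test).
The statistic is invariant to uniform rescaling of either matrix and
antisymmetric in the conditions.

One real limitation deserves emphasis: the per-diagonal expectation is
estimated from the same matrix, so if a large share of a chromosome's bins
sits inside perturbed domains, the expectation itself absorbs part of the
perturbation and the recovered change is biased toward zero (about
−0.1 log2 units when ~9% of bins change, about −0.02 at ~2%, measured on
noise-free synthetic matrices). The statistic is therefore trustworthy for
domain-specific changes, which is its intended use; genome-scale
perturbations would need an external expectation.

**Compartments.** Zero-coverage bins are dropped; the O/E matrix's columns
are correlated (Pearson), and the leading eigenvector of the correlation
matrix gives the compartment track (L2-normalised over covered bins, NA
elsewhere). The global sign is arbitrary, so it is first made deterministic
(largest-magnitude entry positive) and then oriented by requiring positive
correlation with per-bin H3K4me3 peak counts; positive bins are the
euchromatic A compartment. If the top two eigenvalues are closer than a
ratio of `gap_warn_ratio = 1.2` the block structure is weak and a warning
is raised — an invented but configurable safeguard. Note that the full
transform is *not* equivariant under bin permutation (the distance-decay
expectation depends on bin order); the correlation-plus-eigendecomposition
step is, and the test suite checks equivariance exactly there.

## Enhancer–gene linking and concordance

An element's position is its interval midpoint. TAD-constrained linking
requires the element midpoint and the candidate TSS to fall in the same
half-open merged domain and within `max_dist = 100` kb of each other; the
single nearest candidate wins, with ties broken by lexicographically
smallest gene id so results are reproducible. Domains must be
non-overlapping (the merge step guarantees this); overlap is an error
rather than a silent ambiguity.

Concordance restricts to links whose enhancer changed significantly and
asks whether the enhancer and gene fold-changes share a sign, stratified by
regulator occupancy. Genes that are not themselves significantly
differentially expressed still contribute their fold-change sign by
default — the source analysis states no gene-significance filter — and a
`strict_gene_de` switch excludes them for sensitivity analysis. The
stratum comparison is a Pearson χ² on the 2×2 table without continuity
correction; the one-sided p-value halves the two-sided tail when the
observed association matches the stated alternative (bound enhancers more
concordant) and is 1 − p/2 otherwise, with p = 1 at a zero statistic. The
dose–response view splits significant enhancers by sign and then into
`n_groups = 3` magnitude tertiles (quantile split; fixed fold-change
cutoffs were the plausible alternative), comparing extreme groups with
Welch tests.

## Cross-species overlap

Target sets are built by the same nearest-gene rule (TAD-constrained when a
domain list exists; distance-only otherwise, the mode used for a species
with no domain list). Sets and universe are restricted to one-to-one
orthologs — genes in many-to-many rows are dropped when filtering is
enabled, an error otherwise — and the overlap is tested with the exact
upper-tail hypergeometric probability P[X ≥ k]. The universe defaults to
the expressed, ortholog-mapped genes and is configurable; enrichment is the
default alternative, with depletion available.

## Division orientation

Angles are axial (a plane at θ and at 180° − θ is the same plane), so
simulated circular draws are folded to [0°, 90°] by reflection.
Classification cutoffs are `horiz_max = 30°` and `vert_min = 60°` —
symmetric thirds of the quadrant, exposed as parameters because no numeric
cutoffs are conventional. Under uniform angles the two extreme classes
subtend equal arcs, so the vertical:horizontal ratio is 1 in expectation
(a calibration test). Ratios are reported pooled and as per-animal mean ±
s.e.m. (animals are the experimental unit; horizontal divisions act as the
normalising factor). Rose histograms use half-open bins with the final bin
closed at 90° so counts always sum to n.

## The synthetic-data generators

`sim_config()` fixes every generator parameter in one validated object; a
fixed seed yields byte-identical outputs (each generator seeds R's RNG from
`seed` plus a fixed offset). Defaults encode the emulated study design:
element classes 24.2 / 29.0 / 36.3 / 10.5%, RNAPII at 42% of bound vs 17%
of unbound active enhancers, 83% of affected bound elements losing signal,
3 replicates per condition, early/late acetylation transitions of
37.5% / 32.2%, a ~25% loop-domain fraction, per-stratum enhancer–gene
concordance of 0.75 / 0.50, a planted enhancer–gene correlation of 0.35,
and 60 division events per animal for 3 animals per condition with von
Mises concentration κ = 4 about the preferred axis.

Where the emulated design states no value the defaults are explicit
placeholders chosen to be realistic at desk scale: negative-binomial counts
with dispersion 0.1 around log-normal base means (~100), planted
|log2FC| ~ N(2, 0.3), peak jitter ±25 bp and 5% replicate dropout, contact
decay exponent 1.0 with a +1 offset (avoiding the zero-separation
singularity), domain boost 2.0, compartment strength 0.4 in 10-bin blocks
at 50 kb resolution, and Poisson counting noise at a depth of ~60 contacts
for adjacent bins.

Two planting modes exist for expression links because one bivariate model
cannot produce both headline statistics at once: sign-agreement of a
bivariate normal with ρ = 0.35 is only ~0.61, so concordance rates of
0.75 / 0.50 and a Pearson r of 0.35 are planted by different mechanisms
(`link_model = "sign"` flips the gene's sign with the per-stratum
concordance probability; `link_model = "linear"` draws the gene fold-change
from a linear model calibrated to the target correlation). Contact-change
perturbations can be planted either as an independent per-domain fraction
(`frac_domains_changed`, the pipeline default of 5%) or as an exact count
(`n_domains_changed`), the latter matching the domain-specific scenario
under which the O/E statistic is unbiased (see above).

What the generators do *not* emulate — and hence what passing recovery
tests do not show about real data: read-level artefacts (mappability, GC,
duplication), peak-caller behaviour, matrix balancing (matrices are
generated already "normalised"), inter-chromosomal contacts, correlated
replicate structure, batch effects, and any coupling between the epigenome
and architecture layers beyond the planted links. Recovery on this
synthetic data validates the *rules and statistics*, not robustness to
real-data artefacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are well-powered while the whole suite stays fast: one
synthetic chromosome of 6–40 Mb at 50 kb matrix resolution (120–800 bins),
500–10,000 elements, 3 or 6 replicates per arm, 100–500 random instances
per oracle-equivalence property, and 100–200 Monte-Carlo repeats for
calibration checks. Numerical details: q-values are clamped to [0, 1];
degenerate zero-variance regions get p = 1 when the arms agree; O/E entries
on zero-expectation diagonals or uncovered bins are NA and excluded from
means; eigenvectors are deterministic up to the documented sign rule;
division angles at exactly 30° or 60° classify as horizontal and vertical
respectively (closed cutoffs); and all genomic coordinates are 0-based
half-open everywhere inside the package, converted only at the
GenomicRanges boundary.

## Known limitations

* The differential module is a replicate-level t-test stand-in; it does not
  model counts and should not be compared head-to-head with NB-GLM callers
  on real data.
* Intradomain contact change is biased toward zero when perturbations cover
  a non-trivial fraction of the chromosome (quantified above).
* Compartment calls on matrices without block structure are unstable by
  nature; the eigenvalue-gap warning flags, but does not prevent, such
  calls.
* Cross-species mapping requires precomputed ortholog tables; no coordinate
  liftover is attempted.
* The linking rules assign at most one gene per element (nearest-in-TAD);
  multi-target regulatory models are out of scope.
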