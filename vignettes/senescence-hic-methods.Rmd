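---
title: "Methods: 3D-genome reorganization analysis in cellular senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D-genome reorganization analysis in cellular senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seneschic analyses binned Hi-C contact maps through the lens of cellular
senescence: which megabase-scale compartments switch state when a cell
stops dividing, where senescence-associated heterochromatic foci (SAHF)
form, how TAD borders change, and how all of this couples to gene
expression. This vignette explains the models and conventions behind every
stage, the tunable parameters that matter, and what the synthetic-data
generator does and does not emulate.

## The data model

All analyses are cis-only and per-chromosome: a `contact_matrix` holds a
symmetric, non-negative matrix of contact counts on a uniform bin grid
(40 kb by default), plus a mask of excluded bins. Trans (inter-chromosomal)
contacts are out of scope; each chromosome is processed independently and
only genome-wide steps (border-score standardisation, enrichment tests)
pool across chromosomes. Coordinates are 0-based half-open; BED and
bedGraph output follow the same convention.

## Iterative correction (ICE)

Hi-C counts are distorted by multiplicative per-bin biases (mappability,
GC, restriction-site density). `ice_normalize()` removes them by iterative
correction: each sweep divides every entry by the product of its two bins'
normalised marginals, driving all unmasked row sums to a common value. The
default of 30 sweeps follows the convention the rest of the pipeline is
built around. Before iterating, the lowest-coverage 2% of bins (and any
empty bin) are masked; read-level filters operate upstream of this package,
so the coverage quantile is the only bin-level filter.

Convergence speed depends on matrix heterogeneity. On a matrix whose only
structure is distance decay plus separable biases, 30 sweeps reach a
relative row-sum spread of about 2×10⁻⁴; on a strongly structured map
(compartments, TADs, SAHF boosts) the same 30 sweeps land near 5×10⁻³ and
more sweeps are needed for machine-level balance. The iteration count is a
parameter, not a convergence criterion, which matches how the method is
used in practice. Balancing is scale-free, so the output is rescaled to
the input's total unmasked signal.

## Observed/expected and the expected-profile estimator

Compartment analysis works on the observed/expected (O/E) transform: every
contact is divided by the mean contact over all unmasked pairs at the same
bin separation on that chromosome. The estimator is the simple
per-diagonal mean with no smoothing — with 1000-bin chromosomes each
diagonal has hundreds of pairs and smoothing adds assumptions without
measurable benefit at this scale. Diagonals with zero expected value
produce O/E 0. By construction the unmasked mean of each diagonal is 1.

## Compartment scores

`pca_scores()` computes the Pearson correlation matrix of the O/E columns
(masked and zero-variance bins dropped) and extracts its leading
eigenvector. The per-bin score is the unit eigenvector entry ×
√eigenvalue × 100, a scaling chosen so magnitudes land in the tens. Two
conventions make the score deterministic and interpretable:

* **Sign orientation.** An eigenvector's global sign is arbitrary; the
  score is flipped, if necessary, so that it correlates positively with a
  per-bin gene-density track. Gene-rich, euchromatic A compartments score
  positive; gene-poor heterochromatic B compartments score negative.
* **Degeneracy warning.** If PC1 carries less than 10% of the positive
  eigenvalue mass the function warns that compartment separation is weak;
  there is no automatic fallback to PC2, because a silent fallback can
  flip the biological meaning of the track.

A/B compartments are maximal same-sign runs of at least five consecutive
bins (`call_compartments()`, 200 kb at the default resolution). Shorter
runs and missing bins stay unassigned rather than being merged into a
neighbour: merging would manufacture compartment borders that the score
track does not support. A score of exactly zero is treated as unassigned.

## Transitions, BAB reversals and SAHF

`classify_transitions()` labels every bin by its sign pair across two
conditions — AA, BB (stable), BA (B-to-A switch, the hallmark expansion of
active chromatin in senescence), AB (the reverse) — with `NA` wherever
either score is missing or zero. Maximal runs of one switch category form
switch regions; no minimum length is imposed because the underlying
regions are genuinely small (usually 100–500 kb). `classify_bab()` flags
bins that switch B→A in a first contrast (growing → senescent) and A→B in
a second (senescent → condensin-depleted): reversals that tie the switch
to condensin activity.

SAHF detection is a threshold on the compartment score: bins scoring below
the threshold are flagged and contiguous runs reported as regions. **The
threshold is calibration-dependent.** The score scale is an emergent
property of the eigenvector convention and of the data's contrast
structure; the familiar −20 convention (the package default) belongs to
the scaling used on human 40 kb maps. On the synthetic genome described
below, A and SAHF bins saturate near ±60–80 while weakly heterochromatic
bins sit above −30, and the equivalent separating threshold is −40 — the
value the package's own validation uses. When applying `detect_sahf()` to
new data, inspect the score distribution first; the gap between the bulk
of B bins and the extreme tail is the calibration target, not the number
−20 itself.

`lvs_scores()` complements the threshold with a scale-free signature: the
fraction of a bin's cis contact mass (diagonal excluded) carried by
partners more than 2 Mb away. SAHF form by long-range aggregation of
heterochromatin, so SAHF bins show elevated LVS. LVS is computed from the
balanced matrix (the bias structure would otherwise leak into the
numerator and denominator differently).

## TAD border strength

For each bin with a full window on both sides (13 bins of 40 kb by
default), the raw border score is

R = (sum of within-upstream-window pairs + sum of within-downstream-window
pairs) / (sum of upstream-by-downstream pairs),

with unordered pairs counted once and the diagonal excluded — a frozen
convention, because the oracle tests depend on it; on a uniform matrix
every interior bin scores exactly 156/169 (78 + 78 within-pairs over
13 × 13 between-pairs). A small epsilon (10⁻⁶ × mean contact) guards the
denominator on perfectly insulated toy inputs. Masked bins are excluded
from the pair sums and each sum is rescaled to its full pair count, so a
masked bin lowers precision locally instead of displacing the insulation
maximum. Raw scores are standardised genome-wide (pooled across
chromosomes, mean 0, SD 1 over defined bins); a zero-variance profile
yields all-zero z-scores with a warning.

Borders are thresholded local maxima of z (strictly greater than both
neighbours, plateaus resolved to the leftmost bin) with z ≥ 1 by default.
One practical constraint matters: the window must be smaller than the
domains being sought. The 13-bin (520 kb) window suits the ~0.5–1 Mb
domains of real maps; on the synthetic genome, where planted TADs are
exactly 400 kb, validation uses a 5-bin window, since a window wider than
the domain straddles neighbouring borders and suppresses their maxima.

Replicate specificity (`classify_border_specificity()`) matches borders
across datasets within ±1 bin: condition-1-specific borders are present in
every condition-1 replicate and no condition-2 replicate;
condition-2-specific in at least two condition-2 replicates and no
condition-1 replicate; remaining borders seen in at least two datasets are
non-specific; everything else is unclassified. The same ±1-bin tolerance
governs the overlap of TAD borders with compartment borders.

## Enrichment statistics

* `hypergeometric_overlap()` — upper-tail overlap test computed in log
  space, so tails far below double underflow (overlaps of switch regions
  between deep-coverage replicates routinely reach p ~ 10⁻¹⁰⁰ and beyond)
  remain representable through the `log10_p` column. It doubles as the
  one-sided Fisher exact test for gene-set enrichment against plain-text
  gene-group files, with `benjamini_hochberg()` for multiplicity.
* `preranked_gsea()` — weighted Kolmogorov–Smirnov running-sum enrichment
  of a gene set in a ranked list (weight 1 on |score| by default; the
  exponent is exposed because conventions differ). Pre-ranked input admits
  only a gene-label permutation null: random sets of the same size drawn
  from the ranked universe. NES divides ES by the mean magnitude of
  same-sign null scores, and the p-value counts same-sign null scores at
  least as extreme, add-one corrected, so p ≥ 1/(n_perm + 1) and the
  type-I error is calibrated (the test suite checks the rejection rate of
  2000 null sets at α = 0.05).
* Distance-window analysis — gene-to-SAHF distance is the gap between the
  gene body and the nearest SAHF edge on the same chromosome (0 on
  overlap, measured from edges rather than centres so large foci do not
  inflate distances). `sahf_window_sweep()` drives sliding or cumulative
  windows and reports per-window percent of downregulated genes
  (fold change strictly below 1) against the genome-wide control.
* `summarize_track_by_category()` samples up to 500 bins per compartmental
  category (seeded, without replacement; all bins with a warning when
  fewer exist) and compares signal distributions with two-sided
  Mann–Whitney U tests — exact enumeration when the smaller sample has ≤8
  values and no ties, normal approximation with tie correction otherwise;
  two identical samples return p = 1 directly.
* `metagene_profile()` rescales every gene body (TSS→TES, strand-aware) to
  a fixed number of points with fixed-bp flanks and averages a per-bin
  track within expression groups (deciles by default).
* `rank_compartment_contact_change()` averages within-compartment O/E per
  condition on a coarse grid (typically 200 kb via `coarsen()`), ranks
  compartments by the condition ratio (coordinate order breaks ties), and
  selects the bottom fraction — the compartments losing the most internal
  contact, whose genes feed the GSEA stage.

## The synthetic-data generator

`synthetic_config()` / `plant_architecture()` / `simulate_contacts()` /
`simulate_expression_and_tracks()` produce a compact genome (two 40 Mb
chromosomes of 1000 × 40 kb bins by default — large enough for 2 Mb
long-range cutoffs and 13-bin windows, small enough for seconds-scale
runs) with exported ground truth for every recovery metric.

The contact model is a two-state mixture. Each bin carries a continuous
B-state membership weight: A bins nearly pure A-state (0–0.15), plain B
bins weakly B-biased (0.55–0.62 in senescent conditions, 0.70–0.80 in
growing cells), SAHF bins nearly pure B-state (0.9–1.0). Pair affinity is
bilinear in the membership weights (same-state 2×, cross-state 0.6×),
multiplied onto a power-law distance decay (exponent 1), a within-TAD
multiplier (3×), and — in senescent conditions only — a 3× boost on >2 Mb
contacts between SAHF bins. Planted per-bin log-normal biases (SD 0.5)
and pair-level log-normal overdispersion (SD 0.45) sit on top, and counts
are independent Poisson draws, symmetrised and fully seeded.

Two modelling choices deserve explanation because they are what makes the
planted phenomenology recoverable at all:

* **Continuous membership, not binary labels.** On a correlation matrix,
  profile amplitude normalises out: with binary A/B structure and low
  noise, every same-sign bin saturates at the same |PC1| entry and no
  threshold can distinguish SAHF from ordinary heterochromatin. Real
  compartment scores are graded because real bins are mixtures
  (population heterogeneity, facultative heterochromatin). The membership
  weights, together with the pair-level noise floor, reproduce that
  gradation: weakly B-biased bins score mildly negative, SAHF bins
  extreme.
* **Condition-dependent plain-B strength.** Distributed heterochromatin
  is strong in growing cells and weakens as it concentrates into SAHF
  upon senescence. Besides being the biological picture, this is what
  keeps growing-condition compartment signs stable while leaving the
  senescent score distribution with a clean gap between plain B and SAHF.

Other conventions: SAHF candidates are persistent-B stretches (B in both
conditions, ≥8 bins); selected foci are kept >2 Mb apart so each has
long-range partners, with at least two per chromosome — a single isolated
focus would be undetectable by construction. SAHF stretches are condensed,
TAD-free domains with a 2× internal density multiplier that keeps their
coverage comparable to TAD-carrying bins (otherwise the low-coverage mask
would systematically eat them). Switch segments are 100–500 kb, planted
with a one-bin guard so each stays an individually sized region, with
B→A segments twice as abundant as A→B and half the B→A segments reverting
under depletion (the BAB set). Genes tile bins with probability 0.8 in A
and 0.3 in B (the gene-density signal that orients score signs); log2
fold changes are Normal(effect, noise) with +1 on B→A bins, −1 on A→B
bins, a −0.6 shift for genes 500–700 kb from SAHF, and −1 on BAB bins in
the depletion contrast.

What the generator does **not** emulate: a realistic karyotype,
replication timing, lamina association, loops/anchors, sub-compartments,
read-level artefacts (the pipeline starts from binned matrices), and
trans contacts. Passing recovery tests therefore demonstrates that the
algorithms are correct and well-calibrated on data satisfying their
assumptions — not that those assumptions hold on any particular real
dataset.

## Validation problem sizes and numerical choices

The package's validation runs on 1000-bin chromosomes at a mean depth of
50 expected counts per bin pair, with 30 ICE sweeps, and 200–1000
permutations for GSEA (200 in the 2000-trial calibration, 1000 for single
tests); these sizes keep the full suite at about a minute while leaving
every effect many standard errors from its threshold. All randomness is
seeded; fixtures run at the generator's canonical default seed. Degenerate
inputs are handled explicitly rather than by NaN propagation: all-zero
matrices error, zero-variance z-scores warn and return 0, empty gene
lists return missing values, and identical samples return p = 1.

## Known limitations

* The compartment score scale — hence any absolute SAHF threshold — is
  convention-dependent; cross-dataset comparisons should use occupancy,
  LVS, or rank-based summaries instead of raw score magnitudes.
* ICE assumes separable multiplicative biases; copy-number variation
  violates that assumption and will be partially absorbed into the
  balancing.
* Border calling reports point maxima; nested or hierarchical domains are
  out of scope.
* The pre-ranked GSEA null permutes gene labels, which ignores
  inter-gene correlation; p-values on strongly co-regulated sets are
  anti-conservative, as with any pre-ranked analysis.
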