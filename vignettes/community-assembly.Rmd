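---
title: "Quantifying neutral and deterministic assembly in host-associated microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neutral and deterministic assembly in host-associated microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmtools)
```

## The question

When a fish gut (or any host organ) is colonized by microbes, two kinds of
process shape the community. *Neutral* processes — passive dispersal from a
source pool and ecological drift — predict that a taxon's prevalence across
hosts is a simple function of its abundance in the source. *Deterministic*
processes — habitat filtering, host selection, competition — produce taxa
that are systematically more or less prevalent than dispersal alone can
explain. `ncmtools` implements the standard toolkit for separating the two
from 16S OTU tables: the Sloan neutral community model (NCM) with chained
source→target designs, phylogenetic dispersion indices (NRI/NTI),
generalized UniFrac + PERMANOVA + PCoA, and alpha-diversity rank
statistics, together with a generative simulator that makes every stage
testable against ground truth.

The motivating study design is an anadromous salmonid: gut compartments
sampled along the digestive tract of farmed fish (feed/water → stomach →
pyloric cecum → midgut → bile duct) and midgut communities across wild
life-cycle stages (parr, smolt, marine adult, returning adult) compared to
their water source.

## The neutral community model

The local community has (roughly) `N` individuals per sample; the
metacommunity supplies immigrants at per-death probability `m`. At
stationarity, the relative abundance `x` of a taxon with metacommunity
relative abundance `p` follows

    x ~ Beta(N m p, N m (1 - p))

Only the product `Nm` is identifiable from occupancy data. A taxon is
*detected* in a sample when at least one read maps to it; with depths near
`N` that corresponds to a relative-abundance detection limit `d = 1/N`. The
model's predicted occurrence frequency is the upper beta tail

    f(p) = 1 - I_d(Nm p, Nm (1 - p))

with `I_d` the regularized incomplete beta function
(`predict_frequency()`). `fit_ncm()` estimates `m` by nonlinear least
squares of observed occurrence frequencies on `f(p)`, using a bounded Brent
search on `m ∈ (1e-8, 1]` at tolerance `1e-10` (a single smooth parameter;
no multistart is needed, and ties resolve toward smaller `m`). Goodness of
fit is the ordinary coefficient of determination `R² = 1 - SSE/SS_tot`,
which can be negative when the model is worse than the mean. Uncertainty on
`m` comes from a seeded nonparametric bootstrap over OTUs (percentile
interval, 1000 resamples by default); the model itself provides no
sampling distribution for `m`, so resampling the OTU ensemble is the
natural choice.

Conventions worth stating explicitly:

* `p` is the **mean of per-sample relative abundances** over the source
  samples, not the pooled-count proportion, so a single deep source sample
  cannot dominate the metacommunity estimate.
* Taxa absent from the source (`p = 0`) cannot be fit; they are reported in
  `excluded_taxa`, never silently dropped.
* `N` is the rounded mean target depth. Per-sample depths vary (the
  simulator jitters them ±20% on purpose), and using the mean-`N`
  convention with `d = 1/N` is part of the model error the tests
  quantify.

## Partitioning OTUs: why a binomial band, not a Wilson interval

An OTU "fits" the model when its observed occurrence frequency is
consistent with the prediction. The observed quantity is a count `k` out
of `n` target samples. Given the prediction `f`, the exact reference
distribution of `k` is Binomial(`n`, `f`), so `partition_otus()` classifies
an OTU *above* (over-represented — candidate host selection, the
*Mycoplasma*-like signature) when `k` exceeds the `1 - α/2` binomial
quantile, and *below* (selected against) when it falls under the `α/2`
quantile, at `level = 0.95` by default.

A widely used convention instead places a Wilson score interval around
`f`. The Wilson interval answers the inverse question (a CI for an unknown
proportion given an observation) and misbehaves exactly where microbiome
data live: at saturated occupancy. With `f = 0.984` and `n = 50`, observing
`k = 50` has probability 0.45, yet 50/50 lies outside the Wilson band — in
simulations this flagged over a third of genuinely neutral, common OTUs as
"above". The binomial band keeps its nominal pointwise error rate
everywhere (conservatively, because `k` is discrete); the Wilson variant
remains available as `ci_method = "wilson"` for comparability. A
consequence of the discrete band worth knowing: at `f` within `1/n` of 1
the band can sit entirely at `k = n`, so a single missing detection is
(correctly, at the stated error rate) scored "below".

`sequential_chain()` applies the fit along an ordered design either
*stepping-stone* (each community is the source of the next compartment
downstream) or *common-source* (every life stage against the same water
community), returning one fit per link keyed `"A->B"`.

## Phylogenetic dispersion (NRI/NTI)

For each sample, `ses_dispersion()` compares the observed mean pairwise
cophenetic distance (MPD) or mean nearest-taxon distance (MNTD) of the taxa
present against a null obtained by redrawing the same number of taxa
uniformly, without replacement, from the table's full taxon pool (999 runs
by default). The standardized effect size is
`ses = (obs - null_mean)/null_sd`, and the reported indices follow the
Webb sign convention: `NRI = -SES(MPD)`, `NTI = -SES(MNTD)` — positive
means phylogenetic clustering (habitat filtering), negative means
overdispersion, and neutrally assembled communities should sit near zero.
Because sign conventions are a recurring source of confusion in the
literature, the output always carries both `ses` and `index` columns.

Two implementation notes:

* Under this null, the distribution of the metric depends only on
  community richness, so the null is computed once per distinct richness
  value and shared across samples — identical in distribution, bit-reproducible
  under the seed, and much faster on tables where richness repeats.
* The pool is the set of taxa observed anywhere in the analyzed table (per
  comparison), not a global study pool. A sample containing the entire
  pool has a degenerate null (`null_sd = 0`) and is flagged
  `defined = FALSE` rather than given an arbitrary score, as are samples
  with fewer than two taxa.

One subtlety the simulator exposes: even for neutrally assembled samples
the *mean* index over samples need not be exactly zero for one particular
tree, because all samples share the same abundant core taxa and that core
may, by chance, be slightly clustered on that tree. Calibration is
therefore asserted over uniform random communities (where the null is
exact), and clade-restricted communities are used as the positive control
(mean NTI well above 2 on a tree whose clade branches are shortened
tenfold).

Group-level contrasts (`compare_dispersion()`) use Kruskal–Wallis across
groups and pairwise Wilcoxon rank-sum tests with Benjamini–Hochberg
adjustment, the same machinery as the alpha-diversity comparisons; groups
with fewer than two defined samples are excluded with a warning.

## Beta diversity

`gunifrac()` implements generalized UniFrac: for samples A and B and every
branch `b` with length `L_b`, let `p_A`, `p_B` be the relative abundance
summed over tips descending from `b`; then

    d_α(A, B) = Σ_b L_b (p_A + p_B)^α |p_A − p_B| / (p_A + p_B)
              / Σ_b L_b (p_A + p_B)^α

skipping branches with `p_A + p_B = 0`. `α = 1` is weighted-normalized
UniFrac (the test suite verifies this against an independent
implementation to 1e-8); `α = 0.5`, the default, moderates the dominance
of abundant lineages. Distances are invariant to overall branch-length
rescaling and to taxon row order. Taxa missing from the tree are a hard
error — silent pruning would change the denominators of every distance.

`permanova()` computes the one-way pseudo-F from the Gower decomposition of
squared distances (`SS_total = Σ_{i<j} d²_{ij}/n`, within-group sums
analogously) with seeded label permutations and the +1 correction, so the
smallest attainable p is `1/(n_perm + 1)`; small designs can request
exhaustive enumeration of all distinct label assignments, giving exact
permutation p-values. Raw distances are used (no square-root transform) and
only one-way designs are supported, which covers every grouping in the
motivating design. Ordination is classical PCoA (`pcoa_ord()`): the methods
literature for this kind of survey names NMDS in places but presents PCoA;
the package implements the deterministic PCoA only, reporting negative
eigenvalues rather than correcting them.

## The synthetic-data generator

`simulate_study()` builds the study the model assumes, plus controlled
departures:

* **Metacommunity** (`make_metacommunity()`): lognormal(0, 1) rank
  abundances by default (geometric series available), normalized, sorted.
* **Neutral samples** (`simulate_neutral_samples()`): composition ~
  Dirichlet(`Nm·p`), counts ~ Multinomial(depth). The Dirichlet was chosen
  precisely because its taxon-wise marginals are the Beta(`Nm p`,
  `Nm(1-p)`) distribution the NCM fits, which makes parameter recovery a
  well-posed test rather than an approximation. A Kolmogorov–Smirnov check
  of that marginal is part of the suite.
* **Source samples** are generated at `Nm = 1e8`, i.e. faithful replicates
  of `p`, mirroring the role of pooled environmental samples as the
  metacommunity proxy.
* **Selected taxa** (`inject_selected()`): "above" taxa are planted in
  every target sample at a forced relative abundance (other counts
  rescaled by largest-remainder rounding so column totals are exactly
  preserved); "below" taxa are zeroed outside a chosen occupancy fraction
  with reads redistributed. Note an asymmetry that follows from the model
  itself: a taxon common in the source (`p ≈ 0.005` at the default `Nm`)
  has predicted occupancy ≈ 1, so *no* forced occurrence can exceed the
  band — detectable over-representation requires a source-rare taxon. The
  power checks therefore inject "above" taxa at `p ≈ 2e-4` (predicted
  occupancy ≈ 0.5) and "below" taxa at `p ≈ 0.005`.
* **Phylogeny** (`simulate_tree()`): sequential random joins with
  exponential(1) branch increments; an optional monophyletic clade with
  branch lengths scaled by 0.1 provides the clustering signal.
* **Depth structure**: per-sample totals jitter ±20% around `N = 10,000`
  reads, and `n_shallow` extra samples with 1,000–7,999 reads emulate the
  samples an 8,000-read depth filter should discard (`filter_min_reads()`
  drops samples strictly below the threshold; a sample at exactly 8,000
  reads is kept).

Defaults (`S = 300` taxa, 10 source + 50 target samples, `N = 10,000`,
`Nm = 1000`) are the package's standing study conditions; `Nm` values of
100–10,000 span strong drift to near-faithful sampling. These defaults aim
at test power and well-posedness, not at any claim about the true migration
regime of a real fish gut.

What the generator deliberately does **not** emulate: sequencing error and
chimeras, taxon–taxon interactions, abundance–phylogeny correlation,
temporal dynamics, or compositional artifacts of amplification. Passing
tests therefore demonstrate that the estimators recover truth *under the
model's own assumptions* (plus multinomial read noise), not that real gut
data satisfy those assumptions.

## Reproducibility and numerical choices

* Every stochastic function takes an integer `seed` and runs under a
  restored RNG state (`withr::with_seed`); nothing perturbs the caller's
  RNG.
* `run_pipeline()` derives one sub-seed per stage from the global seed via
  a stable string-tag hash (`derive_seed()`), so adding or reordering
  stages never shifts another stage's random stream; with a fixed seed the
  output bundle is byte-identical across reruns (the manifest carries no
  timestamps).
* Depth filtering is applied once, globally, before any per-group
  analysis.
* Missing newick branch lengths are an error unless unit lengths are
  explicitly requested; negative lengths are always an error.
* Count-preserving renormalizations use largest-remainder rounding with
  index-order tie-breaks, so they are deterministic.
* In the test suite the long-running checks use reduced problem sizes
  chosen for statistical head-room (e.g. 20 replicate studies for
  recovery, 220 communities × 999 null draws for SES calibration, 200
  simulations for PERMANOVA type-I error, and a compact 5-group pipeline
  for the byte-identity check); the vignette-scale defaults remain those
  stated above.

## Known limitations

* Only the product `Nm` is identified; reported `m = Nm/N` inherits the
  mean-depth convention.
* The fit is least-squares on occurrence frequencies, not a likelihood; at
  `Nm` near or above `N` the occupancy curve saturates, the estimate loses
  precision, and the optimizer may sit at the `m = 1` boundary (flagged
  `saturated`).
* The NCM assumes one homogeneous source per comparison; multi-source
  mixtures (e.g. weighting feed against water) are pooled with equal
  per-sample weight, and source-tracking is out of scope.
* NRI/NTI use the unweighted (presence) metrics with a uniform-pool null;
  abundance-weighted nulls, and turnover-based assembly classification
  (betaNTI / Raup–Crick), are not implemented.

## A minimal session

```{r example, eval = FALSE}
study <- simulate_study(sim_config(
  Nm = 1000, seed = 7,
  selected_above = list(list(taxon = 290, rel_abundance = 0.01)),
  selected_below = list(list(taxon = 60, occupancy = 0.1))))

input <- build_ncm_input(study$source_table, study$target_table)
fit <- fit_ncm(input, bootstrap = 1000, seed = 7)
fit
subset(fit$records, partition != "neutral")

disp <- ses_dispersion(study$target_table, study$tree, "MNTD",
                       runs = 999, seed = 1)
D <- gunifrac(study$target_table, study$tree, alpha = 0.5)
```
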