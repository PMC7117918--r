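# ncmtools

Tools for asking a basic question about host-associated microbiomes: how
much of a community's membership is explained by passive dispersal and
drift from a source pool (*neutral* assembly), and which taxa deviate from
that expectation in a way that suggests selection by the host
(*deterministic* assembly)? The package was built around the study design
of an anadromous salmonid — gut compartments chained along the digestive
tract of farmed fish, and midgut communities across wild life-cycle stages
compared to their water source — but works for any source→target OTU-table
comparison.

## What it computes

**Sloan neutral community model.** With local community size *N* and
migration rate *m*, the relative abundance *x* of a taxon whose
metacommunity abundance is *p* follows Beta(*Nm p*, *Nm*(1 − *p*)), so its
expected occurrence frequency above a detection limit *d* (= 1/*N* for
one-read detection) is

    f(p) = 1 − I_d(Nm p, Nm (1 − p))

where *I_d* is the regularized incomplete beta function. `fit_ncm()`
estimates *m* by nonlinear least squares of observed occurrence
frequencies on *f(p)* (bounded Brent search, tolerance 1e-10), reports
*R²* and a seeded bootstrap CI, and `partition_otus()` classifies each OTU
`neutral` / `above` / `below` against a 95% binomial prediction band around
its predicted frequency. `sequential_chain()` runs the fits through a
stepping-stone design (upstream compartment as source of the next) or a
common-source design (each life stage vs the same water community).

**Phylogenetic dispersion.** `ses_dispersion()` computes per-sample MPD and
MNTD against a seeded uniform taxon-pool null, yielding NRI = −SES(MPD)
and NTI = −SES(MNTD) (positive = clustering/habitat filtering), with
Kruskal–Wallis / BH-adjusted Wilcoxon group contrasts.

**Diversity statistics.** Alpha diversity (richness, Shannon, Pielou) with
rank tests; generalized UniFrac distances `d_α` (α = 0.5 default, α = 1 is
weighted-normalized UniFrac); one-way PERMANOVA (seeded permutations, or
exact exhaustive enumeration on small designs); classical PCoA; genus-level
differential abundance with BH control.

**Synthetic studies.** `simulate_study()` generates source/target OTU
tables by Dirichlet-multinomial sampling — whose taxon-wise marginals are
exactly the beta distribution the model fits — plus injected selected taxa,
clade-restricted communities, a random phylogeny, sub-depth-filter samples,
and ground-truth labels for every taxon.

`run_pipeline()` chains everything (depth filter at 8,000 reads → NCM
chain → NRI/NTI → alpha → GUniFrac/PERMANOVA/PCoA) into a TSV/JSON report
bundle that is byte-identical under a fixed seed.

## Worked example

Simulate a study at migration regime *Nm* = 1000 with one planted
host-selected taxon (source-rare, forced into every fish at 1% relative
abundance) and one selected-against taxon (source-common, capped to 10%
occupancy), then fit:

```r
library(ncmtools)

study <- simulate_study(sim_config(
  Nm = 1000, seed = 7,
  selected_above = list(list(taxon = 290, rel_abundance = 0.01)),
  selected_below = list(list(taxon = 60, occupancy = 0.1))))

input <- build_ncm_input(study$source_table, study$target_table)
fit <- fit_ncm(input, bootstrap = 1000, seed = 7)
fit
#> Neutral community model fit: 300 OTUs
#>   m = 0.1241 (Nm = 1257.5, N = 10133, d = 9.87e-05)
#>   bootstrap 95% CI for m: [0.11201, 0.14301]
#>   R2 = 0.7478
#>   partition: 91.7% neutral, 1.3% above, 7.0% below
```

The fitted *Nm* ≈ 1258 recovers the generative value within the usual
~15% (occurrence data identify *Nm* only approximately), ~92% of truly
neutral OTUs are classified neutral, and both planted taxa are found:

```r
fit$records[fit$records$otu_id %in% c("OTU_0290", "OTU_0060"), ]
#>       otu_id        p f_obs f_pred ci_low ci_high partition
#> 60  OTU_0060 0.004885   0.1  1.000   1.00    1.00     below
#> 290 OTU_0290 0.000317   1.0  0.527   0.38    0.66     above
```

OTU_0290 is the *Mycoplasma*-like signature: rare in the source
(p ≈ 3e-4, predicted occupancy 0.53) yet present in every fish — assembly
that dispersal cannot explain. OTU_0060 is common in the source
(predicted occupancy ≈ 1) but nearly absent from hosts — selected against.
Downstream stages consume the same objects:

```r
disp <- ses_dispersion(study$target_table, study$tree, "MNTD",
                       runs = 999, seed = 1)   # NTI per sample
D    <- gunifrac(study$target_table, study$tree, alpha = 0.5)
perm <- permanova(D, groups, n_perm = 999, seed = 1)
```

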