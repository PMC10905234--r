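---
title: "Methods: decontamination and diet statistics for scat metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decontamination and diet statistics for scat metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scatdiet analyses predator diet from DNA-metabarcoding of scat samples. Its
study system is the Galapagos sea lion (*Zalophus wollebaeki*): scats from
several rookeries, a ~250 bp 16S prey barcode amplified with and without a
predator-blocking primer, reads clustered upstream into 97% OTUs, and a
BLAST-style best hit per OTU. The package starts at the OTU-by-sample
read-count table — everything upstream (demultiplexing, merging, quality and
chimera filtering, clustering) belongs to standard read-processing tools and
is out of scope.

This vignette documents the models and procedures, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The decontamination cascade

Raw scat metabarcoding tables are dominated by predator reads and carry
several contamination modes: tag switching (index hopping) moves reads
between samples, non-marine taxa enter during collection and lab work, and
cross-contamination spreads abundant OTUs at trace levels. The cascade in
`run_filter_cascade()` applies, in order:

1. **Assay pooling** (`pool_assays`): the blocking and no-blocking PCR
   replicates of each scat are summed before any threshold, so thresholds
   act on the scat's full read complement.
2. **Tag-switch floor** (`compute_tag_switch_floor`,
   `nullify_below_floor`): predator DNA is the one taxon certain to be
   absent from extraction blanks except through misassignment, so the
   maximum predator-read fraction across negative controls estimates the
   per-sample leakage rate. Cells strictly below that relative abundance
   are nullified, totals taken before nullification.
3. **OTU screening** (`screen_otus`): OTUs with no hit, best-hit identity
   strictly below 70%, predator (otariid) matches, or obvious non-marine
   (blacklist) matches are removed, with reasons logged.
4. **Control-based filters** (`control_based_filters`): a cell is nullified
   when its count is *less than or equal to* the maximum count of that OTU
   across negative controls (a per-cell reading of the rule, configurable
   to the sum); then each sample's obvious-contaminant read fraction `c`
   becomes a sample-specific floor — any OTU strictly below `c` in that
   sample is nullified — after which the contaminant columns are dropped.
   The contaminant proportions are therefore measured *before* their
   columns disappear, which is why the cascade defers contaminant-column
   removal past step 3.
5. **Minor-OTU rule** (`minor_otu_filter`): cells strictly below 1% of
   their sample's reads are nullified; dataset-wide singletons (total
   abundance one read; configurable to "present in one sample") are
   removed.
6. **Sample exclusion** (`exclude_samples`): negative controls are dropped;
   samples with fewer than 2 prey reads are dropped; then samples strictly
   below the 25th percentile of the remaining per-sample totals (linear
   interpolation, type-7 quantile) are dropped. Samples exactly at the
   cutoff stay.
7. **Cleanup**: all-zero OTU columns, plus singletons re-created by sample
   exclusion, are removed.

Inferential statistics use `subset_inferential()` — samples with at least
100 prey reads (inclusive).

Two ordering questions are not determined by the workflow description and
were fixed as package decisions: the tag-switch floor is applied after
pooling the two assays, and the quartile cutoff is computed after removing
the 0–1-read samples. Both are configurable.

**Idempotence.** Every step is monotone (no cell ever increases, nothing is
added), and each per-sample rule is a fixed point on its own output. The
one data-derived threshold that moves on re-application is the lowest
quartile: the 25th percentile of already-truncated totals is higher by
construction. The cascade therefore records its derived thresholds (floor,
quartile cutoff) in the `filter_report`, and re-running with those
thresholds frozen into the config removes nothing; with the quartile step
disabled, plain re-application is an exact fixed point. Both forms are
tested.

## Taxonomy assignment

An OTU whose best hit reaches 96% identity is assigned to the hit species
*provided* the species occurs on the regional checklist (case-insensitive
binomial match; synonyms out of scope); otherwise it escalates to genus,
flagged unconfirmed. Below 96%, ranks come from identity bands —
genus at 92%, family at 85%, order below — a reproducible, offline
replacement for manual tree-based placement of low-identity hits. The band
edges are configurable (`identity_bands()`); published analyses placed
low-identity OTUs by phylogenetic inspection, so band-derived rank labels
can differ for those OTUs. OTUs sharing an assigned name and rank collapse
to one taxonomic entity (`collapse_entities`).

Prey categories follow the five habitat classes (epipelagic 0–200 m,
mesopelagic 200–1000 m, bathypelagic 1000–3000 m, rocky bottom 0–200 m,
rocky bottom-deep >200 m) and five half-unit trophic bins from 2.0–2.5
(planktivore) to 4.1–4.5 (carnivore). The printed bins leave one-decimal
gaps (e.g. 2.5–2.6); a trophic level falling in a gap goes to the nearest
bin, ties rounding up, since the bins clearly intend a partition of
one-decimal values.

## Diet summaries

Counts are reduced to presence/absence for all diet statistics — read
counts are a biased proxy for biomass, occurrence is the conservative
choice. For each rookery, `FOO_i` is the fraction of samples containing
item *i* and `POO_i = 100 · FOO_i / Σ_j FOO_j`, so each rookery's POO
vector sums to 100. Category POO treats a sample as containing a category
when it contains any item of that category; items without traits are
excluded from category summaries but stay in item summaries.

Sample-based rarefaction uses the incidence form
`E[S_n] = Σ_i (1 − C(N−f_i, n)/C(N, n))`, with the exact variance
including pairwise joint-absence terms, and a normal 95% CI
(`E ± 1.96·sd`) matching the symmetric intervals conventionally reported.
Read-based curves use the hypergeometric expectation on rookery-pooled
counts and report the depth at which the estimate's coefficient of
variation falls to 0.05. The exact variance formula behind published CIs
is rarely stated; the classical incidence-based form is assumed here and
validated against exhaustive subset enumeration in the tests.

## Community statistics

All multivariate statistics work on Jaccard distances among samples
(`1 − |x∩y|/|x∪y|`) and are implemented from first principles, with vegan
serving as an independent cross-check in the test suite only.

**PERMANOVA** (`permanova`) Gower-centres the squared-distance matrix and
takes sequential (type-I) sums of squares through projection matrices in
the user-given term order — rookery first, then the per-sample read count
as a covariate, matching the convention where term R²s plus residual sum
to one. Significance comes from whole-sample label permutation with the
`(1 + b)/(1 + m)` convention, which cannot produce p = 0 and makes the
test exactly sized at achievable levels. Pairwise comparisons run one
PERMANOVA per rookery pair with Holm correction.

**PERMDISP** (`permdisp`) embeds the distances by principal coordinates
keeping positive and negative eigenvalue axes, computes each sample's
distance to its group centroid as `sqrt(d₊² − d₋²)` (negative radicands
clamped to zero and counted), and tests the group means with a one-way
ANOVA F whose p-value comes from permuting group labels of the
dispersions. Pairwise comparisons use Tukey HSD on the dispersions with a
Holm correction on top, mirroring the published table layout.

**NMDS** (`nmds`) minimises Kruskal stress-1 by alternating an isotonic
(pool-adjacent-violators) fit of configuration distances to the
dissimilarity order with a Guttman transform update; disparities are
rescaled to the configuration's scale each iteration. Ties use the primary
approach — within tie blocks the fit follows the current distances.
Defaults: one metric-MDS (classical scaling) start plus 19 random starts,
1000 iterations, stress-change tolerance 1e-9; the best start is returned,
centred and rotated to principal axes. Sparse binary diet data often
admits near-zero-stress (nearly degenerate) solutions; stress values
should be read alongside the configuration, as with any NMDS.

**Schoener overlap** `D = 1 − 0.5·Σ|p_x − p_y|` on renormalised diet
proportion vectors; POO-based by default, FOO behind a flag, computed on
the inferential subset by default (whether published overlaps used the
full or subset matrix is not stated; both are supported).

**IndVal** (`indval`) scores every item against every non-trivial union of
rookeries: specificity `A_C` is the summed group-mean occurrence inside
the combination over the sum across all groups (group-size independent —
unweighted group means), fidelity `B_C` the fraction of the combination's
sites occupied, `IndVal = sqrt(A·B)`. The permutation p compares the
observed best combination's value with the permuted maximum. Reference
implementations offer several weighting variants; the unweighted choice is
deliberate and flagged, since the original indicator-value formulation is
group-size independent.

**Univariate tests** delegate to base R where the procedure is standard:
Kruskal–Wallis with tie correction, paired Wilcoxon (exact for ≤25 untied
differences, normal approximation with tie correction otherwise), Holm via
`p.adjust`. Spearman's rho uses midranks; its p-value is exact by full
enumeration for n ≤ 8 without ties and the t approximation otherwise —
the t path is what published analyses use when ties are present, and both
paths are validated against enumeration in the tests.

## The synthetic-data generator

`simulate_experiment()` emulates the study's structure with known ground
truth: five rookeries (default sizes 36/23/22/20/23 scats, the retained
study sizes), two assay replicates per scat with predator read fractions
0.55 (blocking) and 0.90 (no blocking), per-replicate depths uniform on
500–5000 reads (study mean ≈ 1969 per pooled sample), per-scat prey
richness zero-truncated Poisson with mean 2.7 (reported mean 2.69–3.40,
median 2), rookery prey pools of 40 OTUs from a global pool of 98 with
Dirichlet(0.4) frequency vectors (sparse enough to give a few dominant
prey per rookery), four non-marine contaminant OTUs at 2% of reads,
tag-switch rate 5e-4 (the scale implied by the published floor of
0.000514), and negative controls of 2000–20000 reads whose predator
fraction (default 0.000514) is exactly what the floor estimator should
recover. Planted low-identity, no-hit and non-checklist OTUs exercise
every screening branch. All randomness flows from one seed through
independent per-component streams, so adding controls does not perturb the
sample draws.

One generator choice needs emphasis: within a scat, prey reads are
allocated by largest-remainder rounding of Dirichlet-mixture shares
floored at 30% of uniform, so every truly-present item receives more than
1% of the scat's prey reads. Without this floor the cascade's own 1% rule
would stochastically erase true occurrences and no exact recovery oracle
could exist. Consequently the generator does not emulate genuinely trace
prey (secondary ingestion, degraded DNA), PCR bias beyond the two assay
fractions, sequence errors, or chimeras — so passing recovery tests show
the cascade's logic is faithful, not that real trace prey survive it.

`simulate_group_shift()` provides the calibration harness for the
permutation tests: binary matrices whose item-occurrence probabilities are
identical across groups at effect size 0 (exchangeable, for type-I
calibration) and mixed with a permuted copy in one group otherwise.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes
chosen to make every oracle exhaustive or near-exhaustive: brute-force
permutation enumeration on 6–7 samples, subset enumeration for rarefaction
on 6 samples, 500 null simulations at 199 permutations for type-I
calibration (the achievable size at α = .05 with the (1+b)/(1+m)
convention is exactly 10/200), and a single study-scale synthetic run
(124 scats) for the structural analogues. Permutation defaults in the
package itself are 9999 as in the published analyses. Comparisons against
permuted statistics subtract `sqrt(.Machine$double.eps)` before `>=` so
exact ties count as exceedances on both sides of the comparison.

## Limitations

* The published per-sample occurrence matrix (supplementary data) is not
  redistributable with the package, so the printed multivariate values
  (overlap 0.227, rookery pseudo-F 3.150, dispersion F 4.481, IndVal
  0.743, stress 0.048, per-rookery richness) are documented claims; the
  package checks their *structure* on study-shaped synthetic data and its
  algorithms against exhaustive oracles and vegan instead.
* Identity-band ranking can disagree with manual phylogenetic placement
  for hits below 96% identity.
* Checklist matching is exact on binomials; taxonomic synonyms must be
  resolved upstream.
* Read-count-based quantities (read shares, read rarefaction) inherit all
  amplification biases of metabarcoding; the package's diet inference
  deliberately stays occurrence-based.
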