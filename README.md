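# scatdiet

Diet analysis from DNA-metabarcoding of predator scat samples, built
around the Galapagos sea lion (*Zalophus wollebaeki*) study system:
16S prey barcodes amplified from scats collected at several rookeries,
clustered upstream into 97% OTUs, with a BLAST-style best hit per OTU.

Scat metabarcoding tables are dominated by predator reads and carry
contamination from tag switching (index hopping), non-marine taxa and
cross-contamination. scatdiet implements the full analysis downstream of
the OTU table:

* **Decontamination cascade** — a tag-switch relative-abundance floor
  derived from negative controls (the maximum predator-read fraction in
  the extraction blanks), removal of no-hit / low-identity (<70%) /
  predator / blacklisted OTUs, negative-control-based cell filters, a
  per-sample 1% minor-OTU rule with singleton removal, and exclusion of
  low-coverage samples (fewer than 2 prey reads, then the lowest quartile
  of per-sample totals).
* **Taxonomy** — species assignment at ≥96% identity with regional
  checklist confirmation, identity bands (92/85) for genus/family/order,
  OTU-to-entity collapsing, habitat and trophic-bin categorisation.
* **Diet summaries** — frequency and percent of occurrence (POO) per
  rookery (items, habitats, trophic bins), prey richness, sample-based
  (incidence) and read-based (hypergeometric) rarefaction with exact
  variances.
* **Community statistics, from first principles** — Jaccard distances;
  PERMANOVA with sequential sums of squares
  (`F = (SS_term/df_term)/(SS_res/df_res)` on the Gower-centred matrix);
  pairwise PERMANOVA with Holm correction; PERMDISP (distances to group
  centroids in a principal-coordinate embedding keeping negative
  eigenvalue axes, `z = sqrt(d₊² − d₋²)`); NMDS minimising Kruskal
  stress-1 with isotonic regression and Guttman updates; Schoener overlap
  `D = 1 − 0.5·Σ|p_x − p_y|`; indicator species analysis
  `IndVal = sqrt(A·B)` over site-group combinations; Spearman,
  Kruskal–Wallis and paired Wilcoxon rank tests. All permutation tests are
  seeded and use `p = (1 + b)/(1 + m)`.
* **Synthetic-data generator** — study-shaped experiments with known
  ground truth (two assay replicates per scat, blocking vs no-blocking
  predator fractions, rookery-structured Dirichlet diets, tag-switch
  leakage, contaminants, negative controls), used by the test suite to
  verify that the cascade recovers the truth exactly on noise-free data.

## Worked example

```r
library(scatdiet)

sim <- simulate_experiment(sim_config(seed = 11))   # 124 scats, 5 rookeries
res <- run_filter_cascade(sim$table, sim$hits,
  filter_config(blacklist = c("Homo sapiens", "Gallus gallus",
                              "Bos taurus", "Canis lupus")))
print(res$report)
```

```
filter_report
  derived tag-switch floor: 0.000752021
  derived quartile cutoff: 989.25 reads
  pool_assays            -  0 OTUs  -124 samples  -       0 reads
  tag_switch_floor       -  0 OTUs  -  0 samples  -     118 reads
  screen_otus            -  6 OTUs  -  0 samples  -  500772 reads
  control_based_filters  -  4 OTUs  -  0 samples  -   52758 reads
  minor_otu_filter       -  0 OTUs  -  0 samples  -       0 reads
  exclude_samples        -  0 OTUs  - 34 samples  -   21724 reads
  drop_empty_otus        - 39 OTUs  -  0 samples  -       0 reads
```

The report reads top to bottom: the 248 assay replicates pool to 124
scats; the floor estimated from the negative controls (here 7.5e-4)
nullifies 118 tag-switched reads; OTU screening drops the predator and
low-identity OTUs (most of the reads in the table are predator DNA); the
control-based filters absorb the contaminant columns; and sample exclusion
drops the controls plus the lowest quartile of prey-read totals (cutoff
989.25 — samples at or above it stay).

```r
inf <- subset_inferential(res$table)          # >= 100 prey reads
occ <- to_occurrence(inf)
d   <- jaccard_distances(occ)
permanova(d, data.frame(rookery = factor(occ$rookery),
                        reads = as.numeric(rowSums(inf$counts))),
          n_perm = 999, seed = 11)
```

```
PERMANOVA (999 permutations)
     term df      SS     R2      F     p
  rookery  4  7.1867 0.1661 4.4219 0.001
    reads  1  0.7256 0.0168 1.7857 0.005
 Residual 87 35.3495 0.8171     NA    NA
    Total 92 43.2618 1.0000     NA    NA
```

Rookery explains 16.6% of the diet variation among the 93 inferential
samples (sequential sums of squares, rookery fitted before the read-count
covariate); the permutation p of 0.001 is the smallest value 999
permutations can produce.

Published summary statistics can be recomputed directly from their printed
count inputs, e.g. the rarefied-richness vs population-size correlation:

```r
rank_correlation(c(30, 23, 22, 41, 36), c(872, 499, 289, 731, 434))
#> rho = 0.50, p = 0.450 (exact enumeration)
```

`run_pipeline(run_config(...))` chains all stages (simulate/load →
filter → assign → summarize → compare) and writes every stage output plus
a provenance record sufficient to re-execute the identical run.

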