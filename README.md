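# reliotu

Replicate reliability and low-abundance OTU filtering for 16S rRNA
amplicon count tables.

## The problem

PCR amplification and sequencing error seed 16S surveys with spurious
operational taxonomic units (OTUs): low-copy taxa that appear in one
subsample of a specimen but not in another. When the same stool specimen
is sequenced in triplicate, typically well under half of the detected
OTUs are found in all three replicates, which inflates richness
estimates and undermines reproducibility. The standard remedy is to
filter low-abundance OTUs, but filtering rules differ in scope (whole
dataset, individual sample, or replicate group) and threshold, and their
consequences for diversity metrics differ too.

`reliotu` is for microbiome analysts who want to quantify that
trade-off. It provides:

* **Six filtering methods** plus an unfiltered baseline, with exact
  threshold semantics:
  * dataset scope — remove an OTU from *all* samples if its pooled share
    is < 0.1% of all reads, or if no single sample has > 10 copies;
  * sample scope — zero an OTU only in the samples where it has 1 copy
    (singletons), or < 10 copies;
  * triplicate scope — within each specimen, zero an OTU in all three
    replicates unless some replicate has ≥ 10 copies, or unless it is
    present in all three (the intersection filter).
* **Reliability**: for each specimen, the percentage of union-detected
  OTUs found in 3, 2, or 1 of its replicates, aggregated as mean (SE)
  across specimens.
* **Quantification precision**: per-OTU coefficient of variation
  CV = sd/mean over the triplicate copy counts, summarized by
  copy-count bins (>1000, 100–1000, 10–100, 1–10, sporadic).
* **Diversity**: observed OTUs, bias-corrected Chao1
  `S_obs + f1(f1−1) / (2(f2+1))`, Shannon `−Σ p ln p`, inverse Simpson
  `1/Σ p²`; Bray–Curtis dissimilarity
  `d(j,k) = Σ|x_ij − x_ik| / Σ(x_ij + x_ik)`, principal-coordinates
  ordination, and a seeded one-way PERMANOVA
  (`R² = SS_between / SS_total`, permutation p with the +1 correction).
* **A synthetic triplicate community generator** with known ground
  truth (lognormal core community, per-specimen Dirichlet perturbation,
  multinomial replicate sampling, replicate-specific spurious low-copy
  OTUs), so the whole pipeline is testable without sequencing data.
* I/O for mothur `.shared` files, generic TSV count matrices,
  replicate-design and greengenes-style taxonomy tables.

## Worked example

```r
library(reliotu)

ds <- simulate_community(sim_config(seed = 1))
ds
#> Synthetic triplicate dataset: 12 specimens x 3 replicates, 1722 detected OTUs

replicate_agreement(ds$table, ds$design)
#> Reliability over 12 specimens: 48.1% (SE 0.6) in 3, 5.2% in 2, 46.7% in 1 replicate(s)

cv_by_abundance_bin(ds$table, ds$design)
#>        bin   mean_cv n_units
#> 1    >1000 0.2441517      63
#> 2 100-1000 0.2475734     620
#> 3   10-100 0.2879841     726
#> 4     1-10 0.4365964     438
#> 5 sporadic 1.6545817    1998

fr <- filter_sample_min_copies(ds$table, min_copies = 10)
replicate_agreement(fr$table, ds$design)
#> Reliability over 12 specimens: 88.2% (SE 1.1) in 3, 6.1% in 2, 5.8% in 1 replicate(s)
percent_reads_removed(fr, ds$table)$mean
#> [1] 0.6693006

run_grid(ds$table, ds$design, ds$taxonomy, seed = 1)
#> Filtering-method grid: 7 methods (seed 1)
#>   none                     reliability 48.1%, reads removed 0.00%, R2 0.871
#>   dataset_relative         reliability 91.6%, reads removed 6.96%, R2 0.849
#>   dataset_max_copies       reliability 86.2%, reads removed 0.26%, R2 0.872
#>   sample_singleton         reliability 66.6%, reads removed 0.12%, R2 0.871
#>   sample_min_copies        reliability 88.2%, reads removed 0.67%, R2 0.872
#>   triplicate_max_copies    reliability 100.0%, reads removed 0.53%, R2 0.873
#>   triplicate_intersection  reliability 100.0%, reads removed 0.25%, R2 0.872
```

Reading the output: without filtering, only 48% of detected OTUs are
reliably seen in all three replicates of a specimen, and sporadic
low-copy OTUs are quantified with a CV near 1.7, versus ~0.25 for
abundant ones. Removing OTUs with < 10 copies per sample raises
reliability to 88% at the cost of 0.67% of reads; the triplicate
intersection filter is 100% reliable by construction. PERMANOVA R²
(~0.87 here) shows that the individual providing the specimen dominates
beta diversity regardless of the filtering method.

`write_grid_report(grid, dir)` writes the per-method reliability,
alpha-diversity, taxon-composition and ordination tables as TSV plus a
single JSON report.

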