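# phagepipe

Discovery and profiling of double-stranded DNA phages from bulk
(whole-community) metagenome assemblies, for researchers studying the
gut virome and its interplay with the bacteriome.

Bulk metagenomes are dominated by bacterial and plasmid sequence, so
the package's discovery stage is built for specificity: an assembled
contig is called a phage only if it passes **six criteria** — (1) size
≥ 10 kb, (2) viral k-mer p ≤ 0.05, (3) ≥ 1 viral hallmark gene (VHG)
and no plasmid hallmark gene, (4) no bacterial single-copy marker or
rRNA gene, (5) not more plasmid-database than viral-database gene
hits, and (6) provirus fraction ≥ 0.8. Complete genomes are recognised
by terminal redundancy (> 130 bp suffix–prefix overlap at > 97%
identity); remaining linear drafts are recovered against complete
genomes (> 40% of genes aligned, size 70–120%) and quality-tiered.

Around the classifier the package builds the full analysis chain:

* **Catalogue** — greedy ANI clustering into species-level vOTUs
  (≥ 95% identity, ≥ 85% coverage), protein clustering with a
  from-scratch Markov Cluster algorithm (inflation 2), family-level
  viral clusters (VCs) linking vOTU pairs sharing > 20% of protein
  clusters, taxonomy voting (> 20% plurality) and
  temperate/virulent lifestyle calls.
* **Host prediction** — CRISPR array detection, spacer filtering
  (25–100 bp), protospacer matching at edit distance ≤ 1 with > 95%
  of the spacer aligned (both strands), genus-level host sets with
  specialist/generalist labels and a fixed exclusion list of
  non-intestinal genera.
* **Quantification** — reads mapped to vOTU representatives' VHGs only
  (≥ 95% identity, ties discarded to avoid over-counting), RPKM per
  vOTU, VC aggregation, relative abundance, detection/richness.
* **Ecology & association** — Shannon and Bray–Curtis diversity,
  phage–host Spearman correlations with the abundance inclusion rules
  (vOTU > 0.01%, genus > 0.5%) and co-absence exclusion,
  defence-system tertile analysis, log10 + univariate OLS scan with
  global Benjamini–Hochberg FDR, stepwise-AIC multivariable
  regression, and PERMANOVA (McArdle–Anderson pseudo-F, permutation
  p-values).
* **Synthetic benchmark** — `generate_community()` /
  `generate_cohort()` plant circular phages, plasmids, prophages,
  CRISPR arrays, phage–host abundance coupling and metadata effects,
  so every stage is scored against known truth.

## Worked example

```r
library(phagepipe)

com  <- generate_community(rng_seed = 42)     # 80 contigs, truth known
disc <- discover_phages(com)                  # six-criterion screen
evaluate_pipeline(disc$calls, com$truth$labels)
#> $tpr
#> [1] 0.9333333
#> $fpr
#> [1] 0

table(disc$calls$tier)
#> complete     high   medium
#>       10        9        9

cat <- build_catalogue(disc, com)
length(unique(cat$votus$votu_id))             # species-level clusters
#> [1] 10
head(cat$taxonomy, 3)
#>    votu_id representative       family lifestyle
#> 1 vOTU_001     phage_sp01   crAss-like  virulent
#> 2 vOTU_002     phage_sp08 Siphoviridae  virulent
#> 3 vOTU_003     phage_sp06   Myoviridae temperate
```

At the default 2% annotation noise the classifier recovers 93% of the
planted phages with no false positives; with noise-free annotation it
separates phages from plasmids and bacterial contigs exactly
(sensitivity 1.0, FPR 0.0). Host prediction then recovers the planted
host genus for every CRISPR-targeted phage, and RPKM profiles
reproduce planted abundance ranks at Spearman ≈ 0.98.

`run_pipeline(seed, outdir)` executes the whole sequence-level chain
and writes `calls.tsv`, `votus.tsv`, `vcs.tsv`, `hosts.tsv`,
`abundance.tsv` and `manifest.json`, byte-identical across reruns with
the same seed.

## Documentation

The methods vignette (`vignettes/phagepipe-methods.Rmd`) describes the
discovery model and its assumptions, every tunable threshold with its
default, the synthetic-community noise and cohort models, the
statistical procedures, and the design decisions taken where the
underlying prescriptions were open.
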