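# hybridscope

Multi-omics dissection of parent-of-origin effects in F1 hybrids.

When a hybrid is profiled against both parental reference genomes, three
questions recur: which genes are expressed from one parent's alleles more
than the other's (homoeolog expression bias, and in aggregate *subgenome
dominance*); where does DNA methylation differ between the hybrid and a
purebred comparator; and how do those methylation differences line up with
differential expression. `hybridscope` implements that pipeline for
analysts working with hybrid crosses (the motivating system is a hybrid
grouper and its maternal purebred, but nothing is fish-specific):

* **Diagnostic SNPs** — hard-filters a two-parent VCF
  (`QD < 2 || FS > 60 || MQ < 40`, `GQ < 20`) and keeps biallelic sites
  where the parents are homozygous for different alleles (0/0 × 1/1), so
  every hybrid RNA-seq read covering the site is parent-assignable. SNPs
  are assigned to genes by exonic overlap.
* **Ortholog pairing** — reciprocal best hits between the two parental
  gene sets from all-vs-all similarity tables (e-value ≤ 1e-5; best =
  highest bitscore, deterministic tie-breaks).
* **Allelic bias** — per gene and replicate, paternal counts are tested
  against the replicate total with a two-sided exact binomial test at
  p = 0.5 and BH-adjusted across genes. A gene is paternal-biased when
  every replicate has paternal:maternal ratio ≥ 2 with q ≤ 0.01
  (maternal: ratio ≤ 0.5), and `dominance_summary()` co-locates bias DEGs
  across the two references through the ortholog map.
* **Methylome** — methylcytosine calling against the bisulfite conversion
  error, pooled CG/CHG/CHH levels by genome, chromosome or strand-aware
  gene region, and DMR calling on 200-bp tiling windows: sites covered
  ≥ 4× in both groups, per-context minimums of 5 sites / |Δ| ≥ 0.25
  (CG, CHG), 15 / 0.15 (CHH) and 20 / 0.2 (pooled C), two-sided Fisher
  exact test on the pooled window counts, BH per context, q ≤ 0.05.
* **Expression** — FPKM (`count × 1e9 / (length × library_size)`), DESeq2
  DEG calling at adjusted p < 0.05 and |log2FC| ≥ 1, cross-tissue
  shared-gene partitions and cross-reference Venn accounting.
* **Integration** — expression bins (RPKM ≤ 1 / ≤ 10 / ≤ 100 / > 100),
  gene-wise Spearman correlation of expression with region methylation,
  and E±/M± quadrant labels for genes that are both DE and differentially
  methylated.

A seeded synthetic hybrid-cross generator (`simulate_cross()`) produces
every input with known ground truth — planted biased genes, DMR windows
and DEGs — so each stage's sensitivity and false-positive rate are
measurable, and `simulate_null_methylome()` provides exchangeable null
draws for type-I checks.

## Worked example

```r
library(hybridscope)

sim  <- simulate_cross(cross_sim_config(n_genes = 60, seed = 11))
gm   <- read_gene_models(sim$paths$gff)

diag <- read_parent_vcf(sim$paths$vcf) |>
  hard_filter() |>
  select_diagnostic(reference_side = "paternal") |>
  assign_to_genes(gm)

bias <- count_alleles(sim$tables$allele_depths, diagnostics = diag) |>
  test_bias()
glance(bias)
#> # A tibble: 1 × 6
#>   n_genes n_paternal n_maternal n_unbiased n_low_coverage mode
#>     <int>      <int>      <int>      <int>          <int> <chr>
#> 1      60          8          6         46              0 per_replicate

dmrs <- call_dmrs(sim$tables$meth$hybrid, sim$tables$meth$maternal)
glance(dmrs)
#> # A tibble: 4 × 5
#>   context n_windows n_tested n_hyper n_hypo
#>   <chr>       <int>    <int>   <int>  <int>
#> 1 CG           1875     1827       0      6
#> 2 CHG          1880     1814       5      0
#> 3 CHH          1885     1826       6      0
#> 4 allC         1885     1842       6      0
```

This simulation planted allelic bias in 60 × (0.15 + 0.10) = 15 genes and
a differential 200-bp window in 6 genes; the bias test recovers 14 of the
15 (8 paternal + 6 maternal; one planted gene falls just short of the
triple-replicate gate) with no false calls, and the DMR caller recovers
17 of the 18 planted context-windows (6 genes × 3 contexts; one CHG
window falls short) — the CG baseline of 0.8 shifts down while the
CHG/CHH baselines shift up, hence the hypo/hyper split. Per-gene
detail is in the returned tibbles (`tidy(bias)` for per-replicate
statistics), and `autoplot()` draws the standard diagnostic panels.
`run_pipeline(pipeline_config())` chains every stage and attaches a
report with configuration echo and ground-truth recovery rates.

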