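---
title: "Models and design choices in hybridscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in hybridscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hybridscope` analyses an F1 hybrid profiled against both parental
reference genomes: allele-specific expression through parent-diagnostic
SNPs, context-resolved differential DNA methylation, differential
expression, and their integration. This vignette documents the
statistical models, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open.

## Diagnostic SNPs

A site is parent-diagnostic when both parents are homozygous for
different alleles; every hybrid read covering it is then assignable to
one parent. Before selection, parental variant calls pass a GATK-style
hard filter: a record is removed when `QD < 2.0 || FS > 60.0 ||
MQ < 40.0` or when either parent's `GQ < 20`. Two conventions matter and
are implemented explicitly:

* The inequalities are strict, exactly as written. A record sitting on a
  boundary (QD 2.0, FS 60.0, MQ 40.0, GQ 20) passes.
* Records with a missing annotation fail conservatively and are tallied,
  as are multi-allelic sites and indels (the homozygous-divergent
  configuration presumes a biallelic SNP) and malformed genotypes.
  Phased-looking separators (`0|0`) are treated as homozygosity
  notation, not phasing — parental resequencing of single individuals
  carries no phase information.

SNPs are assigned to genes by *exonic* overlap, since RNA-seq reads cover
exons; a SNP inside the exons of two overlapping genes is kept for both
and flagged ambiguous rather than dropped. Coordinates are 1-based
inclusive at the VCF/GFF3 boundary and 0-based half-open inside interval
arithmetic, with the conversion confined to the readers and the window
code.

## Homoeolog expression bias

Per gene and replicate, paternal and maternal informative read counts are
summed over the gene's diagnostic SNPs. The published decision rule fixes
the gates — ratio ≥ 2 (or ≤ 0.5) and q ≤ 0.01 in three biological
replicates — but not the test behind q. We use a two-sided exact binomial
test of the paternal count against the replicate total at success
probability 0.5, BH-adjusted across genes within each replicate: the
standard choice for allele-count data, exact at the low counts where a
normal approximation is least trustworthy.

Open choices, resolved as follows and configurable:

* *"In three biological replicates"* is read in its strictest sense —
  every replicate must satisfy both the ratio and the q gate
  (`mode = "per_replicate"`). A pooled mode (sum counts, one test) is
  provided because the alternative reading cannot be excluded.
* A zero maternal count yields an infinite ratio, which legitimately
  satisfies the paternal gate; no pseudocounts are added, because they
  silently shift every ratio at low coverage.
* Genes with any replicate total below `min_total = 10` informative
  reads are never classified and carry a low-coverage flag. The source
  decision rule states no coverage floor; without one, a 2:0 gene could
  be called biased on two reads.

`dominance_summary()` co-locates bias DEGs across the two reference
alignments by ortholog identity (positional co-location is not
implemented; ortholog-id matching is the only joinable key once the two
annotations differ), partitions the shared set by direction consistency,
and compares the mean FPKM of the paternal- and maternal-biased sets.

## Methylome

Methylcytosine calling tests each covered site one-sided against the
bisulfite non-conversion rate (default 0.01): p = P(X ≥ count_m) with
X ~ Binomial(coverage, error), BH across sites, methylated at q ≤ 0.05.
Methylation levels are always coverage-weighted pooled proportions,
Σm / Σ(m+u) — never means of per-site ratios — so a window's level equals
the level its differential test sees.

DMRs are called on fixed non-overlapping 200-bp windows anchored at
coordinate 0. Whether the original windows were tiling or sliding is not
stated; tiling is the simplest reproducible choice and the window width
is configurable. Per window, context and group, counts are pooled over
sites covered at least 4× in *both* groups ("minimum read coverage of 4"
is interpreted per site and per group — the only reading consistent with
site-level counts), and the pooled 2×2 table is tested with a two-sided
Fisher exact test. This test is a deliberate choice: with one library per
group there is no replicate variance to model, and Fisher's exact test is
the canonical two-group comparison of pooled counts. BH runs per context
across all tested windows genome-wide. A call additionally requires the
context's printed minimums: ≥ 5 sites and |Δ| ≥ 0.25 for CG and CHG,
≥ 15 and 0.15 for CHH, ≥ 20 and 0.2 for the pooled all-C track.
"Numbers in each window" is read as the number of eligible cytosines of
the tested context, which is what makes the context-specific minimums
commensurable. Symmetric CG sites on opposite strands are kept separate
(separation is lossless; merging is a lossy convenience the caller does
not need).

Site-level DMC calling reuses the same machinery; its screening
thresholds are nowhere stated, so the defaults are an explicit
assumption: coverage ≥ 4 in both groups, |Δ| ≥ 0.25, q ≤ 0.05, per
context.

## Expression

FPKM is the identity `count × 1e9 / (gene_length × library_size)`, held
to relative precision 1e-12 in the tests. DEGs are called with DESeq2 —
the tool the decision thresholds were defined for — at adjusted p < 0.05
and |log2FC| ≥ 1, with the fold-change sign fixed as hybrid over
maternal. On panels too small or homogeneous for the parametric
dispersion trend, the fit falls back to gene-wise dispersion estimates;
with single replicates, where no dispersion is estimable, a
library-size-conditioned exact binomial test substitutes. Externally
computed tables enter through `deg_calls_from_table()`, which applies
only the classification rule, so the internal test is swappable.

## Integration

Expression bins follow the printed half-open intervals: non (RPKM ≤ 1),
low (1, 10], middle (10, 100], high (> 100). The
methylation–expression correlation is computed gene-wise (Spearman, per
region and context, between each gene's expression and its region
methylation level), with per-bin mean profiles reported descriptively —
the strictest testable reading of a named-but-unspecified pairing. The
E±/M± quadrant of a DEG∩DMG gene combines its expression direction with
its methylation direction. A gene with hyper- and hypomethylated regions
in the same region class yields one record per DMR, flagged multi-hit,
and the region-level direction is the site-count-weighted mean delta
sign — real genes do carry both signs at once, and collapsing them
silently would hide exactly the cases worth inspecting.

## The synthetic cross

`simulate_cross()` generates the full input set under one master seed
(per-file substreams are derived from stable labels, so adding an output
never perturbs another). Defaults define the reference study condition
used by the package's own validation:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 200 | large enough for stable rate estimates, small enough for desk-scale runs |
| `n_replicates` | 3 | the standard triplicate design |
| `rna_depth_per_gene` | 60 | a realistic allele-informative depth for a moderately expressed gene |
| `bias_fold` | 4 | a planted biased gene splits reads 4:1, i.e. paternal fraction 0.8 |
| `frac_paternal_biased` / `frac_maternal_biased` | 0.15 / 0.10 | paternal excess mirrors paternal dominance |
| `meth_baseline` | CG 0.8, CHG 0.3, CHH 0.1 | a CG-dominant vertebrate-like methylome with ~75–80% CG methylation |
| `meth_coverage` | 20 | typical per-cytosine bisulfite depth |
| `frac_dmr_genes` / `dmr_delta` | 0.10 / 0.5 | the planted shift is 2× the CG/CHG gate and > 2× the CHH and all-C gates |
| `frac_deg` / `deg_log2fc` | 0.10 / 2 | clearly-separated planted DEGs |
| `nb_dispersion` | 0.05 | bulk RNA-seq-like biological variability |

Structure: 50 non-overlapping genes per pseudo-chromosome with
alternating strands and ≥ 5 kb spacing (so 2 kb flanks never collide);
two exons per gene with SNP counts Poisson(5) placed uniformly in exons;
allele-informative reads multinomially split across a gene's SNPs and
binomially between alleles; cytosine scaffolds at ~11 CG, ~11 CHG and
~28 CHH sites per 200-bp window with counts drawn binomially from the
per-context level; planted DMR windows are single 200-bp tiles centred in
the gene body, shifted per context toward the feasible side of [0, 1] so
the full delta is realised (CG down, CHG/CHH up under the defaults); the
count matrix is negative-binomial with log-normal baseline means. The
VCF deliberately mixes in decoy records — heterozygous, low-QD, high-FS,
low-MQ, low-GQ, same-homozygote and multi-allelic — so the filter chain
has something to reject.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level artefacts (mapping bias toward the
reference allele, bisulfite non-conversion, M-bias), sequence-realistic
genomes, overlapping or multi-isoform gene models, replicate-level
biological variance in methylation (counts are binomial around a fixed
level, so the Fisher test's no-replication assumption is exactly met),
and linkage between planted effects (bias, DMR and DEG labels are drawn
independently). Recovery rates on this generator are therefore upper
bounds on field performance, and the type-I rates reflect sampling noise
only.

`simulate_null_methylome()` draws both groups' counts from identical
per-site levels over a tiled scaffold; with ≥ 2000 windows the DMR
false-call rate is measured on ~8000 context-windows. Empirically it sits
near zero rather than at the nominal q-level because the delta gates
reject the small random differences that survive the test.

## Problem sizes and runtime choices

The validation suite measures type-I error on 2000 null windows, bias
recovery and false-call rates on the 200-gene reference condition, and
DMR recovery on its 60 planted context-windows; these sizes give binomial
standard errors comfortably inside the asserted margins. The pipeline's
default stage list omits the site-level DMC scan (a Fisher test at every
one of the several hundred thousand simulated cytosines; the windowed
scan already captures the differential signal at a fraction of the
work) — `call_dmcs()` is fully implemented and tested, and adding
`"dmc"` to `stages` enables it. Repeated 2×2 tables are deduplicated
before testing. Stage outputs are plain tibbles produced by pure
functions, so re-running a stage with changed thresholds is cheap and
needs no cache layer; the report echoes the configuration so any
override is visible in the output.

For FPKM on simulated data, the pipeline treats the simulated panel as a
random sample from a 20,000-gene transcriptome and extrapolates library
sizes accordingly (`fpkm_transcriptome_genes`); without this, a 200-gene
"library" would inflate every FPKM by two orders of magnitude and the
absolute expression-bin boundaries would be meaningless.

## Known limitations

Bias testing assumes mapping is unbiased between parental alleles; on
real hybrids a reference-alignment bias inflates apparent dominance
toward the reference parent, which is why analyses against both parental
references, joined through the ortholog map, are first-class here. The
DMR caller models no replicate variance (none is available in the
two-group pooled design) and its q-values are anti-conservative when
biological replicates exist — a beta-binomial extension is out of scope.
RBH orthology is one-to-one by construction and will drop recent
paralogs. The exact binomial bias test conditions on total informative
depth and ignores SNP-level overdispersion within a gene.
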