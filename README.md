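# ribodelta

Genome-wide detection of **differential mRNA translation** from paired
ribosome-profiling (RPF) and mRNA-seq count data.

Ribosome profiling measures two things per sample: transcript abundance
(mRNA-seq) and ribosome occupancy on coding sequences (ribosome-protected
fragments, RPFs). A gene is translationally regulated between two conditions
when its RPF abundance changes *discordantly* with its mRNA. `ribodelta`
quantifies this per gene as the translational log2 fold change

    Δβ_g = log2FC(RPF) − log2FC(mRNA) = log2R(C2) − log2R(C1)

where log2R is the within-condition log2 RPF-to-mRNA ratio. It is written for
analysts of bulk ribosome profiling experiments with two conditions and few
(1–3) replicates.

## Method in brief

Counts are modelled as negative binomial, `K_gi ~ NB(μ_gi, α_g)` with
`μ_gi = s_i · φ_g · 2^(X_i · β_g)`: median-of-ratios size factors `s_i`,
base level `φ_g`, condition indicator `X`, log2 effect `β_g`, and gene-wise
dispersions `α_g` estimated by Cox–Reid likelihood, a parametric
mean–dispersion trend `a0 + a1/μ`, and empirical-Bayes MAP shrinkage toward
the trend. For each gene the package builds a discrete posterior
`Pr(β_g) ∝ Π_i f_NB(K_gi)` on an adaptive 10,000-point grid spanning the
range where the posterior falls to 1e−50 of its peak, profiling `φ_g` at
every grid point.

Two parallel pipelines compare posteriors on a shared grid — log2FC(RPF) vs
log2FC(mRNA), and log2R(C2) vs log2R(C1). From each joint probability matrix
(never materialized; the rank-1 structure reduces everything to marginal
cumulative sums and one FFT) come a two-sided p-value (twice the smaller
triangle sum), the Δβ distribution (anti-diagonal sums), its mode, and an
equal-tailed credible interval (default 95%). The **more conservative**
pipeline (larger p) is reported per gene, followed by Benjamini–Hochberg
adjustment.

The package also ships the simulation benchmark used to validate it
(NB counts with a mean–dispersion trend and spiked fold changes
`1.5 + Gamma(0.6, 0.5)` with known truth labels), ROC/precision-recall
evaluation, a sample-shuffling permutation control, and an RPF read counter
for SAM/GTF input that applies the standard footprint filters (26–34 nt,
uniquely mapped, 5′ end inside the CDS excluding the first 15 and last 5
codons).

## Worked example

```r
library(ribodelta)

# a simulated two-condition benchmark with known truth (15% spiked genes)
cfg <- sim_config(n_genes = 1000, n_replicates = 2,
                  spike_fraction = 0.15, seed = 42)
sim <- simulate_dataset(cfg)

res <- delta_te(sim$mrna, sim$rpf, sim$design)
res
#> differential translation analysis
#>   genes: 1000 (980 tested)
#>   conditions: control vs treated
#>   genes at padj < 0.1: 28

df <- as.data.frame(res)
df[order(df$pvalue_final)[1:3],
   c("gene_id", "delta_log2", "ci_low", "ci_high", "pvalue_final", "padj")]
#>       gene_id delta_log2 ci_low ci_high pvalue_final     padj
#> 494 gene00494       2.49   2.00    2.98     1.23e-22 1.20e-19
#> 771 gene00771       1.61   1.16    2.06     2.80e-12 1.37e-09
#> 839 gene00839       1.74   1.24    2.25     2.27e-11 7.41e-09

roc_auc(ranking_score(res), grepl("^TP", sim$truth$category))$auc
#> [1] 0.742
```

`delta_log2` is the translational log2 fold change (positive = translation up
in the second condition), `[ci_low, ci_high]` its 95% equal-tailed credible
interval, `pvalue_final` the more conservative of the two pipelines' p-values,
and `padj` its BH adjustment. The three genes above are simulated true
positives: two mRNA-only fold changes of 3.8 and 2.8 (down) and one RPF-only
fold change of 3.1 (up), all recovered with the correct sign and magnitude.

Real data enter through TSV tables:

```r
mrna <- read_counts("mrna_counts.tsv", "mRNA")
rpf  <- read_counts("rpf_counts.tsv", "RPF")
design <- sample_design(c("ctrl", "ctrl", "drug", "drug"),
                        samples = colnames(mrna))
res <- delta_te(mrna, rpf, design)   # normalized = TRUE to skip size factors
write_results(res, "differential_translation.tsv")
```

A thin command-line wrapper with `run`, `simulate`, `evaluate`, `permute`,
and `count-rpf` subcommands is installed at
`system.file("scripts/ribodelta-cli.R", package = "ribodelta")`.

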