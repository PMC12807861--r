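# ribospike

Absolute differential translation-efficiency analysis for ribosome
profiling with an orthogonal spike-in, plus the surrounding analyses of a
stress-granule study: granule-enrichment testing, tethering-reporter
quantification, polysome ribosome loads, and a ground-truth synthetic-data
generator.

## Why

Sequencing libraries are compositional. When the integrated stress response
shuts down translation of essentially every mRNA, per-library depth
normalization rescales the collapsed ribosome-profiling libraries back up
and the global shutdown vanishes from the analysis — every gene looks
"unchanged". Conventional RNA spike-ins cannot fix this because the
nuclease step of ribosome profiling destroys unprotected RNA. A
*ribo-spike* — a defined amount of an orthogonal in-vitro translation
reaction (reticulocyte polysomes on a foreign mRNA) added to each lysate —
survives footprinting and anchors normalization on something with constant
true abundance.

With spike-anchored size factors
`f_j = spike_sum_j / geomean(spike_sums)`, the per-gene absolute TE change

```
log2FC_TE(g) = log2( RPF_B / RPF_A ) − log2( RNA_B / RNA_A )
```

(normalized condition means) retains global shifts, with a delta-method
negative-binomial standard error, Wald tests against both the spike zero
line and the bulk median, Benjamini–Hochberg adjustment, and the
stress-response categories *enhanced* / *resistant* / *hypersensitive* /
*bulk* at the |log2 FC| > 1, adjusted p < 0.05 thresholds. The global
shutdown is summarized as the fold reduction `2^(−median log2FC_TE)`.

The package is aimed at analysts of spike-anchored ribosome profiling (or
anyone who wants to see, on controlled synthetic data, exactly what
library-anchored normalization erases and spike anchoring preserves).

## Worked example

Simulate the arsenite experiment the generator emulates — a planted 20-fold
global TE shutdown over 10,000 genes, 3 replicates per condition, with
spike rows of constant true abundance — then recover everything from the
counts alone:

```r
library(ribospike)

sim <- simulate_isr_counts(isr_preset("arsenite", seed = 1))

sf   <- list(rpf = spike_size_factors(sim$rpf_counts, "spike"),
             rna = spike_size_factors(sim$rna_counts, "spike"))
disp <- estimate_dispersions(sim$rpf_counts, sim$rna_counts, sim$design, sf)
te   <- classify_isr(te_foldchange(sim$rpf_counts, sim$rna_counts,
                                   sim$design, sf, disp))

table(te$category)
#>           bulk       enhanced hypersensitive      low_count      resistant
#>           8010            173            190           1196            444

global_te_shift(sim$rpf_counts, sim$rna_counts, sim$design, sf)
#> [1] 20.31
```

The recovered 20.31-fold reduction matches the planted 20-fold shutdown.
Repeating with the no-spike comparator (median-of-ratios library factors)
shows what a spike-free analysis would report:

```r
sfl <- list(rpf = spike_size_factors(sim$rpf_counts, "library"),
            rna = spike_size_factors(sim$rna_counts, "library"))
global_te_shift(sim$rpf_counts, sim$rna_counts, sim$design, sfl)
#> [1] 1.10
```

— a 20-fold shutdown reported as a 1.1-fold change: the compositional
blind spot the spike exists to remove. Individual gene calls look like:

```r
head(te[te$category == "enhanced",
        c("gene_id", "base_mean", "log2fc_te", "se", "padj_abs")], 3)
#>      gene_id base_mean log2fc_te    se     padj_abs
#> 86 gene00086   3529.57      2.02 0.688 3.5e-03
#> 90 gene00090     51.24      2.53 0.315 1.4e-15
#> 97 gene00097    100.06      1.00 0.296 7.8e-04
```

Granule enrichment, reporter time courses and polysome loads follow the
same pattern (`enrichment_test`, `simulate_reporter_timecourse` +
`relative_te`, `ribosome_load`); `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell) chains the stages and writes
TSV artifacts plus a JSON summary. The methods vignette
(`vignettes/ribospike-methods.Rmd`) documents the models, parameter
defaults and their rationale.

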