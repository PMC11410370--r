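# promocc — promoter occupancy analysis

`promocc` is an R toolkit for the integrative genomics of a
promoter-binding transcription factor, built around the question: *does a
factor bind at transcription start sites, which sequence does it
recognize there, and do the genes it binds respond transcriptionally?*
The motivating system is the *Drosophila* germline zinc-finger factor
OVO, whose ChIP peaks concentrate at the TSSs of maternally deposited
genes, but every stage is generic: the package consumes standard BED /
GTF / FASTA / bedGraph / TSV inputs and returns tibbles, so analyses
compose with the pipe.

The pipeline covers five statistical layers:

- **Interval association.** Base-pair Jaccard `J = |A ∩ B| / |A ∪ B|` on
  merged interval sets; the relative-distance statistic
  `d = min(q − b_prev, b_next − q) / (b_next − b_prev)`, uniform on
  [0, 0.5] under spatial independence; peak classification into
  TSS / gene-body / intergenic; and genome-wide peak-overlap Fisher tests
  (`jaccard()`, `relative_distance()`, `classify_peaks()`,
  `overlap_fisher()`).
- **Motif scanning.** IUPAC degenerate-class matching on both strands and
  PWM scanning with *exact* p-value thresholds: the null score
  distribution is computed by dynamic programming on a discretized grid,
  and the score cutoff is the smallest `s` with `P(score ≥ s) ≤ α` under
  the background (`iupac_scan()`, `pwm_scan()`,
  `pwm_threshold_from_pvalue()`). The shipped `ovo_motif_catalog()`
  carries the published OVO consensus variants around the
  5'-TAACNGT-3' core; `motif_mask_rescan()` reproduces the iterative
  discover-remove-rescan accounting.
- **CAGE TSS calling.** CTSS aggregation, tags-per-million scaling,
  distance-based and paraclu maximal-density clustering, dominant-TSS
  extraction and oriented promoter windows (`cluster_ctss()`,
  `paraclu_segments()`, `promoter_windows()`).
- **Core-promoter architecture.** Scanning promoter windows for TATA,
  INR, DPE, MTE, M1BP and factor motifs with per-element strand rules,
  positional histograms around the dominant TSS, and per-element Fisher
  enrichment between promoter classes (`scan_promoters()`,
  `element_positional_histogram()`, `element_class_enrichment()`).
- **ChIP × RNA integration.** Strict DE thresholds (`log2FC > 0.5`,
  `p-adj < 0.05`), gene binding status, 2×2 Fisher enrichments over the
  expressed-gene universe with the sample odds ratio
  `(n11·n22)/(n12·n21)` as the headline statistic, and the
  bound-at-TSS ∧ upregulated target report (`gene_status()`,
  `enrichment_2x2()`, `target_gene_report()`).

A first-class synthetic-data module (`simulate_scenario()`) generates a
genome, gene models, replicate peak sets with a controlled base-pair
Jaccard, planted motif instances, CAGE tags, enrichment-shaped coverage
and a DE table with a planted bound×up odds ratio — every planted
quantity is recorded in a `truth` object so downstream estimates can be
tested against known values. Coverage metaprofiles
(`reference_point_matrix()`, `scale_regions_matrix()`,
`column_profile()`, `order_rows()`) replace the usual
computeMatrix/plotProfile/plotHeatmap steps; `autoplot()` and `plot_*()`
functions render the standard figures with ggplot2.

## Worked example

```r
library(promocc)

bundle <- simulate_scenario(scenario_config(seed = 42))
bundle
#> <scenario_bundle: 2 chrom(s), 150 genes, 300+300 peaks (consensus 244), realized Jaccard 0.647>

jaccard(bundle$peaks_rep1, bundle$peaks_rep2)
#> Jaccard 0.6470 (intersection 90074 bp / union 139208 bp); 244/300 query intervals overlap
```

The realized replicate agreement (0.647) sits on the configured target
of 0.64; the 244 replicate-1 peaks that overlap replicate 2 form the
consensus set used downstream.

```r
classify_peaks(bundle$peaks_consensus, bundle$transcripts) |> tidy()
#> # A tibble: 3 × 4
#>   label          n fraction percent
#> 1 TSS          113    0.463      46
#> 2 gene_body     40    0.164      16
#> 3 intergenic    91    0.373      37

ann <- annotate_peak_motifs(bundle$peaks_consensus, bundle$genome,
                            ovo_motif_catalog())
sprintf("any motif: %.0f%%", 100 * ann$any_fraction)
#> "any motif: 76%"
```

46% of consensus peaks contain a TSS (the generator plants 45% of peaks
on TSSs), and 76% carry at least one catalog motif — the planted
fraction of 72% plus a few background matches to the degenerate
variants.

```r
st <- gene_status(bundle$de_table, bundle$transcripts,
                  bundle$peaks_consensus, bundle$embryo_genes)
enrichment_2x2(st, ~ .x$bound_any, ~ .x$de_class == "up")
#> 2x2 [21 97 / 4 28]: OR = 1.52 (cMLE 1.51), two-sided p = 0.599
```

At 150 genes the bound×up odds ratio is noisy; at the study-scale table
rebuilt from published counts the same statistic is decisive:

```r
fisher_exact(666, 1632, 1328, 7178)
#> 2x2 [666 1632 / 1328 7178]: OR = 2.21 (cMLE 2.21), two-sided p = 7.67e-45
```

Genes bound by the factor are 2.21 times as likely to be upregulated as
unbound genes.

## Vignette

`vignettes/promoter-occupancy.Rmd` documents the models, the parameter
choices and their defaults, what the synthetic generator does and does
not emulate, and the package's numerical conventions.
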