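# ckreg

Promoter motif enrichment and cross-platform validation for hormone-response
transcriptome studies.

## What problem this solves

Hormone treatments such as cytokinin (benzyladenine) trigger broad
transcriptional responses. A central follow-up question is whether the
responding genes are direct targets of the pathway's transcription factors —
for cytokinin, the type-B response regulators, whose binding preferences can
be measured in vitro on all possible 8-mers with a protein binding
microarray. `ckreg` is a toolkit for the bespoke computations such a study
needs:

* **Promoter extraction** — the 1 kb strictly upstream of each gene's
  transcriptional start site, strand-aware, from a genome FASTA and a
  GFF3/BED annotation.
* **Exact k-mer scanning** — does a promoter contain one or more of a
  factor's top-scoring 8-mers (including degenerate patterns such as
  `AAGAT[T/C]TT`), on either strand?
* **Resampling enrichment test** — the core statistic. For a focal gene set
  of size *n* with observed motif-presence fraction *f*, draw *N* random
  same-size samples from the gene universe (without replacement) and report
  the fraction with a strictly higher (enrichment) or lower (depletion)
  presence fraction. Because presence is a fixed binary attribute, the exact
  null is Hypergeometric(*M*, *K*, *n*); the closed-form tails are reported
  beside the Monte-Carlo estimates as a built-in cross-check.
* **NanoString nCounter normalization** — negative-control background
  (mean + 2 SD), positive-control standard-curve scaling, reference-gene
  scaling, with "nd"/"ND" not-detected propagation into log2 fold changes.
* **Concordance and overlap** — Pearson/R² agreement of fold changes across
  platforms, gene-set intersections with direction breakdown, many-to-many
  ortholog direction concordance.
* **Expression summaries** — RPKM, expressed-gene flags (≥ 20 reads),
  top-decile read share, up/down splits.
* **Synthetic data** — seeded generators for every input (toy genomes with
  motifs planted at exact rates, simulated nCounter panels with known lane
  factors, correlated fold-change pairs), so the whole pipeline is testable
  against known ground truth.

## Worked example

Simulate a study-like input bundle (300 genes, a 50-gene "up-regulated" set
with motif-rich promoters and a 50-gene "down-regulated" set with motif-poor
promoters over a 22% background), then run the full chain:

```r
library(ckreg)

dir <- tempfile()
paths <- run_simulate(dir, preset = "paper-like", seed = 42)
run_extract_promoters(paths$genome, paths$annotation,
                      file.path(dir, "promoters.fasta"))
run_scan(file.path(dir, "promoters.fasta"), paths$motifs,
         file.path(dir, "hits.tsv"))
rep <- run_enrich(file.path(dir, "hits.tsv"),
                  c(up = paths$de_up, down = paths$de_down),
                  file.path(dir, "enrichment.tsv"),
                  n_resamples = 1000, seed = 42)
rep$results$up_up
#> enrichment_result 'up_up': n = 50, f_obs = 0.600 (universe M = 300, K = 89)
#>   N = 1000 resamples: 0 higher / 1000 lower / 0 tied
#>   p_enriched = 0 (exact 1.719e-07), p_depleted = 1 (exact 1), seed = 1000045
rep$results$down_down
#> enrichment_result 'down_down': n = 50, f_obs = 0.040 (universe M = 300, K = 89)
#>   N = 1000 resamples: 1000 higher / 0 lower / 0 tied
#>   p_enriched = 1 (exact 1), p_depleted = 0 (exact 8.846e-08), seed = 2000048
```

Reading the output: 60% of the up-set promoters contain a motif versus a
universe rate of 89/300 ≈ 30%, and none of 1,000 random samples of 50 genes
matched it — empirical p_enriched = 0 (< 1/N), with the hypergeometric tail
(1.7e-07) agreeing. The down-set at 4% presence is correspondingly depleted.
Re-running with the same seed reproduces the output byte for byte.

The package also ships a 32-gene rice benzyladenine validation panel with
log2 fold changes measured by both RNA-Seq and nCounter:

```r
vp <- nanostring_validation_panel()
platform_concordance(data.frame(gene_id = vp$gene_id,
                                log2fc_a = vp$root_rnaseq,
                                log2fc_b = vp$root_nano))
#> concordance_report: n = 31 pairs (1 nd excluded, policy 'exclude')
#>   Pearson r = 0.9526, R^2 = 0.9074, b = 0.735 a -0.144, sign concordance = 1.000
```

A thin command-line wrapper is installed at `exec/ckreg` inside the package
directory, with subcommands `simulate`, `extract-promoters`, `scan`,
`enrich`, `nano-norm`, `concord`, `overlap` and `summarize`; every output
TSV starts with a comment header recording the parameters and seed.

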