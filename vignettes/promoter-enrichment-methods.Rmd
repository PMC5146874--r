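---
title: "Methods: promoter motif enrichment and cross-platform validation"
author: "ckreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif enrichment and cross-platform validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckreg)
```

## The scientific question

When a hormone such as cytokinin reshapes a transcriptome, a natural
hypothesis is that many of the responding genes are direct targets of the
pathway's terminal transcription factors — in this case the type-B response
regulators, whose DNA-binding preferences can be read out in vitro on all
4^8 possible 8-mers with a protein binding microarray (PBM). If that
hypothesis is right, the promoters of the responding genes should carry the
factor's binding k-mers more often than chance predicts. `ckreg` implements
that test end-to-end: strand-aware promoter extraction, exact k-mer
scanning, and a resampling enrichment statistic, together with the
supporting analyses such a study needs — NanoString nCounter normalization
for independent validation of RNA-Seq fold changes, cross-platform
concordance, gene-set overlap/direction summaries, and RPKM-style
descriptive statistics.

## The enrichment model

Let the *universe* be the $M$ genes eligible for sampling (by default every
gene with an extractable promoter), of which $K$ carry at least one motif
occurrence in their promoter window. For a focal set of $n$ genes (say, the
up-regulated genes in one tissue) the observed statistic is the presence
fraction

$$f_{\mathrm{obs}} = \frac{\#\{\text{focal genes with} \ge 1
\text{ occurrence}\}}{n}.$$

The null distribution is generated empirically: $N$ samples of $n$ genes are
drawn *without replacement* from the full universe (focal genes are not
excluded — they are ordinary members of the sampling frame), and

$$p_{\mathrm{enriched}} = \frac{\#\{f_{\mathrm{null}} >
f_{\mathrm{obs}}\}}{N}, \qquad p_{\mathrm{depleted}} =
\frac{\#\{f_{\mathrm{null}} < f_{\mathrm{obs}}\}}{N},$$

with ties counted separately so the three categories always sum to $N$.
Strict inequalities are used because the scientific claim is literally "how
many random samples contained a *higher* (or *lower*) percentage"; a
conservative estimator $(r + 1)/(N + 1)$ is reported alongside for users who
prefer a p-value bounded away from zero.

Because motif presence is a fixed binary gene attribute and sampling is
without replacement, the number of motif-positive genes in a null sample is
exactly $\mathrm{Hypergeometric}(M, K, n)$. The implementation therefore
reports the closed-form tails $P(X > n f_{\mathrm{obs}})$ and
$P(X < n f_{\mathrm{obs}})$ next to the Monte-Carlo estimates. This dual
route is the package's main self-check: the empirical values must converge
on the hypergeometric tails, and the test suite verifies that on exhaustive
small cases (e.g. $M = 12$, $K = 5$, $n = 5$, where the upper tail is
exactly $1/792$) and on parameter grids. The Monte-Carlo machinery is kept
(rather than just calling the closed form) because it is the procedure the
histogram outputs visualize and it generalizes to null models the
closed form does not cover.

When several gene sets are tested in one run, Benjamini–Hochberg adjusted
columns are appended for convenience; the raw empirical values remain the
primary output.

### Numerical details

* Tie detection compares null hit *counts* against $n f_{\mathrm{obs}}$ with
  an absolute guard of $10^{-9}$, so fractions that are exactly
  representable (multiples of $1/n$) are classified without floating-point
  surprises.
* Every stochastic function takes a `seed`; the seed is recorded in the
  result object and in all file outputs. Multi-set reports derive per-set
  child seeds from one master seed, and all helpers restore the caller's
  RNG state on exit.
* With $n = M$ every sample equals the universe and both tails are 0 — the
  degenerate case is well-defined rather than an error.

## Promoter windows

The promoter of a gene is the $W$ bp *strictly upstream* of its
transcriptional start site (default $W = 1000$): genomic positions
$[\mathrm{tss} - W, \mathrm{tss} - 1]$ for `+` genes and
$[\mathrm{tss} + 1, \mathrm{tss} + W]$ reverse-complemented for `-` genes,
so every sequence reads 5'→3' toward the TSS. The TSS base itself is
excluded. Windows truncated by a contig edge are kept and flagged rather
than dropped (dropping would silently shrink the universe); genes whose
window has zero length are retained with an empty sequence. Soft-masked
(lowercase) bases are uppercased; `N` bases are retained and can never
match a k-mer, which is the conservative choice when masking provenance is
unknown. Windows are *not* masked against overlapping neighbor genes — with
no principled rule available, leaving the sequence intact is the least
surprising behavior. The TSS is taken from the gene feature's 5' end; the
annotation loader exposes `feature_type` so users whose annotations define
TSSs on `mRNA` features can select them explicitly.

## Motif sets and scanning

A motif set is a plain list of equal-length ACGT k-mers, optionally scored
(e.g. PBM E-scores), with degenerate patterns such as `AAGAT[T/C]TT`
expanded on ingestion. Scanning is exact set-membership of every length-$k$
window — no position-weight thresholds — because the biological statement
being tested is "the promoter contains one or more of the top-scoring
8-mers". Both strands are scanned by default: PBM probes are
double-stranded, so the assay does not fix an orientation. A window that
matches both a k-mer and (as a palindrome) a reverse complement is counted
once. Overlapping occurrences are all counted, but only the binary
`has_hit` feeds the enrichment statistic, so the counting convention cannot
affect headline results. Position frequency matrices (`build_pfm`) are
descriptive output for logo-style visualization, not a scanning model.
Scanning is delegated to `Biostrings` pattern dictionaries; the test suite
holds it to an independent all-substrings brute-force oracle.

## nCounter normalization

The normalization chain follows standard nCounter practice in three steps
per lane:

1. **Background.** $B = \bar{x}_{\mathrm{neg}} + 2\,s_{\mathrm{neg}}$ over
   the (eight) negative-control probes, with the $n-1$ SD. Counts at or
   below $B$ are flagged *not detected* — never floored to a small positive
   value, because a floored value would masquerade as a measurement in every
   downstream ratio.
2. **Standard curve.** Each lane's scale factor is the across-lane
   arithmetic mean of per-lane geometric means of the (six)
   background-corrected positive controls, divided by the lane's own
   geometric mean. The per-lane regression of log counts on the known
   concentration ladder is computed and reported as QC (slope, $R^2$) but
   not used for scaling: with counts inside the linear dynamic range the
   fitted line adds nothing beyond its intercept, and geometric-mean scaling
   is the established estimator.
3. **Reference genes.** The same geometric-mean construction over the
   (three) reference probes, applied after positive-control scaling.

A normalized value is $(x - B)\, s_{\mathrm{pos}}\, s_{\mathrm{ref}}$ when
$x > B$. Per-probe log2 fold changes are the log2 ratio of detected-replicate
condition means (the mean of per-replicate log ratios is available behind a
flag); probes with no detected treated replicate are coded `nd-treated`,
none detected in control `nd-control`, none anywhere `ND`, and these codes
propagate as strings into file outputs.

One property worth stating precisely: rescaling all counts in one lane by a
constant leaves every normalized value multiplied by one *common* factor
(the cross-lane target moves with the lane), so all between-lane ratios and
every log2 fold change are exactly invariant. No normalization whose
targets are cross-lane averages can do better, and the test suite asserts
exactly this form of the invariance.

## Cross-platform concordance and overlap

`platform_concordance` reports Pearson $r$, $R^2$, the least-squares line
and sign concordance for paired log2 fold changes. Not-detected entries are
excluded by default; an `nd_policy = "zero"` variant substitutes 0, provided
because treating an undetected transcript as "no change" is a defensible
alternative reading when comparing against published panel summaries —
the package reports both and asserts neither as canonical. The bundled
32-gene rice benzyladenine validation panel
(`nanostring_validation_panel()`) ships as plain text and serves as a fixed
desk-check: its root-tissue pairs must reproduce the same correlation as an
independent textbook Pearson computation.

`set_overlap` intersects two DE tables and splits the intersection by sign
agreement of log2 fold change; zero fold changes carry no direction and are
reported as undirected rather than forced into either bin. An optional
hypergeometric upper tail for the overlap size is available when a universe
size is stated. `ortholog_concordance` handles many-to-many ortholog maps
with an explicit precedence — a source gene is *same-direction* if any
ortholog is DE with matching sign, else *opposite* if any opposes, else
*not-DE*, and genes without orthologs leave the denominator. The precedence
rule is the package's own decision (no published convention exists for the
many-to-many case); it is deliberately generous to conservation, and the
counts it feeds are all reported so users can re-derive alternatives.

## Expression summaries

RPKM uses user-supplied expressed-sequence lengths and per-sample total
mapped reads (not column sums — reads mapping outside annotated genes still
count toward sequencing effort). A gene is called expressed at a summed
count of ≥ 20 across samples, a minimal-evidence threshold at which roughly
half of annotated rice genes register in seedling tissue. `top_share` ranks
genes by count with ties broken lexicographically by gene id so the
statistic is deterministic; at realistic library scales the tie rule is
invisible.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth:

* **Toy genomes** (`make_toy_genome`): random ACGT contigs with genes in
  fixed-width slots, each with a full window of upstream clearance, on
  alternating strands. Defaults are desk-scale (hundreds of genes, 1 kb
  windows) — large enough to exercise every code path, small enough that the
  whole suite runs in minutes.
* **Motif planting** (`plant_motifs`): background promoter sequence is
  rejection-sampled until motif-free on both strands, then hits are planted
  with probability $p_1$ (focal) or $p_0$ (background) at uniform random
  position and strand. Presence probabilities are therefore *exact*, which
  makes enrichment tests sharp; the corresponding flag-level generator
  (`simulate_hit_universe`) scales the same design to realistic universes
  (30,000 genes, 2,890-gene focal sets, background presence 0.22 vs. focal
  0.278 — a realistic study geometry). At desk scale those rates
  are statistically invisible (a 50-gene set at 27.8% vs. 22% background has
  essentially no power), so the sequence-level `"paper-like"` preset keeps
  the background rate and enlarges the planted contrast (0.65 for the
  up-set, 0.05 for the down-set) — a deliberate, documented trade of
  realism-in-rates for detectability-at-scale; the realistic rates are
  exercised at the realistic scale by the flag-level generator.
* **nCounter panels** (`simulate_nanostring_panel`): expected counts are
  `lane_factor * (baseline * effect + background)`. With `sigma > 0`,
  endogenous probes get multiplicative log-normal noise on their expression
  (per-transcript variability across hybridizations) and every probe gets
  Poisson counting noise; spike-in positive controls and reference genes
  carry counting noise only, since they are precisely the stability anchors
  the normalization chain assumes. `sigma = 0` switches all noise off, and
  endogenous baselines are snapped to multiples of 8 so noiseless panels
  with fold changes in $2^{-3} \dots 2^{3}$ have integer expected counts and
  normalization recovers planted ratios *exactly*. `-Inf`/`Inf` fold changes
  encode transcripts absent from one condition, exercising the `nd` logic.
* **Paired fold changes** (`simulate_paired_foldchanges`): bivariate normal
  with unit variances at a target correlation (default 0.93, the
  validation-study scale).

What the generators do *not* emulate: read-level sequencing (no FASTQ, no
alignment), GC or compositional realism of promoters, gene-length/expression
correlations, or cartridge-level nCounter batch effects. Passing tests
demonstrate that the *computations* are correct under their stated models,
not that real promoters are random ACGT away from planted motifs.

## Pipeline and configuration

The `run_*` functions (and the thin `exec/ckreg` command-line wrapper with
subcommands `simulate`, `extract-promoters`, `scan`, `enrich`, `nano-norm`,
`concord`, `overlap`, `summarize`) bind the stages file-to-file. Every
output TSV begins with `# key=value` comment lines recording the tool
version, parameters and seed, so identical configurations reproduce
byte-identical outputs. Defaults mirror the study design: window 1000 bp,
1,000 resamples, FDR cutoff $10^{-4}$, both-strand scanning, `nd` values
excluded. Run configuration files are flat YAML (`read_run_config`), chosen
as the plainest structured format with a solid R parser; command-line flags
override configuration values.

## Problem sizes in the test suite

The shipped tests run the scan oracle on 1,000 random sequences up to 2 kb;
the exhaustive enrichment check at $M = 12$ with $10^5$ resamples plus a
parameter grid at $2 \times 10^4$; null calibration with 500 random focal
sets at 1,000 resamples each; planted enrichment at the full study geometry
(30,000 genes, 2,890-gene sets) over 100 seeded replicates; and the
end-to-end sequence pipeline at 300 genes. These sizes were chosen so the
complete suite finishes in well under ten minutes on a single core while
every statistical claim is tested at a scale where its tolerance is
meaningful.

## Known limitations

* The null model is unadjusted random sampling: no GC-, length- or
  expression-matched nulls, and no positional weighting within the window.
* Scanning is exact-match only; near-miss binding sites (one mismatch from
  a listed 8-mer) are invisible by design.
* The nCounter chain models one cartridge; combining cartridges needs an
  upstream batch correction the package does not provide.
* `ortholog_concordance`'s precedence rule slightly favors same-direction
  calls for genes with many orthologs; the raw counts are reported so any
  alternative rule can be recomputed.
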