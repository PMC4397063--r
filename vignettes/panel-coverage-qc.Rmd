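---
title: "Evaluating capture efficiency of targeted sequencing panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating capture efficiency of targeted sequencing panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcov)
```

## The problem

Hybridization capture enriches a sequencing library for a designed set of
genomic intervals — a gene panel — before sequencing. Whether an
experiment succeeded is judged not by raw yield but by how the yield is
spent: what fraction of reads landed on the designed target, how deep the
target is covered on average, whether every targeted base reaches the
depth needed for reliable variant calling, and how evenly the capture
spread its depth over the target. These questions become acute when many
indexed libraries are multiplexed on one run and several samples share a
single capture reaction (pre-enrichment pooling): each sample then
receives only a slice of the run, and any capture unevenness is paid for
with extra sequencing.

`panelcov` computes these quantities directly from per-sample alignments
(BAM/SAM) and a BED description of the panel, aggregates them over
pre-enrichment pools, checks multiplex index balance, verifies genotype
calls against an orthogonal SNP-array experiment, and renders a
per-gene/per-exon coverage report for human review.

## Definitions and the model of a "good capture"

Let the *region of interest* (ROI) be the union of the panel's intervals,
with $B$ unique targeted bases, and let $d(b)$ be the depth at base $b$
(defined below). The per-sample metrics are:

* **Mean base coverage** $\mu = \frac{1}{B}\sum_b d(b)$, computed over
  *unique* bases: intervals listed twice, or overlapping exons, count each
  genomic base once. Per-exon means, in contrast, are computed per listed
  interval, so the per-exon report always mirrors the design file.
* **Percentage of bases at threshold** $100 \cdot |\{b: d(b) \ge T\}| / B$
  with $T = 30$ by default, the conventional minimum for confident
  germline variant calling.
* **Enrichment stability** $100 \cdot |\{b: d(b) \ge f\mu\}| / B$ with
  $f = 0.2$. Because the cut scales with $\mu$, this measures evenness of
  capture independently of sequencing depth, and is comparable across
  pools sequenced at different depths.
* **On-target percentage** $100 \cdot$ (retained reads whose aligned span
  overlaps at least one ROI base) / (retained reads). This reflects the
  efficiency of the capture chemistry rather than sequencing depth.
* **Cumulative normalized coverage curve**: the fraction of bases with
  $d(b) \ge x\mu$ as a function of $x$. The curve starts at 100% at
  $x = 0$, is non-increasing, and passes through the stability value at
  $x = f$.

The comparator is `at least` ($\ge$) by default. Published tables often
print such cuts as "$> T$" while describing them as "at least $T$"; the
discrepancy only matters for bases sitting exactly on the cut, and
`metrics_config(comparator = "strictly-greater")` switches the
convention.

## Depth semantics

Depth is computed natively from the alignment records:

* Coordinates are BED convention (0-based half-open) everywhere
  internally; 1-based coordinates appear only in rendered reports.
* A base is covered by a record only through aligned-match CIGAR
  operations (`M`, `=`, `X`). Deletions (`D`) and reference skips (`N`)
  consume reference without covering it; clips and insertions never
  cover. This matches the dominant convention of per-base depth tools.
* The default record filter excludes unmapped, duplicate, secondary,
  supplementary and QC-fail records and applies no mapping-quality cut
  (`read_filter(min_mapq = 0)`), mirroring a standard pipeline in which
  duplicates are flagged upstream.
* Overlapping mates of a read pair both contribute depth. There is no
  mate-aware deduplication; users comparing against mate-aware tools
  should expect slightly higher depths over mate overlaps.
* The on-target test uses the record's aligned span against the merged
  targets with 0 bp padding by default. Padding is exposed
  (`compute_depth(..., padding = )`) because some laboratories count
  near-target reads as usable; the unpadded definition is the strictest
  and most reproducible one.
* Strand is ignored throughout: capture depth is strand-agnostic.

## Pools, index balance and the run budget

`aggregate_pools()` reports, per pre-enrichment pool and for a Total row,
the mean and sample standard deviation (n − 1 denominator, the unbiased
convention for "± SD" across samples) of each metric. SD is omitted for
single-sample pools.

`index_distribution()` converts demultiplexed read counts into each
index's share of its pool, plus a uniformity statistic (maximum absolute
deviation from the ideal $100/n$ percent). Departures beyond ordinary
pipetting variation indicate index synthesis or demultiplexing problems.

`plan_run_budget()` is the closed-form planner
$coverage = yield \cdot (1 - dup) \cdot onTarget / (n \cdot target)$:
with the nominal 4.608 Gb of a 2x150 bp MiSeq v2 run, 96 samples and a
1.6 Mb target it returns exactly 30X, the familiar rule of thumb for how
large a design a single multiplexed run can support.

## Genotype concordance

Concordance against SNP-array genotypes is defined as identical unordered
allele pairs at sites typed by both platforms. Decisions that needed
making beyond that definition:

* **Missing calls** (either side) leave the denominator and are reported
  separately, so per-site denominators count samples genuinely typed by
  both platforms.
* **Strand**: array exports may report genotypes on either strand.
  Minus-strand genotypes are complemented; genotypes with *unknown*
  strand whose alleles are strand-ambiguous (A/T, C/G) are excluded and
  flagged rather than guessed, because a silent strand flip corrupts
  concordance undetectably.
* **Homozygous reference**: variant callers emit no record at a
  non-variant site, which is evidence of hom-ref only if the site was
  sequenced. `infer_homref()` fills hom-ref calls at sites reaching a
  minimum depth (default 30, the same threshold used for coverage QC) and
  leaves under-covered sites missing. This is a stated convention of this
  package; gVCF-based pipelines can supply their own calls instead.

## The coverage report

`render_coverage_report()` writes, in order: general alignment
statistics, the metric table, the cumulative normalized coverage curve,
one exon-coverage bar chart per gene with a horizontal red threshold
line, and base-level depth plots. Base-level plots default to
`failing-only` — exons with at least one base below the threshold — which
keeps reports small while still exposing local coverage drops; `always`
and `never` are available. Exon bars are ordered by genomic position
within each gene and gene panels alphabetically, so output is
deterministic. Displayed numbers follow the conventional rounding
(coverage as integers, percentages to 2 decimals); all computation is
full precision.

HTML is the primary format: figures are inline SVG, structure is
assertable, and with timestamping disabled (the default) two renders of
the same inputs are byte-identical. PDF output uses R's `pdf()` device,
whose container embeds a creation timestamp, so the byte-identical
guarantee applies to the HTML renderer. A JSON companion with every
plotted number is always written next to the report.

## The fixture generator

Synthetic data underpin every test, so what the generator does — and does
not — emulate matters.

`generate_roi()` lays out disjoint exons with fixed spacing; the default
shape (18 genes, 20 exons each, 157 kb total) matches a realistic small
diagnostic panel. `generate_alignments()` tiles reads layer by layer so
that *every* targeted base receives exactly the requested depth — the
manifest's expected depths and counts are therefore known arithmetically,
independent of the coverage engine. Off-target reads go to a dedicated
decoy chromosome, which makes on-target counting unambiguous by
construction; duplicate-flagged copies are depth-neutral under the
default filter. Reads are single-end since no depth semantics depend on
pairing. `generate_genotypes()` plants exact numbers of discordant and
missing calls, so the expected concordance table is exact.

What this emulates well: the accounting. Depth, on-target fractions,
pool means, concordance counts are all exercised against analytically
known truth. What it does not emulate: sequencing error, GC- and
probe-dependent capture bias at base resolution, insert-size structure,
mate overlaps, and alignment artefacts. Passing tests therefore
demonstrate that the *computation* is correct, not that any particular
real experiment will look like the fixtures.

## Simulation sizes and numerical choices

The package's own end-to-end simulations use a scaled panel — 18 genes x
4 exons x 250 bp (18 kb of target) for the 34-sample pooled-study
simulation, and the full 360-exon/157 kb shape where panel shape itself
is under test — sizes chosen so the whole suite runs comfortably on a
laptop. The pooled-study simulation draws per-sample mean depths around
per-pool targets (553/243/157/180 for pools of 4/8/10/12 samples),
applies gamma-distributed per-exon capture bias (CV 0.25), and marks a
fixed small subset of exons (scaled from 4 per 360) as weak probes
retaining 2–15% of expected depth — reflecting the observation that a few
probes in any design underperform consistently across samples.

Other numerical conventions: depths are integers; percentages are exact
ratios of integer counts (closure tests assert them to 1e-9); the
cumulative-curve grid defaults to $x \in \{0, 0.05, \ldots, 2\}$, which
covers the $f = 0.2$ landmark exactly; interval merging treats touching
intervals as one; degenerate samples ($\mu = 0$) report 0 for the
threshold and stability percentages with a warning rather than NaN.

## Known limitations

* No CRAM input; no base-quality-weighted pileup; no indel-aware depth.
* Mate overlaps double-count (documented above).
* Whether listed exons may overlap is design-dependent; global metrics
  use merged bases, per-exon tables use listed intervals, and both
  conventions are stated rather than configurable.
* The array-genotype reader supports one documented TSV dialect
  (site rows, sample columns, explicit strand column); other export
  formats need reshaping first.

## A worked example

```{r example, eval = FALSE}
panel <- generate_roi(n_genes = 4, exons_per_gene = 5, exon_length = 300,
                      spacing = 1000)
fx <- generate_alignments(panel, depth = 60L, read_length = 150,
                          off_target_fraction = 0.23, seed = 99,
                          sam_path = "demo.sam")
rec <- read_alignments("demo.sam")
res <- compute_depth(rec, panel)
summ <- summarize_coverage(res$profile, res$counts, sample_id = "demo")
summ
render_coverage_report(summ, res$profile, panel, report_spec(), "demo.html")
```
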