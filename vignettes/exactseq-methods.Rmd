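---
title: "Exact-match split-read quantification and noise-regularized fold changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact-match split-read quantification and noise-regularized fold changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exactseq)
```

# The pipeline

`exactseq` implements a deterministic desk-scale RNA-seq analysis chain —
exact-match split-read mapping on a suffix array, median-coverage gene
expression, quantile normalization, density-peak noise estimation,
noise-regularized log2 fold changes, correlation-based sample outlier
screening, heat-map standardization — together with the ΔCt qPCR arithmetic
used to validate differential calls, and a synthetic-data generator that
stands in for unreleased raw sequencing data. This vignette explains the
model behind each stage, the tunable parameters, and the design choices made
where the procedure was genuinely open.

# Mapping model

A read of length $L$ is trimmed by 2 nt at each end and split into three
parts of $k = (L-4)/3$ nt, so the canonical 100-nt single-end read gives
three 32-mers at read offsets 2, 34 and 66. Each part is looked up, on both
strands, in a lexicographically sorted suffix array over the concatenated
reference (sentinel bytes between sequences keep matches from crossing
boundaries; the construction is a plain comparison sort in C++, adequate far
beyond the 50-kb desk scale this package targets). A *candidate placement*
is a position where all three parts hit the same sequence and strand at
exact spacing $k$. The read's status is:

* `unique` — exactly one candidate genome-wide (the only status that
  contributes to coverage under the default policy);
* `multi` — more than one candidate (dropped by default; `keep-first`
  retains the first in reference order);
* `unmapped` — some part has no hit on either strand;
* `discordant` — every part hits somewhere, but never collinearly;
* `geometry_skipped` — $(L-4)$ not divisible by 3, or parts shorter than
  `min_part` (default 20 nt, below which spurious exact hits become likely).

Exactness is taken literally: `N` in the reference matches nothing, queries
containing `N` match nothing, and a single substitution anywhere in the
inner $3k$ nt discards the read (errors in the trimmed 2-nt flanks are
invisible). The reconciliation rule — all three parts, exact spacing, one
strand — is the strictest reading consistent with unambiguous coverage;
whether the original procedure rescued reads with one failed part is
unknown, so no rescue is attempted.

Coordinates are 0-based half-open internally and converted only at output
boundaries (SAM is 1-based; BED stays 0-based).

# Expression and normalization

Unique placements add depth 1 over the full trimmed span ($3k$ = 96 bp for
100-nt reads). Since the three parts are adjacent by construction, counting
the whole span versus the parts separately differs only for discordant
reads, which are excluded anyway. A gene's expression is the **median depth
over every base of its interval(s)** (even counts take the mean of the two
central values); a base shared by overlapping genes counts toward both, and
multi-interval genes are summarized over their concatenated bases.

Sample columns are quantile normalized to the across-sample mean of order
statistics, with ties receiving the mean of their tied target quantiles
(via `limma::normalizeQuantiles(ties = TRUE)`, whose contract is exactly
this). The operation is idempotent and rank-preserving within columns.

# Noise estimation and regularized fold change

All values of the normalized matrix are pooled and transformed by
$y = \log_2(1 + x)$; a Gaussian kernel density with Silverman's rule
bandwidth on a 512-point uniform grid is evaluated, and the noise level is
the inverse transform of the density argmax. In data with a cohort of genes
at a shared low-expression floor, the argmax sits on that floor: the floor
cohort is tight while genuinely expressed genes spread over orders of
magnitude. The estimate is computed *after* normalization and after outlier
exclusion (recorded in the estimate's metadata); a degenerate all-equal
matrix returns that value with a warning flag.

The per-gene statistic is

$$\mathrm{lgFC}(g) = \log_2 \frac{\overline{\mathrm{case}}(g) + \mathrm{noise}}
{\overline{\mathrm{ctrl}}(g) + \mathrm{noise}}$$

with group means taken over retained replicates. Adding the noise to both
means shrinks every fold change toward zero — strictly, unless the means are
equal — and monotonically in the noise, so low-expression genes cannot
reach large |lgFC|; a gene at zero in both conditions reports exactly 0.
Two conventions are configurable: the log base (default 2, matching the
log2-scaled heat maps) and the orientation. The default is
case-over-control, which reproduces the reported signs (knockdown-induced
genes positive); `orientation = "printed"` gives the control-over-case form
of the written equation, which is the same quantity with the sign flipped.
No p-values are attached — the regularization, not a test, is what keeps
the top of the ranking meaningful.

# Outlier screening

Samples are compared by Pearson correlation of their $\log_2(1+x)$ columns.
Exclusion is greedy and iterative: while the worst retained sample's mean
correlation to the other retained samples is below the threshold (default
0.8), it is excluded and the means recomputed. The iteration matters: a
single shuffled or swapped sample drags *every* sample's one-shot mean
correlation down, so a non-iterative cutoff would flag the whole batch,
while the greedy version isolates exactly the discordant sample. At least
two samples are always retained, and with fewer than three the screen is
reported as not applicable. The metric and threshold are package decisions —
the source procedure says only that coverage was used to cluster samples
and exclude outliers — and both are recorded in the report.

# Heat-map standardization

Figure panels display lgFC clipped to $[-1.5, +1.5]$ (blue to red on a log2
scale). `standardize_for_heatmap()` clips, orders rows by the requested
panel, and reports panel genes missing from the table rather than dropping
them silently. Rendering (via pheatmap) is cosmetic; no analysis reads the
figure back.

# qPCR quantification

Triplicate Ct values are averaged arithmetically on the Ct scale (no
replicate rejection — no rule was given). Relative expression of a target
within a sample is $2^{\mathrm{Ct}_{\mathrm{ref}} - \mathrm{Ct}_{\mathrm{target}}}$,
i.e. $2^{-\mathrm{Ct(target)}}/2^{-\mathrm{Ct(reference)}}$ under perfect
doubling; the reference gene (rpp0-style) cancels sample-wide efficiency
shifts, so adding a constant to every Ct of a sample leaves fold changes
unchanged. The condition fold change is the **ratio of condition means of
per-sample relative expressions** — matching per-sample dots in validation
figures — rather than $2^{-\Delta\Delta \mathrm{Ct}}$ on condition-mean Cts;
the two coincide except under replicate imbalance. Because clutch pairing
was not stated per gene, both pooled (default) and paired (`pair_id`) modes
are provided; they agree exactly when pairs share control values.

# The synthetic-data generator

No accession exists for the original raw reads, so the generator defines the
study conditions the package is tested under:

* two conditions ("std MO"-style control vs "mpi MO"-style case) × 3
  replicates, 100-nt single-end reads, target depth 30×;
* 200 genes of 500–800 bp laid out non-overlapping with 50-bp spacers on a
  uniform-random chromosome; repeat-free mode redraws until every 32-mer is
  unique, so exact search is single-valued for oracle tests;
* per-gene baselines log-normal with meanlog $\log 50$ and sdlog 1.2 — a
  few orders of magnitude of dynamic range, as real transcriptomes show;
* 30% of genes at a shared low floor of 5 expression units (10% of the
  median baseline): low but nonzero, so the floor appears as a distinct
  sharp peak in the pooled density — the feature the noise estimator keys
  on;
* 20 planted log2 fold changes of ±2, drawn from the 60th–90th baseline
  percentile of non-floor genes. They are well above the floor ("high
  expression") but deliberately *inside* the expression continuum: rank-based
  quantile normalization relies on most genes at any rank being unchanged,
  and stacking all up-regulated genes at the extreme tail — where no anchor
  genes remain above them — collapses their fold change by construction, an
  artifact of a 200-gene toy that a 20k-gene transcriptome does not exhibit;
* read counts per gene multinomial over expression-weighted gene lengths,
  uniform start positions and strands, i.i.d. substitution errors at a
  configured rate (default 0), constant qualities;
* qPCR plates with $\mathrm{Ct} = \mathrm{offset} - \log_2(\mathrm{expression})
  + \mathcal{N}(0, 0.2^2)$ cycles in triplicate and a fold-change-1 reference
  gene.

Every simulator is a pure function of (config, seed), and every read carries
ground truth (source gene, position, strand). What the generator does *not*
emulate — positional and GC bias, quality-dependent errors, splicing,
library-size heterogeneity, biological replicate variance beyond counting
noise — bounds what passing tests show: they validate the pipeline's
arithmetic and its recovery of planted signal under the stated design, not
robustness to real-library artifacts.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the design above (~230k
reads across six samples, a ~140-kb reference) plus a 50-kb/1000-read
mapper-versus-oracle comparison; both complete in well under a minute each
on one CPU. Tolerances in stochastic tests derive from the simulation
itself (binomial intervals for read allocation, propagated Ct noise for
qPCR recovery, ±25% for mode recovery of a 90/10 mixture at $n = 1000$).
Deterministic contracts — split geometry, median oracle, quantile
normalization target, clipping, ΔCt identities — are asserted exactly.

Known limitations: exact matching makes sensitivity fall linearly with the
error rate (a 1% per-base error rate discards roughly $1 - 0.99^{96} \approx
62\%$ of reads); the suffix array is held uncompressed in memory and is not
meant for genome-scale references; multi-mappers are dropped rather than
rescued; and the noise estimate is a single global value shared by all genes
and both groups.
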