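# exactseq

Exact-match split-read RNA-seq quantification with noise-regularized fold
changes, plus the ΔCt qPCR arithmetic used to validate such calls.

## The problem

Short-read RNA-seq pipelines usually tolerate mismatches during alignment and
model counts with a parametric distribution. An alternative, entirely
deterministic strategy — used to profile morpholino-knockdown zebrafish
embryos against standard-control morphants — is:

1. **Exact-match split-read mapping.** Each 100-nt single-end read is trimmed
   by 2 nt at each end and split into three 32-nt parts (read offsets 2, 34,
   66). The parts are looked up in a suffix array over the reference and the
   read is placed only where all three parts match *exactly*, collinearly, at
   spacing 32, on one strand of one sequence. One such locus genome-wide
   gives a unique placement; several, a multi-mapper; none, an unmapped or
   discordant read. Sequencing errors in the trimmed flanks are invisible;
   any error in the inner 96 nt discards the read.
2. **Median-coverage expression.** Unique placements add depth 1 over their
   full 96-bp trimmed span; a gene's expression is the **median depth across
   its transcript** — robust to coverage spikes at this scale.
3. **Quantile normalization** across samples (mean-of-order-statistics
   target, ties averaged), followed by correlation-based screening for
   outlier samples ("cluster and exclude").
4. **Noise-regularized log fold change.** The pooled expression density on a
   log2(1+x) scale has a sharp peak at the low-expression floor; that peak is
   the *noise* level, and per-gene fold changes are

   lgFC(g) = log2 ( (case(g) + noise) / (ctrl(g) + noise) )

   so weakly expressed genes cannot reach large fold changes. Heat-map panels
   clip lgFC to the display range [−1.5, 1.5].
5. **qPCR validation arithmetic.** Relative expression within a sample is
   2^−Ct(target) / 2^−Ct(reference) = 2^(Ct(ref) − Ct(target)) after
   averaging triplicate Cts; condition fold change is the ratio of condition
   means of those per-sample values (optionally paired by clutch).

The raw sequencing data behind the original study are not public, so the
package ships a first-class synthetic-data generator (`sim_config()`,
`simulate_reference()`, `simulate_reads()`, `simulate_qpcr()`) that emulates
the study design — two conditions × 3 replicates, ~30× depth, 200 genes, 20
planted log2 fold changes of ±2, a shared low-expression noise floor — with
per-read ground truth, making every stage testable end to end.

## Worked example

```r
library(exactseq)

cfg <- sim_config(seed = 42)    # the default synthetic study design
res <- run_experiment(cfg)      # simulate -> index -> map -> quant -> normalize -> DE

res$stats$ctrl_1
#>            total           unique            multi         unmapped
#>            38832            38832                0                0
#>       discordant geometry_skipped
#>                0                0

res$noise
#> NoiseEstimate: 1.348792 (scale log2(1+x) )

head(res$de, 5)
#>   gene_id mean_ctrl mean_case      lgFC
#> 1 gene017  90.66667 18.277778 -2.229068
#> 2 gene116 114.19444 24.777778 -2.144843
#> 3 gene055  42.47222  9.111111 -2.066753
#> 4 gene174  36.77778  8.333333 -1.977401
#> 5 gene064  24.58333 90.666667  1.827136

evaluate_recovery(res$de, res$sim$truth)
#> $sign_accuracy
#> [1] 1
#> $mae
#> [1] 0.3233068
#> $n_de
#> [1] 20
```

Every error-free read maps back uniquely (exact matching on a repeat-free
reference); the noise estimate sits at the planted low-expression floor
(coverage ≈ 1.3 after normalization); the top of the fold-change table is
exactly the planted ±2 cohort, with shrinkage pulling |lgFC| slightly below
2; over the 20 planted genes the sign is always right and the mean absolute
error is 0.32 log2 units.

The `DETable` feeds `standardize_for_heatmap()` (clipping at ±1.5 for figure
panels) and the qPCR side is exercised with `simulate_qpcr()` +
`fold_change()`.

A command-line front end wraps the same functions:

```sh
exec/exactseq simulate --seed 5 --outdir sim/
exec/exactseq index    --fasta sim/ref.fa --out ref.idx
exec/exactseq map      --index ref.idx --fastq sim/ctrl_1.fq --out pl.tsv
exec/exactseq quant    --placements pl.tsv --fasta sim/ref.fa --bed sim/genes.bed --out expr.tsv
exec/exactseq de       --expr expr.tsv --groups groups.tsv --out de.tsv
exec/exactseq qpcr     --ct sim/ct.tsv --reference rpp0 --gene gene005 --out fc.tsv
```

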