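#' Run the full synthetic two-condition experiment
#'
#' Convenience wrapper chaining every stage: simulate reference and reads,
#' build the suffix-array index, map each sample, accumulate coverage and
#' median-coverage expression, assemble and quantile-normalize the matrix,
#' screen sample outliers, estimate the noise level, and compute the
#' regularized log2 fold-change table.
#'
#' @param config A [sim_config()].
#' @param repeat_free Passed to [simulate_reference()].
#' @return List: `sim` (reference/annotation/truth), `index`, `stats`
#'   (per-sample mapping stats), `raw` and `normalized` expression matrices,
#'   `groups`, `outliers`, `noise`, `de` (the `DETable`).
#' @export
run_experiment <- function(config, repeat_free = TRUE) {
  sim <- simulate_reference(config, repeat_free = repeat_free)
  index <- build_index(sim$refs)
  trimmed_len <- config$read_length - 4L
  samples <- list()
  groups <- character()
  stats <- list()
  i <- 0L
  for (cond in c("ctrl", "case")) {
    for (r in seq_len(config$n_replicates)) {
      i <- i + 1L
      sid <- sprintf("%s_%d", cond, r)
      rd <- simulate_reads(sim, cond, config, sample_id = sid,
                           seed = config$seed + i)
      m <- map_fastq(index, rd$reads)
      cov <- accumulate_coverage(m$placements, sim$refs, trimmed_len)
      samples[[sid]] <- gene_expression(cov, sim$annot)
      groups[sid] <- cond
      stats[[sid]] <- m$stats
    }
  }
  raw <- build_matrix(samples, sim$annot)
  normalized <- quantile_normalize(raw)
  outliers <- detect_outliers(normalized)
  keep <- outliers$sample_id[!outliers$excluded]
  normalized_kept <- normalized[, keep, drop = FALSE]
  noise <- estimate_noise(normalized_kept)
  de <- de_table(normalized_kept, groups[keep], noise)
  list(sim = sim, index = index, stats = stats, raw = raw,
       normalized = normalized, groups = groups, outliers = outliers,
       noise = noise, de = de)
}

#' Compare a fold-change table with planted truth
#'
#' @param de A `DETable`.
#' @param truth Gene-level truth with `gene_id` and `log2fc`.
#' @return List: `sign_accuracy` (fraction of planted DE genes whose lgFC
#'   sign matches the planted sign), `mae` (mean absolute lgFC error over
#'   planted DE genes), `n_de`.
#' @export
evaluate_recovery <- function(de, truth) {
  planted <- truth[truth$log2fc != 0, , drop = FALSE]
  est <- de$lgFC[match(planted$gene_id, de$gene_id)]
  list(sign_accuracy = mean(sign(est) == sign(planted$log2fc)),
       mae = mean(abs(est - planted$log2fc)),
       n_de = nrow(planted))
}
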