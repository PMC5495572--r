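#' Read a qPCR Ct table
#'
#' Headered TSV with columns `sample_id`, `condition` (`ctrl`/`case`),
#' optional `pair_id` (clutch pairing), `gene_id`, and replicate columns
#' `ct_1..ct_n` (NA allowed for missing replicates).
#'
#' @param path TSV path.
#' @param reference Reference gene id (rpp0 / Rps28 / RPS18 style); must be
#'   measured in every sample.
#' @return A `CtTable` data.frame with attribute `"reference"`.
#' @export
read_ct_table <- function(path, reference) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ct_table(df, reference)
}

#' Construct/validate a CtTable
#'
#' @param df data.frame as described in [read_ct_table()].
#' @param reference Reference gene id.
#' @return Validated `CtTable`.
#' @export
ct_table <- function(df, reference) {
  needed <- c("sample_id", "condition", "gene_id")
  stopifnot(all(needed %in% names(df)))
  ct_cols <- grep("^ct_", names(df), value = TRUE)
  if (length(ct_cols) == 0) stop("no replicate columns (ct_1..ct_n) found")
  cts <- as.matrix(df[, ct_cols, drop = FALSE])
  if (any(rowSums(is.finite(cts)) < 1)) {
    stop("every (sample, gene) row needs at least one finite Ct replicate")
  }
  if (any(cts[is.finite(cts)] <= 0)) stop("Ct values must be positive")
  if (!all(df$condition %in% c("ctrl", "case"))) {
    stop("condition must be 'ctrl' or 'case'")
  }
  samples <- unique(df$sample_id)
  has_ref <- vapply(samples, function(s) {
    any(df$sample_id == s & df$gene_id == reference)
  }, logical(1))
  if (!all(has_ref)) {
    stop("reference gene '", reference, "' not measured in sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  }
  attr(df, "reference") <- reference
  class(df) <- c("CtTable", "data.frame")
  df
}

#' Relative expression from mean Ct values
#'
#' Target abundance normalized to the reference gene within a sample:
#' 2^-Ct(target) / 2^-Ct(reference) = 2^(Ct(reference) - Ct(target)).
#'
#' @param ct_target,ct_reference Mean Ct of target and reference gene
#'   (vectorized).
#' @return Strictly positive relative expression.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(ct_reference - ct_target)
}

mean_ct <- function(table, sample, gene) {
  rows <- table$sample_id == sample & table$gene_id == gene
  if (!any(rows)) return(NA_real_)
  cts <- as.matrix(table[rows, grep("^ct_", names(table)), drop = FALSE])
  mean(cts[is.finite(cts)])
}

#' Condition fold change of a gene from a CtTable
#'
#' Per sample, replicate Cts are averaged and relative expression against the
#' reference gene is computed; the fold change is the ratio of condition
#' means of those per-sample values (case over ctrl). In paired mode
#' (`pair_id` present and `paired = TRUE`) per-pair case/ctrl ratios are
#' averaged instead.
#'
#' @param table A `CtTable`.
#' @param gene Target gene id.
#' @param paired Use clutch pairing via `pair_id` (default FALSE).
#' @return List: `fc`, and `per_sample` data.frame of sample-level relative
#'   expressions (`sample_id`, `condition`, `rel_expr`).
#' @export
fold_change <- function(table, gene, paired = FALSE) {
  stopifnot(inherits(table, "CtTable"))
  reference <- attr(table, "reference")
  rows <- table[table$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("gene '", gene, "' absent from the table")
  samples <- unique(rows$sample_id)
  rel <- vapply(samples, function(s) {
    relative_expression(mean_ct(table, s, gene), mean_ct(table, s, reference))
  }, numeric(1))
  cond <- rows$condition[match(samples, rows$sample_id)]
  per_sample <- data.frame(sample_id = samples, condition = cond,
                           rel_expr = unname(rel), stringsAsFactors = FALSE)
  if (!any(cond == "ctrl") || !any(cond == "case")) {
    stop("gene '", gene, "' must be measured in both conditions")
  }
  if (paired) {
    if (!"pair_id" %in% names(rows)) stop("paired mode needs a pair_id column")
    per_sample$pair_id <- rows$pair_id[match(samples, rows$sample_id)]
    pairs <- unique(per_sample$pair_id)
    ratios <- vapply(pairs, function(p) {
      sub <- per_sample[per_sample$pair_id == p, ]
      mean(sub$rel_expr[sub$condition == "case"]) /
        mean(sub$rel_expr[sub$condition == "ctrl"])
    }, numeric(1))
    fc <- mean(ratios)
  } else {
    fc <- mean(per_sample$rel_expr[cond == "case"]) /
      mean(per_sample$rel_expr[cond == "ctrl"])
  }
  list(fc = fc, per_sample = per_sample)
}
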