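#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics, preserving within-sample ranks.
#' Ties within a column receive the mean of their tied target quantiles.
#'
#' @param mat Genes x samples numeric matrix, >= 2 samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (anyNA(mat)) stop("expression matrix contains NA/NaN")
  if (ncol(mat) < 2) stop("quantile normalization needs >= 2 samples")
  if (nrow(mat) < 1) stop("empty expression matrix")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Estimate the noise level from the density peak of expression values
#'
#' All matrix values are pooled, transformed by log2(1 + x), and a Gaussian
#' kernel-density estimate (Silverman's rule bandwidth, uniform grid) is
#' computed; the noise is the inverse transform of the density argmax. With a
#' low-expression floor shared by many genes, this picks out that floor.
#'
#' @param mat Normalized expression matrix (>= 10 values).
#' @param n_grid Density grid size (default 512).
#' @param bw Bandwidth rule or value passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @return A `NoiseEstimate` list: `value` (expression units), `bandwidth`,
#'   `n_grid`, `scale` ("log2(1+x)"), `degenerate` flag.
#' @export
estimate_noise <- function(mat, n_grid = 512L, bw = "nrd0") {
  x <- as.numeric(mat)
  if (length(x) < 10) stop("need at least 10 expression values")
  if (anyNA(x) || any(x < 0)) stop("expression values must be finite and >= 0")
  y <- log2(1 + x)
  degenerate <- diff(range(y)) == 0
  if (degenerate) {
    warning("all expression values identical; returning that value")
    return(structure(list(value = x[1], bandwidth = NA_real_,
                          n_grid = n_grid, scale = "log2(1+x)",
                          degenerate = TRUE),
                     class = "NoiseEstimate"))
  }
  d <- density(y, bw = bw, n = n_grid)
  peak <- d$x[which.max(d$y)]
  structure(list(value = 2^peak - 1, bandwidth = d$bw, n_grid = n_grid,
                 scale = "log2(1+x)", degenerate = FALSE),
            class = "NoiseEstimate")
}

#' @export
print.NoiseEstimate <- function(x, ...) {
  cat("NoiseEstimate:", format(x$value), "(scale", x$scale,
      if (x$degenerate) ", degenerate density)" else ")", "\n")
  invisible(x)
}

#' Noise-regularized log fold change
#'
#' lgFC = log2((case + noise) / (ctrl + noise)) in the default
#' case-over-control orientation; orientation `"printed"` swaps numerator and
#' denominator (control over case). Adding the noise level to both means
#' keeps low-expression genes away from large fold changes.
#'
#' @param mean_ctrl,mean_case Non-negative group means (vectorized).
#' @param noise Positive noise level (a `NoiseEstimate` or a number).
#' @param log_base Logarithm base (default 2).
#' @param orientation `"case-over-ctrl"` (default) or `"printed"`.
#' @return Numeric vector of regularized log fold changes, finite for all
#'   non-negative means.
#' @export
regularized_fc <- function(mean_ctrl, mean_case, noise, log_base = 2,
                           orientation = c("case-over-ctrl", "printed")) {
  orientation <- match.arg(orientation)
  if (inherits(noise, "NoiseEstimate")) noise <- noise$value
  if (any(!is.finite(noise)) || any(noise <= 0)) {
    stop("noise must be positive and finite")
  }
  if (any(mean_ctrl < 0) || any(mean_case < 0)) {
    stop("group means must be non-negative")
  }
  num <- if (orientation == "case-over-ctrl") mean_case else mean_ctrl
  den <- if (orientation == "case-over-ctrl") mean_ctrl else mean_case
  log((num + noise) / (den + noise), base = log_base)
}

#' Differential expression table of regularized log fold changes
#'
#' Group means are taken on the (normalized) matrix per gene; the ratio of
#' noise-augmented means gives the regularized lgFC. No p-values are
#' computed; ranking is by |lgFC|.
#'
#' @param mat Normalized genes x samples matrix.
#' @param groups Named character vector sample_id -> `"ctrl"` / `"case"`.
#' @param noise Positive noise level or `NoiseEstimate`; `NULL` to estimate
#'   from `mat` with [estimate_noise()].
#' @param orientation Passed to [regularized_fc()].
#' @return A `DETable` data.frame: `gene_id`, `mean_ctrl`, `mean_case`,
#'   `lgFC`, sorted by decreasing |lgFC| (ties by gene_id); the noise used is
#'   attached as attribute `"noise"`.
#' @export
de_table <- function(mat, groups, noise = NULL,
                     orientation = c("case-over-ctrl", "printed")) {
  orientation <- match.arg(orientation)
  if (!all(names(groups) %in% colnames(mat))) {
    stop("groups name samples absent from the matrix")
  }
  ctrl <- names(groups)[groups == "ctrl"]
  case <- names(groups)[groups == "case"]
  if (length(ctrl) == 0 || length(case) == 0) {
    stop("both conditions need at least one sample")
  }
  if (is.null(noise)) noise <- estimate_noise(mat)
  noise_val <- if (inherits(noise, "NoiseEstimate")) noise$value else noise
  m_ctrl <- rowMeans(mat[, ctrl, drop = FALSE])
  m_case <- rowMeans(mat[, case, drop = FALSE])
  lgfc <- regularized_fc(m_ctrl, m_case, noise_val, orientation = orientation)
  tab <- data.frame(gene_id = rownames(mat), mean_ctrl = m_ctrl,
                    mean_case = m_case, lgFC = lgfc,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-abs(tab$lgFC), tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "noise") <- noise
  attr(tab, "orientation") <- orientation
  class(tab) <- c("DETable", "data.frame")
  tab
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' Pairwise Pearson correlation of log2(1 + x) expression columns. Exclusion
#' is greedy and iterative: while some retained sample's mean correlation to
#' the other retained samples is below the threshold, the worst such sample
#' is excluded and the means are recomputed. One discordant sample therefore
#' cannot drag a clean replicate set below the cutoff. Never excludes so
#' many samples that fewer than 2 remain; with fewer than 3 samples the
#' screen is not applicable and nothing is flagged.
#'
#' @param mat Genes x samples matrix.
#' @param threshold Mean-correlation cutoff (default 0.8).
#' @return An `OutlierReport` data.frame: `sample_id`, `mean_cor` (mean
#'   correlation to the retained samples at the final/exclusion step),
#'   `excluded`; attributes `threshold` and `note`.
#' @export
detect_outliers <- function(mat, threshold = 0.8) {
  ids <- colnames(mat)
  note <- NA_character_
  if (ncol(mat) < 3) {
    rep_df <- data.frame(sample_id = ids,
                         mean_cor = rep(NA_real_, ncol(mat)),
                         excluded = FALSE, stringsAsFactors = FALSE)
    note <- "fewer than 3 samples: outlier screen not applicable"
  } else {
    cc <- suppressWarnings(cor(log2(1 + mat), method = "pearson"))
    cc[is.na(cc)] <- 0
    diag(cc) <- NA
    keep <- seq_along(ids)
    mean_cor <- rep(NA_real_, length(ids))
    repeat {
      mc <- rowMeans(cc[keep, keep, drop = FALSE], na.rm = TRUE)
      mean_cor[keep] <- mc
      worst <- which.min(mc)
      if (mc[worst] >= threshold || length(keep) <= 2) {
        if (length(keep) == 2 && length(ids) > 2 && any(mc < threshold)) {
          note <- "exclusion capped to retain 2 samples"
        }
        break
      }
      keep <- keep[-worst]
    }
    excluded <- !(seq_along(ids) %in% keep)
    rep_df <- data.frame(sample_id = ids, mean_cor = mean_cor,
                         excluded = excluded, stringsAsFactors = FALSE)
  }
  attr(rep_df, "threshold") <- threshold
  attr(rep_df, "note") <- note
  class(rep_df) <- c("OutlierReport", "data.frame")
  rep_df
}

#' Standardize fold changes for a heat-map panel
#'
#' Clips lgFC values to `[-clip, clip]` (the figures use a log2 scale in the
#' range -1.5 to 1.5) and orders rows by the panel gene list. Panel genes
#' absent from the table are reported via the `"missing"` attribute and a
#' warning, never silently dropped.
#'
#' @param table A `DETable` (or data.frame with `gene_id` and `lgFC`).
#' @param panel Character vector of gene ids, in display order.
#' @param clip Clipping bound (default 1.5).
#' @return data.frame `gene_id`, `lgFC` (clipped), rows in panel order;
#'   attribute `"missing"` lists absent panel genes.
#' @export
standardize_for_heatmap <- function(table, panel, clip = 1.5) {
  if (length(panel) == 0) stop("empty panel")
  found <- panel[panel %in% table$gene_id]
  missing <- setdiff(panel, table$gene_id)
  if (length(missing)) {
    warning("panel genes absent from table: ", paste(missing, collapse = ", "))
  }
  idx <- match(found, table$gene_id)
  out <- data.frame(gene_id = found,
                    lgFC = pmin(pmax(table$lgFC[idx], -clip), clip),
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- missing
  attr(out, "clip") <- clip
  out
}

#' Render a standardized panel as a heat map
#'
#' Convenience wrapper around pheatmap for one- or multi-contrast panels;
#' figure output is cosmetic and never load-bearing.
#'
#' @param panel_mat Matrix of clipped lgFC values (genes x contrasts).
#' @param path Optional PNG path; `NULL` draws to the active device.
#' @param clip Color range bound (default 1.5).
#' @export
plot_heatmap <- function(panel_mat, path = NULL, clip = 1.5) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_heatmap requires the pheatmap package")
  }
  cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  brk <- seq(-clip, clip, length.out = 102)
  if (!is.null(path)) {
    pheatmap::pheatmap(panel_mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = cols, breaks = brk, filename = path)
  } else {
    pheatmap::pheatmap(panel_mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = cols, breaks = brk)
  }
  invisible(panel_mat)
}
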