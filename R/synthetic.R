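#' Simulation configuration
#'
#' Defaults describe the study design the pipeline targets: a two-condition
#' morpholino experiment (control vs knockdown) read out with 100-nt
#' single-end reads at ~30x coverage, 3 replicates per condition, 200 genes
#' of which 20 carry planted log2 fold changes of +/-2 at high expression,
#' and a cohort of genes sitting at a shared low-expression noise floor that
#' the density-peak noise estimator must find.
#'
#' @param seed Integer seed; every simulator output is a pure function of
#'   (config, seed).
#' @param n_genes Number of genes (default 200).
#' @param gene_length Min/max gene length in bp (default 500-800).
#' @param read_length Read length (default 100 nt; must satisfy the mapper
#'   geometry (L-4) divisible by 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline expression weight (defaults log(50), 1.2 — a few
#'   orders of magnitude of dynamic range, as in real transcriptomes).
#' @param n_de Number of DE genes with planted effects (default 20, half up
#'   half down), drawn from the upper-middle of the baseline distribution
#'   (60th-90th percentile of non-floor genes): well above the noise floor
#'   but inside the expression continuum, so rank-based normalization keeps
#'   its anchor genes above and below them.
#' @param de_log2fc Magnitude of planted log2 fold changes (default 2).
#' @param noise_floor_frac Fraction of genes at the shared low floor
#'   (default 0.3).
#' @param noise_floor_level Floor expression weight (default 5, i.e. 10% of
#'   the median baseline): low but nonzero, so the floor shows up as a
#'   distinct peak in the pooled expression density.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param depth Target mean raw read depth over gene bases (default 30).
#' @param n_replicates Replicates per condition (default 3).
#' @param qpcr_sd Replicate Ct standard deviation in cycles (default 0.2).
#' @param qpcr_offset Ct of a unit-expression transcript (default 30).
#' @param reference_gene qPCR reference gene id (default "rpp0").
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_genes = 200L,
                       gene_length = c(500L, 800L),
                       read_length = 100L,
                       baseline_meanlog = log(50),
                       baseline_sdlog = 1.2,
                       n_de = 20L,
                       de_log2fc = 2,
                       noise_floor_frac = 0.3,
                       noise_floor_level = 5,
                       error_rate = 0,
                       depth = 30,
                       n_replicates = 3L,
                       qpcr_sd = 0.2,
                       qpcr_offset = 30,
                       reference_gene = "rpp0") {
  stopifnot(length(seed) == 1, is.finite(seed))
  if ((read_length - 4) %% 3 != 0) {
    stop("read_length must satisfy (L - 4) divisible by 3")
  }
  stopifnot(error_rate >= 0, error_rate <= 1,
            noise_floor_frac >= 0, noise_floor_frac <= 1,
            gene_length[1] >= read_length)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy reference, annotation and gene-level ground truth
#'
#' Genes are laid out non-overlapping on one synthetic chromosome with
#' spacer gaps, i.i.d.-uniform base composition. In repeat-free mode the
#' sequence is rejected (and redrawn) until every 32-mer is unique, so exact
#' full-span search has a single answer per planted read.
#'
#' @param config A [sim_config()].
#' @param repeat_free Guarantee unique 32-mers (default TRUE).
#' @return List: `refs` (`ReferenceSet`), `annot` (`Annotation`), `truth`
#'   (data.frame gene_id, seq_id, start, end, baseline, log2fc).
#' @export
simulate_reference <- function(config, repeat_free = TRUE) {
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(seq(config$gene_length[1], config$gene_length[2]), n,
                 replace = TRUE)
  gap <- 50L
  total <- sum(lens) + gap * (n + 1)
  for (attempt in 1:20) {
    seq <- random_dna(total)
    if (!repeat_free) break
    k <- 32L
    kmers <- substring(seq, 1:(total - k + 1), k:total)
    if (!anyDuplicated(kmers)) break
    if (attempt == 20) stop("could not build a repeat-free reference")
  }
  starts <- gap + cumsum(c(0L, head(lens + gap, -1L)))
  gene_ids <- sprintf("gene%03d", seq_len(n))
  annot <- annotation(data.frame(seq_id = "chrS", start = starts,
                                 end = starts + lens, gene_id = gene_ids,
                                 stringsAsFactors = FALSE))
  n_floor <- round(config$noise_floor_frac * n)
  floor_idx <- sample(n, n_floor)
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  baseline[floor_idx] <- config$noise_floor_level
  log2fc <- numeric(n)
  nonfloor <- setdiff(order(baseline, decreasing = TRUE), floor_idx)
  # upper-middle band: high expression without occupying the extreme tail,
  # where rank-based (quantile) normalization has no anchor genes left;
  # widened downward when the gene panel is too small to hold n_de genes
  lo <- ceiling(0.10 * length(nonfloor))
  hi <- max(floor(0.40 * length(nonfloor)), lo + config$n_de - 1L)
  band <- nonfloor[seq(lo, min(hi, length(nonfloor)))]
  de_idx <- sample(band, min(config$n_de, length(band)))
  if (length(de_idx)) {
    half <- ceiling(length(de_idx) / 2)
    log2fc[de_idx[seq_len(half)]] <- config$de_log2fc
    log2fc[de_idx[-seq_len(half)]] <- -config$de_log2fc
  }
  truth <- data.frame(gene_id = gene_ids, seq_id = "chrS", start = starts,
                      end = starts + lens, baseline = baseline,
                      log2fc = log2fc, stringsAsFactors = FALSE)
  list(refs = reference_set(c(chrS = seq)), annot = annot, truth = truth)
}

#' Simulate one sample's reads
#'
#' Read counts per gene are multinomial over expression-weighted gene
#' lengths (case condition multiplies the baseline by 2^log2fc); start
#' positions are uniform within the gene, strand uniform, substitution
#' errors i.i.d. at the configured rate, qualities constant.
#'
#' @param sim Output of [simulate_reference()].
#' @param condition `"ctrl"` or `"case"`.
#' @param config A [sim_config()].
#' @param sample_id Sample label (used in read ids).
#' @param seed Seed for this sample's draws (derive from `config$seed`).
#' @return List: `reads` (data.frame read_id, sequence, quality) and
#'   `read_truth` (read_id, gene_id, start global 0-based, strand).
#' @export
simulate_reads <- function(sim, condition = c("ctrl", "case"), config,
                           sample_id = condition, seed = config$seed) {
  condition <- match.arg(condition)
  set.seed(seed)
  truth <- sim$truth
  L <- config$read_length
  if (any(truth$end - truth$start < L)) {
    stop("every gene must be at least one read length long")
  }
  expr <- truth$baseline * if (condition == "case") 2^truth$log2fc else 1
  w <- expr * (truth$end - truth$start)
  n_reads <- round(config$depth * sum(truth$end - truth$start) / L)
  counts <- as.integer(stats::rmultinom(1, n_reads, w / sum(w)))
  gene_of <- rep.int(seq_len(nrow(truth)), counts)
  offmax <- (truth$end - truth$start - L)[gene_of]
  start <- truth$start[gene_of] +
    floor(runif(length(gene_of)) * (offmax + 1))
  strand <- ifelse(runif(length(gene_of)) < 0.5, "+", "-")
  chr <- sim$refs[["chrS"]]
  seqs <- substring(chr, start + 1L, start + L)
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  if (config$error_rate > 0 && length(seqs)) {
    mat <- matrix(unlist(strsplit(seqs, "")), nrow = L)
    hit <- which(matrix(runif(length(mat)) < config$error_rate, nrow = L))
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      for (i in hit) {
        mat[i] <- sample(setdiff(bases, mat[i]), 1)
      }
    }
    seqs <- apply(mat, 2, paste, collapse = "")
  }
  ids <- sprintf("%s_r%06d", sample_id, seq_along(seqs))
  list(reads = data.frame(read_id = ids, sequence = seqs,
                          quality = strrep("I", L), stringsAsFactors = FALSE),
       read_truth = data.frame(read_id = ids,
                               gene_id = truth$gene_id[gene_of],
                               start = start, strand = strand,
                               stringsAsFactors = FALSE))
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  lines <- rbind(paste0("@", reads$read_id), reads$sequence, "+",
                 reads$quality)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Simulate a qPCR plate from gene-level ground truth
#'
#' Ct = offset - log2(true expression) + Normal(0, replicate sd), in
#' triplicate, for each queried gene in both conditions; the reference gene
#' is simulated with fold change 1.
#'
#' @param truth Gene-level truth (from [simulate_reference()]).
#' @param genes Target gene ids to assay.
#' @param config A [sim_config()].
#' @param n_per_group Samples per condition (default 6).
#' @param seed Seed for the Ct noise.
#' @return A `CtTable` with triplicate columns `ct_1..ct_3` and `pair_id`.
#' @export
simulate_qpcr <- function(truth, genes, config, n_per_group = 6L,
                          seed = config$seed) {
  set.seed(seed)
  stopifnot(all(genes %in% truth$gene_id))
  ref_expr <- 100  # reference gene abundance, identical in both conditions
  rows <- list()
  for (cond in c("ctrl", "case")) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%d", cond, i)
      assay <- c(setNames(ref_expr, config$reference_gene),
                 setNames(truth$baseline[match(genes, truth$gene_id)] *
                            if (cond == "case")
                              2^truth$log2fc[match(genes, truth$gene_id)]
                            else 1,
                          genes))
      ct0 <- config$qpcr_offset - log2(assay)
      reps <- matrix(rnorm(3 * length(ct0), 0, config$qpcr_sd), ncol = 3)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, condition = cond, pair_id = sprintf("pair_%d", i),
        gene_id = names(assay),
        ct_1 = ct0 + reps[, 1], ct_2 = ct0 + reps[, 2],
        ct_3 = ct0 + reps[, 3], stringsAsFactors = FALSE)
    }
  }
  ct_table(do.call(rbind, rows), config$reference_gene)
}
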