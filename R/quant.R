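#' Read a BED annotation
#'
#' 4+ column BED (chrom, start, end, name). Intervals are kept 0-based
#' half-open, matching BED itself. A gene may own several intervals
#' (multi-exon); its expression is then summarized over the concatenated
#' bases.
#'
#' @param path BED file path.
#' @return An `Annotation` data.frame: `seq_id`, `start`, `end`, `gene_id`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  annotation(data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to BED 0-based half-open
    end = GenomicRanges::end(gr),
    gene_id = gr$name,
    stringsAsFactors = FALSE))
}

#' Construct/validate an Annotation
#'
#' @param df data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and `gene_id`.
#' @return The validated data.frame with class `"Annotation"`.
#' @export
annotation <- function(df) {
  stopifnot(all(c("seq_id", "start", "end", "gene_id") %in% names(df)))
  if (any(!nzchar(df$gene_id)) || anyNA(df$gene_id)) {
    stop("every annotation interval needs a non-empty gene_id")
  }
  if (any(df$start < 0) || any(df$end <= df$start)) {
    stop("annotation intervals must satisfy 0 <= start < end")
  }
  class(df) <- c("Annotation", "data.frame")
  df
}

#' Accumulate per-base coverage from placements
#'
#' Every `unique` placement (and, under the keep-first multi policy, every
#' `multi` placement that carries coordinates) adds depth 1 over its full
#' trimmed span `[start, start + trimmed_len)`; other statuses contribute
#' nothing.
#'
#' @param placements Placement data.frame.
#' @param refs `ReferenceSet` (defines sequence universe and lengths).
#' @param trimmed_len Trimmed span length in bp (3k; 96 for 100-nt reads).
#' @return A `CoverageTrack`: named list of integer depth vectors, one per
#'   reference sequence, each of the sequence's length.
#' @export
accumulate_coverage <- function(placements, refs, trimmed_len = 96L) {
  lens <- setNames(nchar(refs), names(refs))
  used <- placements[!is.na(placements$start), , drop = FALSE]
  bad <- !(used$seq_id %in% names(refs))
  if (any(bad)) stop("placement on unknown sequence: ", used$seq_id[which(bad)[1]])
  if (any(used$start < 0 | used$start + trimmed_len > lens[used$seq_id])) {
    stop("placement coordinates outside sequence bounds")
  }
  out <- lapply(names(refs), function(sid) {
    p <- used[used$seq_id == sid, , drop = FALSE]
    if (nrow(p) == 0) return(integer(lens[[sid]]))
    ir <- IRanges::IRanges(start = p$start + 1L, width = trimmed_len)
    as.integer(IRanges::coverage(ir, width = lens[[sid]]))
  })
  structure(setNames(out, names(refs)), class = "CoverageTrack")
}

#' Median-coverage gene expression
#'
#' Expression of a gene is the median of the depth values at every base of
#' its interval(s); an even number of bases takes the mean of the two central
#' values ([stats::median()]'s rule).
#'
#' @param coverage A `CoverageTrack`.
#' @param annot An `Annotation`.
#' @return Named numeric vector of per-gene expression, one entry per gene in
#'   annotation order (first appearance for multi-interval genes).
#' @export
gene_expression <- function(coverage, annot) {
  stopifnot(inherits(annot, "Annotation"))
  for (i in seq_len(nrow(annot))) {
    sid <- annot$seq_id[i]
    if (!sid %in% names(coverage)) stop("annotation on unknown sequence: ", sid)
    if (annot$end[i] > length(coverage[[sid]])) {
      stop("annotation interval out of bounds for gene ", annot$gene_id[i])
    }
  }
  genes <- unique(annot$gene_id)
  vapply(genes, function(g) {
    rows <- which(annot$gene_id == g)
    depths <- unlist(lapply(rows, function(i) {
      coverage[[annot$seq_id[i]]][(annot$start[i] + 1L):annot$end[i]]
    }), use.names = FALSE)
    if (length(depths) == 0) stop("gene ", g, " has a zero-length footprint")
    median(as.numeric(depths))
  }, numeric(1))
}

#' Assemble an expression matrix from per-sample expression vectors
#'
#' @param samples Named list: sample_id -> named expression vector over a
#'   common gene set.
#' @param annot `Annotation` fixing the row (gene) order.
#' @return Genes x samples numeric matrix with dimnames.
#' @export
build_matrix <- function(samples, annot) {
  if (length(samples) == 0) stop("no samples given")
  ids <- names(samples)
  if (is.null(ids) || anyDuplicated(ids)) stop("sample ids must be unique")
  genes <- unique(annot$gene_id)
  mat <- vapply(samples, function(v) {
    if (!all(genes %in% names(v))) {
      stop("sample missing genes: ",
           paste(setdiff(genes, names(v))[1:3], collapse = ", "))
    }
    as.numeric(v[genes])
  }, numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, ids))
  mat
}

#' Write / read an expression matrix as headered TSV
#'
#' @param mat Genes x samples matrix.
#' @param path TSV path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Export a CoverageTrack as bedGraph
#'
#' @param coverage A `CoverageTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sid in names(coverage)) {
    r <- rle(coverage[[sid]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", sid, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
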