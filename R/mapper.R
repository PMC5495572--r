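#' Mapping configuration
#'
#' @param min_part Minimum allowed part length after trimming and splitting
#'   (default 20 nt); shorter parts make spurious exact hits likely.
#' @param multi Policy for reads whose three parts place consistently at more
#'   than one locus: `"drop"` (default; excluded from coverage) or
#'   `"keep-first"` (first locus in reference order is retained).
#' @return A list of class `"map_config"`.
#' @export
map_config <- function(min_part = 20L, multi = c("drop", "keep-first")) {
  multi <- match.arg(multi)
  stopifnot(min_part >= 1)
  structure(list(min_part = as.integer(min_part), multi = multi),
            class = "map_config")
}

#' Trim and split a read into three equal parts
#'
#' The canonical geometry: 2 nt are trimmed from each end and the remainder is
#' split into three equal parts, so a 100-nt read yields three 32-mers at read
#' offsets 2, 34 and 66 (0-based).
#'
#' @param sequence Read sequence.
#' @param config A [map_config()].
#' @return List with `parts` (three strings of equal length `k`), `k`, and
#'   `offsets_in_read` (0-based offsets 2, 2+k, 2+2k).
#' @export
split_read <- function(sequence, config = map_config()) {
  L <- nchar(sequence)
  if (L < 4 || (L - 4) %% 3 != 0) {
    stop("read length ", L, " violates the split geometry: ",
         "(length - 4) must be divisible by 3")
  }
  k <- (L - 4L) %/% 3L
  if (k < config$min_part) {
    stop("read length ", L, " gives part length ", k,
         " below min_part = ", config$min_part)
  }
  offs <- c(2L, 2L + k, 2L + 2L * k)
  parts <- substring(sequence, offs + 1L, offs + k)
  list(parts = parts, k = k, offsets_in_read = offs)
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences (A,C,G,T,N).
#' @return Reverse complement of each element.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Place a single read by exact matching of its three parts
#'
#' All three parts must hit the same sequence on the same strand at exact
#' spacing `k`. Exactly one such locus genome-wide gives status `unique`;
#' more than one `multi`; parts that all hit somewhere but never collinearly
#' `discordant`; any part with zero hits on both strands `unmapped`.
#'
#' @param index A `SuffixIndex`.
#' @param sequence Read sequence (a `ReadRecord`'s sequence; qualities are
#'   ignored by the exact-match method).
#' @param read_id Read identifier carried into the result.
#' @param config A [map_config()].
#' @return A one-row data.frame: `read_id`, `seq_id`, `start` (0-based start
#'   of the trimmed span), `strand`, `status`.
#' @export
place_read <- function(index, sequence, read_id = "read", config = map_config()) {
  res <- map_reads_cpp(index$text, index$suffix_table, sequence,
                       config$min_part, config$multi == "keep-first")
  placement_frame(index, read_id, res)
}

status_levels <- c("unique", "multi", "unmapped", "discordant",
                   "geometry_skipped")

placement_frame <- function(index, read_ids, res) {
  status <- status_levels[res$status + 1L]
  seq_id <- rep(NA_character_, length(status))
  pos <- rep(NA_integer_, length(status))
  has_pos <- !is.na(res$start)
  if (any(has_pos)) {
    loc <- offsets_to_local(index, res$start[has_pos])
    seq_id[has_pos] <- loc$seq_id
    pos[has_pos] <- loc$pos
  }
  data.frame(read_id = read_ids, seq_id = seq_id, start = pos,
             strand = as.character(res$strand), status = status,
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records; Phred+33 qualities if present).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (near record ",
         length(lines) %/% 4 + 1, ")")
  }
  idx <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[idx], "@") | !startsWith(lines[idx + 2], "+"))
  if (length(bad)) stop("malformed FASTQ record at index ", bad[1])
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  badlen <- which(nchar(quals) != nchar(seqs))
  if (length(badlen)) {
    stop("malformed FASTQ record at index ", badlen[1],
         ": quality length differs from sequence length")
  }
  data.frame(read_id = sub("\\s.*$", "", sub("^@", "", lines[idx])),
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

#' Map a FASTQ file against a suffix-array index
#'
#' Each read is trimmed, split and placed with [place_read()]'s rule; reads
#' violating the split geometry are counted as `geometry_skipped`, not as
#' unmapped.
#'
#' @param index A `SuffixIndex`.
#' @param fastq Path to a FASTQ file, or a data.frame as from [read_fastq()].
#' @param config A [map_config()].
#' @return List with `placements` (one row per read) and `stats`, a named
#'   integer vector `total, unique, multi, unmapped, discordant,
#'   geometry_skipped` whose categories partition `total`.
#' @export
map_fastq <- function(index, fastq, config = map_config()) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq
  if (nrow(reads) == 0) {
    pl <- placement_frame(index, character(),
                          list(status = integer(), start = integer(),
                               strand = character()))
    stats <- setNames(integer(6), c("total", status_levels))
    return(list(placements = pl, stats = stats))
  }
  res <- map_reads_cpp(index$text, index$suffix_table, reads$sequence,
                       config$min_part, config$multi == "keep-first")
  pl <- placement_frame(index, reads$read_id, res)
  counts <- table(factor(pl$status, levels = status_levels))
  stats <- c(total = nrow(pl), setNames(as.integer(counts), status_levels))
  list(placements = pl, stats = stats)
}

#' Write placements as headered TSV
#'
#' @param placements Placement data.frame.
#' @param path Output path.
#' @export
write_placements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read placements written by [write_placements()]
#' @param path TSV path.
#' @return Placement data.frame.
#' @export
read_placements <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(read_id = "character", seq_id = "character",
                            start = "integer", strand = "character",
                            status = "character"))
}

#' Write unique placements as minimal SAM
#'
#' Unique placements only, CIGAR `<trimmed_len>M`, flag 0 (+) or 16 (-).
#' The recorded sequence is the trimmed span on the forward reference strand.
#'
#' @param placements Placement data.frame.
#' @param refs `ReferenceSet` used for the header and trimmed-span length.
#' @param trimmed_len Trimmed span length (3k; 96 for 100-nt reads).
#' @param path Output path.
#' @export
write_sam <- function(placements, refs, trimmed_len, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)), con)
  u <- placements[placements$status == "unique", , drop = FALSE]
  if (nrow(u)) {
    flag <- ifelse(u$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       u$read_id, flag, u$seq_id, u$start + 1L, trimmed_len),
               con)
  }
  invisible(path)
}
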