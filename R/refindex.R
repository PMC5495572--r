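#' Read a reference FASTA into a ReferenceSet
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file into an ordered
#' set of uppercase nucleotide sequences. `U` is converted to `T`; the only
#' bases accepted after normalization are A, C, G, T and N.
#'
#' @param path Path to a FASTA file.
#' @return A `ReferenceSet`: a named character vector of sequences (names are
#'   the sequence ids, file order preserved) with class `"ReferenceSet"`.
#'   `lengths()` on it gives per-sequence lengths in bp.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # BStringSet: permissive parse, so normalization/validation (U -> T,
  # uppercase, alphabet check) is ours and bad codes error instead of being
  # silently dropped
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  reference_set(setNames(as.character(set), ids))
}

#' Construct a ReferenceSet from named sequences
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return A validated `ReferenceSet`.
#' @export
reference_set <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("every reference sequence needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- gsub("U", "T", toupper(sequences), fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,U,N}")
  }
  if (any(!nzchar(seqs))) {
    stop("record '", ids[which(!nzchar(seqs))[1]], "' has an empty sequence")
  }
  structure(setNames(seqs, ids), class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", length(x), "sequence(s),",
      sum(nchar(x)), "bp total\n")
  invisible(x)
}

#' Build a suffix-array index over a ReferenceSet
#'
#' Concatenates all sequences (each followed by a sentinel byte that no query
#' can contain, so matches never cross sequence boundaries) and builds the
#' lexicographically sorted suffix table over all non-sentinel offsets.
#' Construction is deterministic.
#'
#' @param refs A `ReferenceSet`.
#' @return A `SuffixIndex` list: `text`, `suffix_table` (0-based global
#'   offsets), `seq_ids`, `seq_start` (global offset of each sequence),
#'   `seq_len`, and a format `version`.
#' @export
build_index <- function(refs) {
  refs <- reference_set(refs)
  if (sum(nchar(refs)) == 0) stop("total reference length is zero")
  sep <- rawToChar(as.raw(1L))
  text <- paste0(paste0(unname(refs), sep), collapse = "")
  sa <- sa_build_cpp(text)
  lens <- nchar(refs)
  starts <- cumsum(c(0L, head(lens + 1L, -1L)))
  structure(
    list(text = text,
         suffix_table = sa,
         seq_ids = names(refs),
         seq_start = as.integer(starts),
         seq_len = as.integer(lens),
         version = 1L),
    class = "SuffixIndex")
}

#' @export
print.SuffixIndex <- function(x, ...) {
  cat("SuffixIndex over", length(x$seq_ids), "sequence(s),",
      length(x$suffix_table), "indexed positions\n")
  invisible(x)
}

# global 0-based offsets -> data.frame(seq_id, pos) with pos local 0-based
offsets_to_local <- function(index, offsets) {
  i <- findInterval(offsets, index$seq_start)
  data.frame(seq_id = index$seq_ids[i],
             pos = offsets - index$seq_start[i],
             stringsAsFactors = FALSE)
}

#' Find all exact occurrences of a query
#'
#' Binary search on the suffix table. Queries must be non-empty; queries
#' containing any character other than A, C, G, T (including N) match nothing.
#'
#' @param index A `SuffixIndex`.
#' @param query Nucleotide string.
#' @return data.frame with columns `seq_id` and `pos` (0-based), sorted by
#'   reference record order then position; zero rows when absent.
#' @export
find_exact <- function(index, query) {
  stopifnot(inherits(index, "SuffixIndex"))
  if (!is.character(query) || length(query) != 1L || !nzchar(query)) {
    stop("query must be a single non-empty string")
  }
  if (grepl("[^ACGT]", query)) {
    return(data.frame(seq_id = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  hits <- sa_find_cpp(index$text, index$suffix_table, query)
  # drop hits whose span would cross a sentinel (can't happen for ACGT
  # queries, kept as a guard)
  offsets_to_local(index, sort(hits))
}

#' Save / load a SuffixIndex
#'
#' The on-disk format is a versioned JSON blob; loading rejects a mismatched
#' version.
#'
#' @param index A `SuffixIndex`.
#' @param path Destination / source file.
#' @return `load_index` returns the `SuffixIndex`; `save_index` its path,
#'   invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "SuffixIndex"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("index serialization requires the jsonlite package")
  }
  payload <- list(version = index$version,
                  seq_ids = index$seq_ids,
                  seq_len = index$seq_len,
                  text = index$text,
                  suffix_table = index$suffix_table)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("index serialization requires the jsonlite package")
  }
  payload <- jsonlite::fromJSON(path)
  if (is.null(payload$version) || payload$version != 1L) {
    stop("unsupported index version: ", payload$version)
  }
  lens <- as.integer(payload$seq_len)
  structure(
    list(text = payload$text,
         suffix_table = as.integer(payload$suffix_table),
         seq_ids = as.character(payload$seq_ids),
         seq_start = as.integer(cumsum(c(0L, head(lens + 1L, -1L)))),
         seq_len = lens,
         version = 1L),
    class = "SuffixIndex")
}
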