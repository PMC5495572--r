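# Independent oracles and tiny fixture builders shared across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force suffix order of a small string (enumerate + sort)
brute_suffix_order <- function(text) {
  n <- nchar(text)
  suffixes <- substring(text, seq_len(n), n)
  order(suffixes) - 1L  # 0-based offsets in lexicographic order
}

# all exact occurrences of pattern in refs via Biostrings (0-based starts)
oracle_hits <- function(refs, pattern) {
  out <- lapply(names(refs), function(sid) {
    m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(refs[[sid]]))
    if (length(m) == 0) return(NULL)
    data.frame(seq_id = sid, pos = Biostrings::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(seq_id = character(), pos = integer(),
                               stringsAsFactors = FALSE) else out
}

# full-trimmed-span exact search of a read on both strands
oracle_place <- function(refs, sequence) {
  L <- nchar(sequence)
  trimmed <- substr(sequence, 3, L - 2)
  f <- oracle_hits(refs, trimmed)
  r <- oracle_hits(refs, exactseq::revcomp(trimmed))
  n <- nrow(f) + nrow(r)
  if (n == 0) return(list(status = "none"))
  if (n > 1) return(list(status = "multi"))
  if (nrow(f) == 1) {
    list(status = "unique", seq_id = f$seq_id, start = f$pos, strand = "+")
  } else {
    list(status = "unique", seq_id = r$seq_id, start = r$pos, strand = "-")
  }
}

sort_median <- function(x) {
  s <- sort(as.numeric(x))
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# plant a 100-nt read at 0-based position p (trimmed span starts at p + 0
# after trimming the 2-nt flank, i.e. read covers [p - 2, p + 98))
planted_read <- function(seq, trim_start, strand = "+") {
  read <- substr(seq, trim_start - 1, trim_start + 98)  # 2-nt flanks included
  if (strand == "-") read <- exactseq::revcomp(read)
  read
}

write_temp_fasta <- function(records, wrap = 0) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  for (id in names(records)) {
    writeLines(paste0(">", id), con)
    s <- records[[id]]
    if (wrap > 0) {
      starts <- seq(1, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  close(con)
  path
}
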