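test_that("split geometry: 100 nt gives three 32-mers at offsets 2/34/66", {
  set.seed(21)
  read <- rand_dna(100)
  sp <- split_read(read)
  expect_identical(sp$k, 32L)
  expect_identical(sp$offsets_in_read, c(2L, 34L, 66L))
  expect_identical(nchar(sp$parts), rep(32L, 3))
  expect_identical(paste(sp$parts, collapse = ""), substr(read, 3, 98))

  sp94 <- split_read(rand_dna(94))
  expect_identical(sp94$k, 30L)

  expect_error(split_read(rand_dna(10)), "min_part|geometry")
  expect_error(split_read(rand_dna(99)), "divisible")
})

test_that("planted reads place uniquely; any internal mismatch kills the read", {
  set.seed(31)
  chr <- rand_dna(3000)
  refs <- reference_set(c(chr1 = chr))
  idx <- build_index(refs)

  p <- 500L  # trimmed-span start, 0-based
  read <- planted_read(chr, p)
  pl <- place_read(idx, read)
  expect_identical(pl$status, "unique")
  expect_identical(pl$seq_id, "chr1")
  expect_identical(pl$start, p)
  expect_identical(pl$strand, "+")

  # same read from the reverse strand
  plr <- place_read(idx, planted_read(chr, p, strand = "-"))
  expect_identical(plr$status, "unique")
  expect_identical(plr$start, p)
  expect_identical(plr$strand, "-")

  # substitution inside the middle part: all-or-nothing per part
  mid <- read
  pos <- 50L
  substr(mid, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read, pos, pos))[1]
  expect_identical(place_read(idx, mid)$status, "unmapped")

  # mismatches in the 2-nt flanks are trimmed away and tolerated
  flank <- read
  substr(flank, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                 substr(read, 1, 1))[1]
  substr(flank, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read, 100, 100))[1]
  expect_identical(place_read(idx, flank)$status, "unique")
})

test_that("multi and discordant statuses are detected", {
  set.seed(32)
  unit <- rand_dna(120)
  # duplicated locus: the same 120-mer twice
  refs <- reference_set(c(chr1 = paste0(unit, rand_dna(150), unit)))
  idx <- build_index(refs)
  read <- planted_read(refs[["chr1"]], 10L)
  pl <- place_read(idx, read)
  expect_identical(pl$status, "multi")
  expect_true(is.na(pl$start))
  pk <- place_read(idx, read, config = map_config(multi = "keep-first"))
  expect_identical(pk$status, "multi")
  expect_identical(pk$start, 10L)

  # all three parts present but never collinear at spacing k
  read2 <- rand_dna(100)
  sp <- split_read(read2)
  scattered <- paste0(rand_dna(60), sp$parts[1], rand_dna(40), sp$parts[2],
                      rand_dna(40), sp$parts[3], rand_dna(60))
  idx2 <- build_index(reference_set(c(chr1 = scattered)))
  expect_identical(place_read(idx2, read2)$status, "discordant")
})

test_that("strand symmetry: mirroring reads and reference mirrors placements", {
  set.seed(33)
  chr <- rand_dna(2000)
  idx_f <- build_index(reference_set(c(chr1 = chr)))
  idx_r <- build_index(reference_set(c(chr1 = revcomp(chr))))
  L <- 2000L
  trimmed <- 96L
  for (p in c(100L, 777L, 1500L)) {
    read <- planted_read(chr, p)
    a <- place_read(idx_f, read)
    b <- place_read(idx_r, read)
    expect_identical(a$status, "unique")
    expect_identical(b$status, "unique")
    expect_identical(b$start, L - (a$start + trimmed))
    expect_true(a$strand != b$strand)
  }
})

test_that("map_fastq counts partition reads and handle geometry violations", {
  set.seed(34)
  chr <- rand_dna(5000)
  refs <- reference_set(c(chr1 = chr))
  idx <- build_index(refs)
  starts <- seq(10L, 2000L, length.out = 10)
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    sequence = vapply(as.integer(starts), function(p) planted_read(chr, p),
                      character(1)),
    quality = strrep("I", 100), stringsAsFactors = FALSE)
  res <- map_fastq(idx, reads)
  expect_identical(unname(res$stats[c("total", "unique")]), c(10L, 10L))
  expect_identical(sum(res$stats[-1]), res$stats[["total"]])

  # a 10-nt read is geometry_skipped, not unmapped
  short <- rbind(reads, data.frame(read_id = "short", sequence = rand_dna(10),
                                   quality = strrep("I", 10)))
  res2 <- map_fastq(idx, short)
  expect_identical(res2$stats[["geometry_skipped"]], 1L)
  expect_identical(res2$stats[["unmapped"]], 0L)
  expect_identical(res2$placements$status[11], "geometry_skipped")

  # empty FASTQ
  empty <- tempfile(fileext = ".fq")
  file.create(empty)
  res3 <- map_fastq(idx, empty)
  expect_identical(res3$stats[["total"]], 0L)
  expect_identical(nrow(res3$placements), 0L)

  # malformed FASTQ
  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(map_fastq(idx, bad), "malformed")
})

test_that("placements agree with a full-span substring oracle", {
  set.seed(35)
  chr <- rand_dna(10000)
  refs <- reference_set(c(chr1 = chr))
  idx <- build_index(refs)
  starts <- sample(5:9800, 200)
  reads <- data.frame(
    read_id = sprintf("r%03d", seq_along(starts)),
    sequence = vapply(starts, function(p) {
      planted_read(chr, p, strand = sample(c("+", "-"), 1))
    }, character(1)),
    quality = strrep("I", 100), stringsAsFactors = FALSE)
  got <- map_fastq(idx, reads)$placements
  for (i in seq_len(nrow(reads))) {
    want <- oracle_place(refs, reads$sequence[i])
    expect_identical(got$status[i], want$status)
    expect_identical(got$start[i], want$start)
    expect_identical(got$strand[i], want$strand)
  }
})

test_that("placement TSV and SAM outputs round-trip the unique placements", {
  set.seed(36)
  chr <- rand_dna(1000)
  refs <- reference_set(c(chr1 = chr))
  idx <- build_index(refs)
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c(planted_read(chr, 100L),
                                   planted_read(chr, 300L, "-")),
                      quality = strrep("I", 100), stringsAsFactors = FALSE)
  pl <- map_fastq(idx, reads)$placements
  tsv <- tempfile(fileext = ".tsv")
  write_placements(pl, tsv)
  expect_identical(read_placements(tsv), pl)

  sam <- tempfile(fileext = ".sam")
  write_sam(pl, refs, 96L, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_length(body, 2L)
  f <- strsplit(body, "\t")
  expect_identical(vapply(f, `[`, "", 2), c("0", "16"))
  expect_identical(vapply(f, `[`, "", 4), c("101", "301"))  # SAM is 1-based
  expect_identical(vapply(f, `[`, "", 6), c("96M", "96M"))
})
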