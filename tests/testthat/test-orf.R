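# Spliced-sequence extraction, the longest-putative-ORF statistic,
# translation, and the length/ORF filters.

test_that("spliced sequences concatenate exons and honour strand", {
  genome <- c(c1 = "NNATGNNNNNTAANN")
  plus <- tx("p", c(3, 11), c(5, 13))       # "ATG" + "TAA"
  expect_equal(spliced_sequences(plus, genome)$sequence, "ATGTAA")
  minus <- tx("m", c(3, 11), c(5, 13), strand = "-")
  expect_equal(spliced_sequences(minus, genome)$sequence, "TTACAT")

  expect_error(spliced_sequences(tx("z", 1, 5, chrom = "c9"), genome),
               "absent from genome")
  expect_error(spliced_sequences(tx("z", 10, 50), genome), "beyond the end")
  expect_error(spliced_sequences(tx("z", 1, 5, strand = "."), genome),
               "unknown strand")
})

test_that("spliced sequences match per-base extraction on random fixtures", {
  set.seed(61)
  chrom <- random_dna(4000)
  genome <- c(c1 = chrom)
  bases <- strsplit(chrom, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in 1:25) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 3500, by = 120), n_ex))
    ends <- starts + sample(10:100, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    t1 <- tx("t", starts, ends, strand = strand)
    got <- spliced_sequences(t1, genome)$sequence
    per_base <- unlist(mapply(function(s, e) bases[s:e], starts, ends,
                              SIMPLIFY = FALSE))
    want <- if (strand == "-") {
      paste(rev(unname(comp[per_base])), collapse = "")
    } else {
      paste(per_base, collapse = "")
    }
    expect_equal(got, want)
  }
})

test_that("longest ORF handles starts, stops and absent ATG", {
  got <- find_longest_orf("ATGAAATAG")
  expect_equal(got$nt_length, 6L)
  expect_equal(got$aa_length, 2L)
  expect_true(got$has_stop)
  expect_equal(got$start_offset, 0L)

  expect_equal(find_longest_orf("CCCCCCCCCC")$nt_length, 0L)
  # no stop: runs to the last complete codon
  open <- find_longest_orf("ATGAAAAAAAA")
  expect_equal(open$nt_length, 9L)
  expect_false(open$has_stop)
  # N-containing codons are never a start or stop
  expect_equal(find_longest_orf("ATNAAATAG")$nt_length, 0L)
  n_stop <- find_longest_orf("ATGAAATANAAATAG")
  expect_equal(n_stop$nt_length, 12L)
})

test_that("longest ORF equals exhaustive span enumeration", {
  set.seed(71)
  for (i in 1:120) {
    s <- random_dna(sample(50:600, 1),
                    alphabet = c("A", "C", "G", "T",
                                 if (i %% 5 == 0) "N"))
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    expect_equal(got$nt_length, want$nt_length)
    expect_equal(got$nt_length %% 3, 0)
    if (want$nt_length > 0) {
      expect_equal(got$start_offset, want$start_offset)
      expect_equal(got$has_stop, want$has_stop)
    }
  }
})

test_that("ORF length is invariant to bases appended after the stop", {
  set.seed(73)
  for (i in 1:20) {
    s <- plant_orf(300, 150)
    got <- find_longest_orf(s)
    expect_true(got$has_stop)
    appended <- paste0(s, random_dna(sample(1:30, 1), c("C", "G", "T")))
    expect_equal(find_longest_orf(appended)$nt_length, got$nt_length)
  }
})

test_that("minus-strand ORF equals plus-strand ORF of the reverse complement", {
  set.seed(79)
  chrom <- random_dna(2000)
  genome <- c(c1 = chrom)
  for (i in 1:10) {
    starts <- sort(sample(seq(1, 1700, by = 150), 2))
    ends <- starts + sample(60:140, 2)
    seq_minus <- spliced_sequences(tx("t", starts, ends, strand = "-"),
                                   genome)$sequence
    seq_plus <- spliced_sequences(tx("t", starts, ends, strand = "+"),
                                  genome)$sequence
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_plus)))
    expect_equal(seq_minus, rc)
    expect_equal(find_longest_orf(seq_minus)$nt_length,
                 find_longest_orf(rc)$nt_length)
  }
})

test_that("translation follows the standard genetic code, N -> X", {
  expect_equal(translate_orf("ATGTTTTAA", 0, 6), "MF")
  expect_equal(translate_orf("ATGAAACCC", 0, 9), "MKP")
  expect_equal(translate_orf("CCATGTTNTGGTAA", 2, 9), "MXW")
  expect_error(translate_orf("ATG", 0, 0), "zero-length")

  set.seed(83)
  for (i in 1:25) {
    s <- plant_orf(240, 120)
    orf <- find_longest_orf(s)
    got <- translate_orf(s, orf$start_offset, orf$nt_length)
    want <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, orf$start_offset + 1, orf$start_offset + orf$nt_length))))
    expect_equal(got, want)
    expect_equal(nchar(got), orf$aa_length)
  }
})

test_that("length filter is strict at 200 nt", {
  x <- dplyr::bind_rows(
    tx("len200", 1, 200, fpkm = 1),
    tx("len201", 1000, 1200, fpkm = 1)
  )
  got <- unique(extract_length(x)$transcript_id)
  expect_equal(got, "len201")
  expect_equal(nrow(extract_length(x[0, ])), 0)
})

test_that("ORF filter is strict at 300 nt and reports every input", {
  set.seed(89)
  genome_chars <- rep("C", 6000)
  mk <- function(id, at, orf_nt) {
    len <- 600
    s <- plant_orf(len, orf_nt)
    genome_chars[at:(at + len - 1)] <<- strsplit(s, "")[[1]]
    tx(id, at, at + len - 1, fpkm = 1)
  }
  x <- dplyr::bind_rows(
    mk("orf297", 1, 297),
    mk("orf300", 1001, 300),
    mk("orf0", 2001, 0),
    mk("orf402", 3001, 402)
  )
  genome <- c(c1 = paste(genome_chars, collapse = ""))
  got <- extract_orf(x, genome)
  expect_equal(sort(unique(got$transcript_id)), c("orf0", "orf297"))
  rep <- attr(got, "orf_report")
  expect_equal(nrow(rep), 4)
  expect_equal(rep$nt_length[match(c("orf297", "orf300", "orf0", "orf402"),
                                   rep$transcript_id)],
               c(297L, 300L, 0L, 402L))
})
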