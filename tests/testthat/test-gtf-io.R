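# GTF parsing/writing and basic transcript structure statistics.

test_that("read_gtf builds transcripts from exon rows and lifts FPKM", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "# a comment",
    "c1\tasm\ttranscript\t101\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\"; FPKM \"2.12\";",
    "c1\tasm\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\"; FPKM \"2.12\";",
    "c1\tasm\texon\t301\t400\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\"; FPKM \"2.12\";",
    "c1\tasm\texon\t50\t80\t.\t-\t.\tgene_id g2; transcript_id t2; cov 8.1;"
  ), path)
  x <- read_gtf(path)
  s <- transcript_summary(x)
  expect_equal(nrow(s), 2)
  t1 <- s[s$transcript_id == "t1", ]
  expect_equal(t1$n_exons, 2L)
  expect_equal(t1$start, 101L)
  expect_equal(t1$end, 400L)
  expect_equal(t1$fpkm, 2.12)
  # unquoted attributes parse too; unknown attributes survive in `extra`
  t2 <- x[x$transcript_id == "t2", ]
  expect_equal(t2$strand, "-")
  expect_match(t2$extra, "cov 8.1")
})

test_that("malformed GTF input fails loudly with the line number", {
  bad_cols <- withr::local_tempfile(fileext = ".gtf")
  writeLines("c1\tasm\texon\t1\t10", bad_cols)
  expect_error(read_gtf(bad_cols), "line 1.*9 tab-separated")

  bad_coord <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "c1\ta\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "c1\ta\texon\t50\t20\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"
  ), bad_coord)
  expect_error(read_gtf(bad_coord), "line 2.*end.*start")

  non_num <- withr::local_tempfile(fileext = ".gtf")
  writeLines("c1\ta\texon\txx\t10\t.\t+\t.\ttranscript_id \"t\";", non_num)
  expect_error(read_gtf(non_num), "non-numeric")

  dup <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "c1\ta\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
    "c1\ta\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"
  ), dup)
  expect_error(read_gtf(dup), "duplicate exon")
})

test_that("overlapping exons within a transcript are rejected", {
  expect_error(
    as_transcripts(tx("t", c(1, 50), c(100, 120))),
    "overlapping"
  )
  expect_error(
    as_transcripts(tx("t", c(10), c(5))),
    "end < start"
  )
})

test_that("GTF round-trip preserves structures, ids, strand and FPKM", {
  set.seed(11)
  n <- 300
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:5, 1)
    ex_len <- sample(30:400, n_ex, replace = TRUE)
    in_len <- sample(40:900, max(n_ex - 1, 1), replace = TRUE)
    at <- sample(1:1e6, 1)
    starts <- integer(0); ends <- integer(0); pos <- at
    for (k in seq_len(n_ex)) {
      starts <- c(starts, pos); ends <- c(ends, pos + ex_len[k] - 1L)
      pos <- pos + ex_len[k] + (if (k < n_ex) in_len[k] else 0L)
    }
    tx(sprintf("t%04d", i), starts, ends,
       strand = sample(c("+", "-", "."), 1),
       chrom = sample(paste0("chr", 1:4), 1),
       fpkm = round(stats::rlnorm(1, 1, 1.5), 4))
  })
  x <- as_transcripts(dplyr::bind_rows(rows))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(x, path)
  y <- read_gtf(path)
  cols <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand", "fpkm")
  expect_equal(as.data.frame(y[, cols]), as.data.frame(x[, cols]))
})

test_that("an empty collection writes a valid empty GTF", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx("t", 1, 10)[0, ], path)
  expect_true(file.exists(path))
  expect_equal(nrow(read_gtf(path)), 0)
})

test_that("exonic_length sums exon widths, matching a per-base count", {
  expect_equal(exonic_length(tx("t", c(1, 201), c(100, 300)))$exonic_length, 200L)
  expect_equal(exonic_length(tx("t", 5, 5))$exonic_length, 1L)
  set.seed(21)
  for (i in 1:50) {
    n_ex <- sample(1:6, 1)
    starts <- sort(sample(seq(1, 5000, by = 10), n_ex))
    ends <- starts + sample(1:9, n_ex, replace = TRUE) - 1L
    t1 <- tx("t", starts, ends)
    per_base <- length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
    expect_equal(exonic_length(t1)$exonic_length, per_base)
  }
})

test_that("intron chains partition the span together with the exons", {
  ch <- intron_chains(tx("t", c(1, 201), c(100, 300)))
  expect_equal(ch$start, 101L)
  expect_equal(ch$end, 200L)
  ch3 <- intron_chains(tx("t", c(1, 21, 41), c(10, 30, 50)))
  expect_equal(ch3$start, c(11L, 31L))
  expect_equal(ch3$end, c(20L, 40L))
  expect_error(intron_chains(tx("t", 1, 10)), "single-exon")

  set.seed(31)
  for (i in 1:30) {
    n_ex <- sample(2:6, 1)
    starts <- cumsum(sample(50:200, n_ex)) + sample(1:100, 1)
    ends <- starts + sample(10:40, n_ex, replace = TRUE)
    starts[-1] <- pmax(starts[-1], ends[-n_ex] + 2L)  # keep a real gap
    ends <- pmax(ends, starts)
    t1 <- as_transcripts(tx("t", starts, ends))
    ch <- intron_chains(t1)
    span <- max(ends) - min(starts) + 1L
    expect_equal(ch$intron_index, seq_len(n_ex - 1L))
    expect_equal(exonic_length(t1)$exonic_length + sum(ch$end - ch$start + 1L),
                 span)
    # exonic and intronic positions tile the span exactly once
    pos <- c(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE)),
             unlist(mapply(seq, ch$start, ch$end, SIMPLIFY = FALSE)))
    expect_equal(sort(pos), seq(min(starts), max(ends)))
  }
})

test_that("span-overlap prefilter agrees with a linear scan", {
  set.seed(41)
  mk <- function(n) {
    tibble::tibble(
      transcript_id = sprintf("s%04d", seq_len(n)),
      chrom = sample(c("c1", "c2", "c3"), n, replace = TRUE),
      start = sample(1:100000, n, replace = TRUE)
    ) |>
      dplyr::mutate(end = start + sample(10:5000, n, replace = TRUE))
  }
  subj <- mk(400)
  qry <- mk(1000)
  hits <- lncscan:::.span_overlaps(qry, subj)
  got <- sort(paste(hits[, 1], hits[, 2]))
  want <- character(0)
  for (i in seq_len(nrow(qry))) {
    for (j in seq_len(nrow(subj))) {
      if (qry$chrom[i] == subj$chrom[j] &&
          qry$start[i] <= subj$end[j] && subj$start[j] <= qry$end[i]) {
        want <- c(want, paste(i, j))
      }
    }
  }
  expect_equal(got, sort(want))
})

test_that("gtf_stats reports counts and length summaries", {
  x <- dplyr::bind_rows(tx("a", c(1, 301), c(100, 400)),
                        tx("b", 1000, 1050, gene = "g_a"))
  s <- gtf_stats(x)
  expect_equal(s$n_transcripts, 2)
  expect_equal(s$n_exons, 3)
  expect_equal(s$n_multi_exon, 1)
  expect_equal(s$max_length, 200L)
})
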