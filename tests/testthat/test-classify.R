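# Class-code assignment, annotation merging and category extraction.

ref1 <- as_transcripts(dplyr::bind_rows(
  tx("r1", c(101, 501, 901), c(200, 700, 1100), gene = "rg1"),  # 3-exon +
  tx("r2", c(5001, 5501), c(5200, 5700), strand = "-", gene = "rg2")
))

test_that("each class code is assigned per its structural definition", {
  cases <- list(
    # identical intron chain, padded ends -> "="
    list(tx("q", c(81, 501, 901), c(200, 700, 1150)), "="),
    # contiguous sub-chain inside the span -> "c"
    list(tx("q", c(121, 501), c(200, 650)), "c"),
    # one shared junction but an exon outside the span -> "j"
    list(tx("q", c(51, 501), c(200, 560)), "j"),
    # exon overlap, same strand, no shared junction -> "o"
    list(tx("q", c(151, 351), c(250, 420)), "o"),
    # entirely inside the first reference intron, same strand -> "i"
    list(tx("q", c(251, 361), c(320, 430)), "i"),
    # exon overlap on the opposite strand only -> "x"
    list(tx("q", c(151, 351), c(250, 420), strand = "-"), "x"),
    # opposite-strand intron-intron overlap, no exon overlap -> "s"
    list(tx("q", c(251, 361), c(320, 430), strand = "-"), "s"),
    # no reference overlap at all -> "u"
    list(tx("q", c(20001, 20501), c(20100, 20600)), "u")
  )
  for (case in cases) {
    got <- classify_transcripts(case[[1]], ref1)
    expect_equal(got$class_code, case[[2]])
    if (case[[2]] == "u") {
      expect_true(is.na(got$ref_transcript_id))
    } else {
      expect_false(is.na(got$ref_transcript_id))
    }
  }
})

test_that("an empty reference codes everything intergenic", {
  got <- classify_transcripts(tx("q", c(1, 101), c(50, 150)), ref1[0, ])
  expect_equal(got$class_code, "u")
})

test_that("complete match is symmetric in structure", {
  q <- tx("q", c(81, 501, 901), c(200, 700, 1150))
  expect_equal(classify_transcripts(q, ref1)$class_code, "=")
  r1_only <- ref1[ref1$transcript_id == "r1", ]
  expect_equal(classify_transcripts(r1_only, q)$class_code, "=")
})

test_that("unknown-strand queries get overlap codes but never '='/'j'", {
  q_eq <- tx("q", c(81, 501, 901), c(200, 700, 1150), strand = ".")
  got <- classify_transcripts(q_eq, ref1)
  expect_false(got$class_code %in% c("=", "j"))
  expect_true(got$strand_unknown)
  q_ov <- tx("q", c(151, 351), c(250, 420), strand = ".")
  expect_equal(classify_transcripts(q_ov, ref1)$class_code, "o")
})

test_that("indexed classifier equals the brute-force all-pairs ladder", {
  sets <- random_transcript_set(n_query = 300, n_ref = 40, seed = 99)
  got <- classify_transcripts(sets$query, sets$reference)
  got <- got[match(sort(got$transcript_id), got$transcript_id), ]
  want <- oracle_classify(sets$query, sets$reference)
  expect_equal(got$class_code, want$class_code)
  expect_equal(got$ref_transcript_id, want$ref_transcript_id)
  # every transcript received exactly one code
  expect_equal(nrow(got), length(unique(sets$query$transcript_id)))
  # no "u" transcript has exonic overlap with any reference exon
  r_ex <- sets$reference
  for (tid in got$transcript_id[got$class_code == "u"]) {
    q_ex <- sets$query[sets$query$transcript_id == tid, ]
    ov <- any(vapply(seq_len(nrow(q_ex)), function(k)
      any(r_ex$chrom == q_ex$chrom[k] & r_ex$start <= q_ex$end[k] &
            r_ex$end >= q_ex$start[k]), logical(1)))
    expect_false(ov)
  }
})

test_that("merge_annotations deduplicates by structure, keeping first ids", {
  a <- dplyr::bind_rows(
    tx("a1", c(101, 501), c(200, 700), gene = "ga1"),
    tx("a2", 900, 1000, gene = "ga2")
  )
  # same intron chain as a1 with padded ends; same exon interval as a2
  b <- dplyr::bind_rows(
    tx("b1", c(81, 501), c(200, 750), gene = "gb1"),
    tx("b2", 900, 1000, gene = "gb2"),
    tx("b3", c(2001, 2501), c(2100, 2600), gene = "gb3")
  )
  m <- merge_annotations(a, b)
  s <- transcript_summary(m)
  expect_equal(sort(s$transcript_id), c("a1", "a2", "b3"))

  # disjoint sets just concatenate
  m2 <- merge_annotations(a, tx("z", c(9001, 9501), c(9100, 9600)))
  expect_equal(nrow(transcript_summary(m2)), 3)
})

test_that("merge_annotations matches a pairwise structural dedup oracle", {
  set.seed(7)
  base <- random_transcript_set(n_query = 0, n_ref = 30, seed = 5)$reference
  # plant duplicates: copies with padded outer exons under new ids
  s <- transcript_summary(base)
  dup_ids <- sample(s$transcript_id, 10)
  dups <- dplyr::bind_rows(lapply(seq_along(dup_ids), function(k) {
    d <- base[base$transcript_id == dup_ids[k], ]
    d$transcript_id <- sprintf("D%02d", k)
    d$start[1] <- max(1L, d$start[1] - sample(1:20, 1))
    d$end[nrow(d)] <- d$end[nrow(d)] + sample(1:20, 1)
    d
  }))
  m <- merge_annotations(base, dups)
  # O(n^2) oracle: count structurally distinct transcripts
  all_t <- c(split(base, base$transcript_id), split(dups, dups$transcript_id))
  key <- vapply(all_t, function(e) {
    e <- e[order(e$start), ]
    n <- nrow(e)
    if (n > 1) {
      paste(e$chrom[1], e$strand[1],
            paste(e$end[-n] + 1L, e$start[-1] - 1L, collapse = ";"))
    } else {
      paste(e$chrom[1], e$strand[1], e$start, e$end)
    }
  }, character(1))
  expect_equal(nrow(transcript_summary(m)), length(unique(key)))
})

test_that("extract_category keeps exactly the wanted codes", {
  cls <- tibble::tibble(
    transcript_id = sprintf("t%d", 1:7),
    class_code = c("=", "=", "=", "c", "j", "j", "u")
  )
  x <- dplyr::bind_rows(lapply(1:7, function(i)
    tx(sprintf("t%d", i), i * 1000, i * 1000 + 100)))
  got <- extract_category(x, cls)
  expect_equal(sort(unique(got$transcript_id)), c("t5", "t6", "t7"))
  expect_equal(nrow(extract_category(x, cls, wanted = character(0))), 0)
  expect_equal(sort(unique(extract_category(x, cls, wanted = "=")$transcript_id)),
               c("t1", "t2", "t3"))
})

test_that("categorize_summary reproduces planted count shares", {
  counts <- c(j = 180, i = 26, o = 44, u = 52, x = 6)
  cls <- tibble::tibble(
    transcript_id = sprintf("t%d", seq_len(sum(counts))),
    class_code = rep(names(counts), counts)
  )
  tab <- categorize_summary(cls)
  expect_equal(sum(tab$n), 308)
  expect_equal(round(tab$percentage[match(c("j", "i", "o", "u", "x"),
                                          tab$class_code)], 2),
               c(58.44, 8.44, 14.29, 16.88, 1.95))
  expect_equal(sum(tab$percentage), 100)
  # single transcript -> 100%
  one <- categorize_summary(tibble::tibble(transcript_id = "t", class_code = "u"))
  expect_equal(one$percentage, 100)
})
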