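# Independent oracles: deliberately simple, index-free reimplementations of
# the statistics under test, used only to verify the package's fast paths.

# --- quick exon-table constructor ------------------------------------------

tx <- function(id, starts, ends, strand = "+", chrom = "c1", gene = NULL,
               fpkm = NA_real_) {
  tibble::tibble(
    transcript_id = id, gene_id = gene %||% paste0("g_", id), chrom = chrom,
    start = as.integer(starts), end = as.integer(ends), strand = strand,
    fpkm = fpkm
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force all-pairs class-code classifier ---------------------------
# Evaluates every (query, reference) pair against the documented precedence
# ladder with plain loops and no interval index.

.orc_prep <- function(df) {
  df <- df[order(df$transcript_id, df$start), ]
  lapply(split(df, df$transcript_id), function(e) {
    n <- nrow(e)
    list(id = e$transcript_id[1], chrom = e$chrom[1], strand = e$strand[1],
         ex = cbind(e$start, e$end),
         int = if (n > 1) cbind(e$end[-n] + 1L, e$start[-1] - 1L) else
           matrix(integer(0), ncol = 2),
         span = c(min(e$start), max(e$end)))
  })
}

.orc_any_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a[i, 1] <= b[j, 2] && b[j, 1] <= a[i, 2]) return(TRUE)
    }
  }
  FALSE
}

.orc_chain_str <- function(m) paste(m[, 1], m[, 2], collapse = ";")

.orc_subchain <- function(qm, rm) {
  nq <- nrow(qm); nr <- nrow(rm)
  if (nq == 0) return(TRUE)
  if (nq > nr) return(FALSE)
  for (s in seq_len(nr - nq + 1)) {
    if (identical(qm[, , drop = FALSE], rm[s:(s + nq - 1), , drop = FALSE])) {
      return(TRUE)
    }
  }
  FALSE
}

.orc_pair <- function(q, r) {
  if (q$chrom != r$chrom) return(NA_character_)
  same <- q$strand != "." && q$strand == r$strand
  opp <- q$strand %in% c("+", "-") && r$strand %in% c("+", "-") &&
    q$strand != r$strand
  loose <- same || q$strand == "." || r$strand == "."
  qm <- nrow(q$int) > 0; rm_ <- nrow(r$int) > 0

  if (same && qm && rm_ &&
      .orc_chain_str(q$int) == .orc_chain_str(r$int)) return("=")
  if (loose && q$span[1] >= r$span[1] && q$span[2] <= r$span[2] &&
      .orc_subchain(q$int, r$int) &&
      !(qm && .orc_chain_str(q$int) == .orc_chain_str(r$int)) &&
      (qm || .orc_any_overlap(q$ex, r$ex))) return("c")
  if (same && qm && rm_) {
    qj <- paste(q$int[, 1], q$int[, 2])
    rj <- paste(r$int[, 1], r$int[, 2])
    if (any(qj %in% rj)) return("j")
  }
  if (loose && .orc_any_overlap(q$ex, r$ex)) return("o")
  if (loose && rm_) {
    for (k in seq_len(nrow(r$int))) {
      if (r$int[k, 1] <= q$span[1] && r$int[k, 2] >= q$span[2]) return("i")
    }
  }
  if (opp && .orc_any_overlap(q$ex, r$ex)) return("x")
  if (opp && qm && rm_ && .orc_any_overlap(q$int, r$int) &&
      !.orc_any_overlap(q$ex, r$ex)) return("s")
  NA_character_
}

oracle_classify <- function(query, reference) {
  qs <- .orc_prep(query)
  rs <- .orc_prep(reference)
  prio <- c("=", "c", "j", "o", "i", "x", "s")
  out <- data.frame(transcript_id = names(qs), class_code = "u",
                    ref_transcript_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(qs)) {
    best <- NULL
    for (r in rs) {
      code <- .orc_pair(qs[[i]], r)
      if (is.na(code)) next
      cand <- list(p = match(code, prio), chrom = r$chrom, start = r$span[1],
                   id = r$id, code = code)
      if (is.null(best) ||
          cand$p < best$p ||
          (cand$p == best$p && (cand$chrom < best$chrom ||
            (cand$chrom == best$chrom && (cand$start < best$start ||
              (cand$start == best$start && cand$id < best$id)))))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      out$class_code[i] <- best$code
      out$ref_transcript_id[i] <- best$id
    }
  }
  out[match(sort(out$transcript_id), out$transcript_id), ]
}

# --- exhaustive ORF enumeration --------------------------------------------
# Every ATG...stop span in all three frames, by direct position loops.

oracle_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  codon_at <- function(p) paste(ch[p:(p + 2)], collapse = "")
  best_len <- 0L; best_off <- NA_integer_; best_stop <- FALSE
  for (start in seq_len(max(n - 2, 0))) {
    if (codon_at(start) != "ATG") next
    p <- start
    len <- 0L
    has_stop <- FALSE
    while (p + 2 <= n) {
      cd <- codon_at(p)
      if (p > start && cd %in% c("TAA", "TAG", "TGA")) {
        has_stop <- TRUE
        break
      }
      len <- len + 3L
      p <- p + 3L
    }
    if (len > best_len || (len == best_len && len > 0 &&
                           (is.na(best_off) || start - 1L < best_off))) {
      best_len <- len; best_off <- start - 1L; best_stop <- has_stop
    }
  }
  list(start_offset = best_off, nt_length = best_len, has_stop = best_stop)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- rank-based Mann-Whitney AUC -------------------------------------------

oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- textbook BH step-up ----------------------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * p[o[i]] / i)
    q_sorted[i] <- min(running_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# --- hand Welch t -----------------------------------------------------------

oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# --- random transcript sets for classifier stress tests ---------------------
# Mixes structures derived from the reference (exact copies, sub-chains,
# shared junctions, intronic placements on both strands) with fully random
# ones, so that all eight class codes are reachable.

random_transcript_set <- function(n_query, n_ref, seed) {
  set.seed(seed)
  chroms <- c("c1", "c2")
  refs <- list()
  for (i in seq_len(n_ref)) {
    n_ex <- sample(2:4, 1)
    ex_len <- sample(60:200, n_ex, replace = TRUE)
    in_len <- sample(150:800, n_ex - 1, replace = TRUE)
    at <- sample(1:40000, 1)
    starts <- integer(0); ends <- integer(0); pos <- at
    for (k in seq_len(n_ex)) {
      starts <- c(starts, pos); ends <- c(ends, pos + ex_len[k] - 1L)
      pos <- pos + ex_len[k] + (if (k < n_ex) in_len[k] else 0L)
    }
    refs[[i]] <- tx(sprintf("R%03d", i), starts, ends,
                    strand = sample(c("+", "-"), 1),
                    chrom = sample(chroms, 1))
  }
  reference <- dplyr::bind_rows(refs)
  if (n_query == 0) {
    reference <- as_transcripts(reference)
    return(list(query = reference[0, ], reference = reference))
  }

  qs <- list()
  for (i in seq_len(n_query)) {
    mode <- sample(c("copy", "sub", "jshare", "intronic", "intronic_opp",
                     "random", "single"), 1,
                   prob = c(.1, .1, .15, .1, .1, .35, .1))
    r <- refs[[sample(n_ref, 1)]]
    r <- r[order(r$start), ]
    strand <- sample(c("+", "-", "."), 1, prob = c(.47, .47, .06))
    q <- switch(mode,
      copy = {
        out <- r
        out$start[1] <- max(1L, out$start[1] - sample(0:30, 1))
        out$end[nrow(out)] <- out$end[nrow(out)] + sample(0:30, 1)
        out$strand <- sample(c(r$strand[1], setdiff(c("+", "-"), r$strand[1])),
                             1, prob = c(.8, .2))
        out
      },
      sub = {
        if (nrow(r) < 3) r else {
          out <- r[1:2, ]
          out$start[1] <- out$start[1] + sample(0:20, 1)
          out$end[2] <- out$end[2] - sample(0:20, 1)
          out
        }
      },
      jshare = {
        e1 <- c(max(1L, r$start[1] - sample(40:120, 1)), r$end[1])
        e2 <- c(r$start[2], r$start[2] + sample(20:60, 1))
        tx("q", c(e1[1], e2[1]), c(e1[2], e2[2]), strand = r$strand[1],
           chrom = r$chrom[1])
      },
      intronic = ,
      intronic_opp = {
        gap_start <- r$end[1] + 1L
        gap_end <- r$start[2] - 1L
        w <- gap_end - gap_start + 1L
        if (w < 60) {
          tx("q", gap_start, gap_start + 5L, strand = "+", chrom = r$chrom[1])
        } else {
          e1s <- gap_start + 2L
          e1e <- e1s + max(5L, w %/% 6)
          e2s <- min(e1e + max(4L, w %/% 6), gap_end - 3L)
          e2e <- min(e2s + max(3L, w %/% 6), gap_end)
          st <- if (mode == "intronic") r$strand[1] else
            setdiff(c("+", "-"), r$strand[1])
          tx("q", c(e1s, e2s), c(e1e, e2e), strand = st, chrom = r$chrom[1])
        }
      },
      random = {
        n_ex <- sample(1:4, 1)
        ex_len <- sample(40:250, n_ex, replace = TRUE)
        in_len <- sample(50:600, max(n_ex - 1, 1), replace = TRUE)
        at <- sample(1:45000, 1)
        starts <- integer(0); ends <- integer(0); pos <- at
        for (k in seq_len(n_ex)) {
          starts <- c(starts, pos); ends <- c(ends, pos + ex_len[k] - 1L)
          pos <- pos + ex_len[k] + (if (k < n_ex) in_len[k] else 0L)
        }
        tx("q", starts, ends, strand = strand, chrom = sample(chroms, 1))
      },
      single = {
        at <- sample(1:45000, 1)
        tx("q", at, at + sample(50:400, 1), strand = strand,
           chrom = sample(chroms, 1))
      }
    )
    q$transcript_id <- sprintf("Q%04d", i)
    q$gene_id <- sprintf("qg%04d", i)
    qs[[i]] <- q
  }
  list(query = as_transcripts(dplyr::bind_rows(qs)),
       reference = as_transcripts(reference))
}
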