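# Class-code assignment of assembled transcripts against a reference
# annotation: the cuffcompare-style vocabulary
#   "=" complete match of intron chain
#   "c" contained by a reference transcript
#   "j" at least one splice junction shared with a reference transcript
#   "o" generic exonic overlap with a reference transcript
#   "i" transfrag falling entirely within a reference intron
#   "x" exonic overlap with reference on the opposite strand
#   "s" an intron overlaps a reference intron on the opposite strand
#   "u" unknown, intergenic transcript
#
# Each query is evaluated against every span-overlapping reference transcript
# and receives the best code under a fixed precedence ladder
# (= > c > j > o > i > x > s > u), ties between references broken by
# (chrom, start, transcript_id).

.CODE_PRIORITY <- c("=", "c", "j", "o", "i", "x", "s")

#' Class code vocabulary
#' @return Character vector of the eight class codes in precedence order
#'   (`"u"` last).
#' @export
class_codes <- function() c(.CODE_PRIORITY, "u")

.exons_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  any(outer(a[, 1], b[, 2], `<=`) & outer(a[, 2], b[, 1], `>=`))
}

.is_contiguous_subchain <- function(qi, ri) {
  nq <- nrow(qi); nr <- nrow(ri)
  if (nq == 0) return(TRUE)
  if (nr < nq) return(FALSE)
  starts <- which(ri[, 1] == qi[1, 1] & ri[, 2] == qi[1, 2])
  for (s0 in starts) {
    idx <- s0:(s0 + nq - 1L)
    if (idx[nq] <= nr && all(ri[idx, 1] == qi[, 1]) && all(ri[idx, 2] == qi[, 2])) {
      return(TRUE)
    }
  }
  FALSE
}

# Code for one (query, reference) pair, or NA when the pair supports no code.
# q and r are .trx_index entries on the same chromosome.
.pair_code <- function(q, r) {
  qs <- q$strand; rs <- r$strand
  strict_same <- qs %in% c("+", "-") && qs == rs
  strict_opp <- qs %in% c("+", "-") && rs %in% c("+", "-") && qs != rs
  loose_same <- strict_same || qs == "." || rs == "."
  q_multi <- nrow(q$introns) > 0
  r_multi <- nrow(r$introns) > 0

  if (strict_same && q_multi && r_multi && q$chain == r$chain) return("=")

  if (loose_same &&
      q$start >= r$start && q$end <= r$end &&
      .is_contiguous_subchain(q$introns, r$introns) &&
      !(q$chain == r$chain && q_multi) &&
      (q_multi || .exons_overlap(q$exons, r$exons))) {
    return("c")
  }

  if (strict_same && q_multi && r_multi &&
      length(intersect(q$junctions, r$junctions)) > 0) {
    return("j")
  }

  if (loose_same && .exons_overlap(q$exons, r$exons)) return("o")

  if (loose_same && r_multi &&
      any(r$introns[, 1] <= q$start & r$introns[, 2] >= q$end)) {
    return("i")
  }

  if (strict_opp && .exons_overlap(q$exons, r$exons)) return("x")

  if (strict_opp && q_multi && r_multi &&
      .exons_overlap(q$introns, r$introns) &&
      !.exons_overlap(q$exons, r$exons)) {
    return("s")
  }

  NA_character_
}

#' Classify assembled transcripts against a reference annotation
#'
#' Assigns every query transcript exactly one class code (see
#' [class_codes()]). Queries with no reference span overlap are `"u"`
#' (intergenic). Unknown-strand (`"."`) queries match either strand for the
#' overlap codes but are ineligible for `"="`/`"j"` (junction sharing needs a
#' strand); they are flagged in the output.
#'
#' @param query,reference Exon tables. `reference` is typically the output of
#'   [merge_annotations()].
#' @return Tibble with one row per query transcript: `transcript_id`,
#'   `class_code`, `ref_transcript_id`, `ref_gene_id` (both `NA` for `"u"`),
#'   `strand_unknown`.
#' @export
#' @examples
#' ref <- tibble::tibble(
#'   transcript_id = "r1", gene_id = "rg1", chrom = "chr1",
#'   start = c(101L, 501L), end = c(200L, 700L), strand = "+"
#' )
#' q <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(81L, 501L), end = c(200L, 650L), strand = "+"
#' )
#' classify_transcripts(q, ref)  # identical intron chain -> "="
classify_transcripts <- function(query, reference) {
  qi <- .trx_index(query)
  ri <- .trx_index(reference)
  qs <- qi$summary
  out <- tibble(
    transcript_id = qs$transcript_id,
    class_code = rep("u", nrow(qs)),
    ref_transcript_id = NA_character_,
    ref_gene_id = NA_character_,
    strand_unknown = qs$strand == "."
  )
  if (nrow(qs) == 0 || nrow(ri$summary) == 0) return(out)

  hits <- .span_overlaps(qs, ri$summary)
  if (nrow(hits) == 0) return(out)

  codes <- character(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    codes[k] <- .pair_code(qi$entries[[hits[k, 1]]], ri$entries[[hits[k, 2]]])
  }
  ok <- !is.na(codes)
  if (!any(ok)) return(out)
  cand <- tibble(
    qrow = hits[ok, 1],
    code = codes[ok],
    priority = match(codes[ok], .CODE_PRIORITY),
    ref_chrom = ri$summary$chrom[hits[ok, 2]],
    ref_start = ri$summary$start[hits[ok, 2]],
    ref_transcript_id = ri$summary$transcript_id[hits[ok, 2]],
    ref_gene_id = ri$summary$gene_id[hits[ok, 2]]
  ) |>
    arrange(.data$qrow, .data$priority, .data$ref_chrom, .data$ref_start,
            .data$ref_transcript_id) |>
    group_by(.data$qrow) |>
    slice(1L) |>
    ungroup()
  out$class_code[cand$qrow] <- cand$code
  out$ref_transcript_id[cand$qrow] <- cand$ref_transcript_id
  out$ref_gene_id[cand$qrow] <- cand$ref_gene_id
  out
}

#' Merge reference annotations into one set
#'
#' Unions several annotation sources (e.g. RefSeq + Ensembl + UCSC known
#' genes) and removes structural duplicates: multi-exon transcripts are
#' duplicates when they share (chrom, strand, intron chain) -- exon-end
#' padding differences do not matter -- and single-exon transcripts when they
#' share the identical exon interval. The first-seen source's ids are kept.
#' A transcript_id colliding across sources with a *different* structure is
#' suffixed (`"_2"`, ...) to keep ids unique.
#'
#' @param ... Exon tables (or a single list of them).
#' @return Merged, deduplicated exon table.
#' @export
merge_annotations <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) == 0) abort("merge_annotations() needs at least one annotation set")
  sets <- lapply(sets, as_transcripts)
  seen_keys <- character(0)
  seen_ids <- character(0)
  out <- list()
  for (set in sets) {
    if (nrow(set) == 0) next
    idx <- .trx_index(set)
    for (tid in idx$summary$transcript_id) {
      e <- idx$entries[[tid]]
      key <- if (nrow(e$introns) > 0) {
        paste(e$chrom, e$strand, e$chain, sep = "|")
      } else {
        paste(e$chrom, e$strand, e$exons[1, 1], e$exons[1, 2], sep = "|")
      }
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      rows <- set[set$transcript_id == tid, ]
      new_id <- tid
      k <- 2L
      while (new_id %in% seen_ids) {
        new_id <- paste0(tid, "_", k)
        k <- k + 1L
      }
      rows$transcript_id <- new_id
      seen_ids <- c(seen_ids, new_id)
      out[[length(out) + 1L]] <- rows
    }
  }
  if (length(out) == 0) return(sets[[1]][0, ])
  as_transcripts(bind_rows(out))
}

#' Extract candidate transcripts by class code
#'
#' Step 1 of the detection scan: keep the categories that can harbour novel
#' lncRNAs. The default -- intronic `"i"`, novel-isoform `"j"`, exonic-overlap
#' `"o"`, intergenic `"u"` and antisense `"x"` -- excludes everything already
#' annotated (`"="`) or likely partial (`"c"`).
#'
#' @param x Exon table.
#' @param classification Output of [classify_transcripts()] for `x`.
#' @param wanted Class codes to keep.
#' @return Exon table restricted to transcripts with a wanted code.
#' @export
extract_category <- function(x, classification, wanted = c("i", "j", "o", "u", "x")) {
  x <- as_transcripts(x)
  keep <- classification$transcript_id[classification$class_code %in% wanted]
  x[x$transcript_id %in% keep, ]
}

#' Class-code frequency table
#'
#' @param classification Output of [classify_transcripts()].
#' @return Tibble `class_code`, `n`, `percentage` (percentages sum to 100).
#' @export
categorize_summary <- function(classification) {
  tab <- classification |>
    count(.data$class_code, name = "n") |>
    mutate(percentage = 100 * .data$n / sum(.data$n))
  tab[order(match(tab$class_code, class_codes())), ]
}
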