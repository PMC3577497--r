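# Per-transcript structural statistics: spans, exonic length, intron chains,
# and the interval prefilter used by the classifier.

#' Per-transcript summary of an exon table
#'
#' @param x Exon table.
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `start`/`end` (transcript span),
#'   `exonic_length` (summed exon lengths) and `fpkm`.
#' @export
transcript_summary <- function(x) {
  x <- as_transcripts(x)
  if (nrow(x) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  n_exons = integer(), exonic_length = integer(),
                  start = integer(), end = integer(), fpkm = numeric()))
  }
  x |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      exonic_length = sum(.data$end - .data$start + 1L),
      start = min(.data$start),
      end = max(.data$end),
      fpkm = first(.data$fpkm),
      .groups = "drop"
    )
}

#' Exonic length of each transcript
#'
#' The transcript length used throughout the pipeline is the summed exon
#' length (the spliced length), not the genomic span.
#'
#' @param x Exon table.
#' @return Tibble `transcript_id`, `exonic_length`.
#' @export
exonic_length <- function(x) {
  transcript_summary(x)[, c("transcript_id", "exonic_length")]
}

#' Intron chains of multi-exon transcripts
#'
#' Introns are the gaps between consecutive exons: `(prev_end + 1,
#' next_start - 1)`. A transcript with `n` exons has `n - 1` introns; each
#' intron's boundaries form one splice junction. Single-exon transcripts have
#' no intron chain and are a contract violation here -- filter them out first.
#'
#' @param x Exon table.
#' @return Tibble `transcript_id`, `chrom`, `strand`, `intron_index`,
#'   `start`, `end` (intron coordinates, 1-based inclusive).
#' @export
intron_chains <- function(x) {
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  if (any(s$n_exons < 2)) {
    abort(paste0("intron chain undefined for single-exon transcript '",
                 s$transcript_id[which(s$n_exons < 2)[1]], "'"))
  }
  x |>
    group_by(.data$transcript_id) |>
    dplyr::reframe(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      intron_index = seq_len(n() - 1L),
      intron_start = .data$end[-n()] + 1L,
      intron_end = .data$start[-1L] - 1L
    ) |>
    rename(start = "intron_start", end = "intron_end")
}

#' Keep only multi-exon transcripts
#'
#' Single-exon assemblies are unreliable (mono-exonic fragments are the
#' typical assembly artefact) and the pipeline drops them before
#' classification.
#'
#' @param x Exon table.
#' @return Exon table restricted to transcripts with >= 2 exons.
#' @export
filter_multi_exon <- function(x) {
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  semi_join(x, s[s$n_exons > 1, "transcript_id"], by = "transcript_id")
}

# Internal structural index: one entry per transcript with exon/intron
# matrices and precomputed chain keys. Used by the classifier and the
# structure-overlap report.
.trx_index <- function(x) {
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  ex_split <- split(seq_len(nrow(x)), x$transcript_id)[s$transcript_id]
  entries <- vector("list", nrow(s))
  names(entries) <- s$transcript_id
  for (i in seq_len(nrow(s))) {
    idx <- ex_split[[i]]
    exons <- cbind(x$start[idx], x$end[idx])
    n <- nrow(exons)
    introns <- if (n > 1) cbind(exons[-n, 2] + 1L, exons[-1, 1] - 1L) else
      matrix(integer(0), ncol = 2)
    entries[[i]] <- list(
      transcript_id = s$transcript_id[i],
      gene_id = s$gene_id[i],
      chrom = s$chrom[i],
      strand = s$strand[i],
      start = s$start[i],
      end = s$end[i],
      exons = exons,
      introns = introns,
      chain = if (n > 1) paste(introns[, 1], introns[, 2], sep = "-", collapse = ",") else "",
      junctions = if (n > 1) paste(introns[, 1], introns[, 2], sep = "-") else character(0)
    )
  }
  list(summary = s, entries = entries)
}

# Span-overlap prefilter: indices of `subject` transcripts whose span overlaps
# each `query` span on the same chromosome (strand ignored). Returns a
# two-column matrix of (query row, subject row) into the summary tibbles.
.span_overlaps <- function(query_summary, subject_summary) {
  hits_q <- integer(0)
  hits_s <- integer(0)
  for (chr in intersect(unique(query_summary$chrom), unique(subject_summary$chrom))) {
    qi <- which(query_summary$chrom == chr)
    si <- which(subject_summary$chrom == chr)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(query_summary$start[qi], query_summary$end[qi]),
      IRanges::IRanges(subject_summary$start[si], subject_summary$end[si])
    )
    hits_q <- c(hits_q, qi[S4Vectors::queryHits(ov)])
    hits_s <- c(hits_s, si[S4Vectors::subjectHits(ov)])
  }
  cbind(query = hits_q, subject = hits_s)
}
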