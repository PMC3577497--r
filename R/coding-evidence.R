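# Coding-potential evidence from external tools: per-transcript PhyloCSF
# scores and HMMER/Pfam domain hits. The tools themselves run elsewhere;
# this module consumes their output files and applies the retention rules:
#   step 4: keep PhyloCSF score < 0 (strict) or an ORF-too-short test failure
#   step 5: drop any transcript with a significant Pfam domain hit

#' Read a PhyloCSF per-transcript score file
#'
#' Expects a tab- (or whitespace-) separated file with the transcript id in
#' the first column and the score (decibans) or a failure message in the
#' second. A non-numeric second field is a failure: messages mentioning a
#' too-short ORF (the tool cannot score ORFs under 25 aa) map to status
#' `"orf_too_short"`, anything else to `"failed"`.
#'
#' @param path Path to the score file (plain or gzipped); `#` comment lines
#'   are skipped.
#' @return Tibble `transcript_id`, `score` (`NA` unless scored), `status`
#'   (`"scored"`, `"orf_too_short"`, `"failed"`).
#' @export
read_phylocsf <- function(path) {
  if (!file.exists(path)) abort(paste0("PhyloCSF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(transcript_id = character(), score = numeric(),
                  status = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  one_col <- lengths(fields) < 2
  fields[one_col] <- strsplit(trimws(lines[one_col]), "\\s+")
  if (any(lengths(fields) < 2)) {
    bad <- which(lengths(fields) < 2)[1]
    abort(sprintf("malformed PhyloCSF line %d: need id and score/status columns", bad))
  }
  id <- vapply(fields, `[`, character(1), 1L)
  raw <- trimws(vapply(fields, `[`, character(1), 2L))
  if (anyDuplicated(id)) {
    abort(paste0("duplicate transcript id in PhyloCSF file: ",
                 id[which(duplicated(id))[1]]))
  }
  score <- suppressWarnings(as.numeric(raw))
  status <- ifelse(!is.na(score), "scored",
                   ifelse(grepl("orf.*(short|too)|too.*short|<\\s*25", raw,
                                ignore.case = TRUE),
                          "orf_too_short", "failed"))
  tibble(transcript_id = id, score = score, status = status)
}

#' Filter transcripts by PhyloCSF evidence
#'
#' Step 4 of the detection scan: a transcript is retained when its PhyloCSF
#' score is strictly below `cutoff` (default 0 decibans; a score of exactly 0
#' is dropped) or when the test failed *because the ORF was too short to
#' score* -- a tiny ORF is itself evidence against coding capacity. Other
#' failures (alignment unavailable, tool error) are missing evidence, not
#' non-coding evidence, and are dropped by default.
#'
#' @param x Exon table.
#' @param records Tibble from [read_phylocsf()].
#' @param cutoff Strict upper bound on the score for retention.
#' @param missing How to treat transcripts absent from `records`:
#'   `"drop"` (default; treated like a failed test) or `"keep"`.
#' @return Exon table of retained transcripts.
#' @export
phylocsf_filter <- function(x, records, cutoff = 0, missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  x <- as_transcripts(x)
  ids <- unique(x$transcript_id)
  m <- match(ids, records$transcript_id)
  status <- records$status[m]
  score <- records$score[m]
  keep <- ids[(is.na(m) & missing == "keep") |
                (!is.na(m) & ((status %in% "scored" & !is.na(score) & score < cutoff) |
                                status %in% "orf_too_short"))]
  x[x$transcript_id %in% keep, ]
}

#' Read an HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited `--domtblout` format in hmmscan
#' orientation (target = Pfam domain, query = transcript peptide), one row
#' per domain hit; `#` comment lines are skipped.
#'
#' @param path Path to the domtblout file (plain or gzipped).
#' @return Tibble `transcript_id`, `domain_name`, `domain_accession`,
#'   `full_evalue`, `independent_evalue`, `bit_score`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) abort(paste0("domtblout file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(transcript_id = character(), domain_name = character(),
                  domain_accession = character(), full_evalue = numeric(),
                  independent_evalue = numeric(), bit_score = numeric()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 23)) {
    bad <- which(lengths(fields) < 23)[1]
    abort(sprintf("malformed domtblout line %d: expected >= 23 whitespace-separated columns, found %d",
                  lineno[bad], lengths(fields)[bad]))
  }
  get <- function(k) vapply(fields, `[`, character(1), k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(get(k)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(sprintf("malformed domtblout line %d: non-numeric field %d",
                    lineno[bad], k))
    }
    v
  }
  tibble(
    transcript_id = get(4L),
    domain_name = get(1L),
    domain_accession = get(2L),
    full_evalue = num(7L),
    independent_evalue = num(13L),
    bit_score = num(14L)
  )
}

#' Filter transcripts by Pfam domain hits
#'
#' Step 5 of the detection scan: a transcript is dropped when any of its
#' domain hits has an independent E-value at or below `evalue_cutoff`
#' (default 1e-3); transcripts with no hits, or only insignificant hits, are
#' retained.
#'
#' @param x Exon table.
#' @param hits Tibble from [read_domtblout()].
#' @param evalue_cutoff Inclusive significance bound on the independent
#'   E-value; must be > 0.
#' @return Exon table of retained transcripts.
#' @export
pfam_filter <- function(x, hits, evalue_cutoff = 1e-3) {
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0) {
    abort("evalue_cutoff must be > 0")
  }
  x <- as_transcripts(x)
  sig <- unique(hits$transcript_id[hits$independent_evalue <= evalue_cutoff])
  x[!(x$transcript_id %in% sig), ]
}
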