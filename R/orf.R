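# Spliced-sequence extraction and the longest-putative-ORF statistic.
#
# A putative ORF is the longest ATG-anchored in-frame codon run on the sense
# strand: it starts at ATG and extends to the base before the first in-frame
# stop (TAA/TAG/TGA), or to the last complete codon when no stop occurs
# (has_stop = FALSE). Lengths exclude the stop codon, so 300 nt <=> 100 aa.
# Codons containing N never match ATG or a stop.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    # FASTA headers may carry descriptions; key on the first word
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    return(toupper(seqs))
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  abort("genome must be a FASTA path, a DNAStringSet, or a named character vector")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements the whole for `"-"` strand transcripts, yielding the
#' 5'->3' sense-strand sequence. Sequence length equals the exonic length.
#'
#' @param x Exon table; strands must be known (`"+"`/`"-"`).
#' @param genome FASTA path, `Biostrings::DNAStringSet`, or named character
#'   vector of chromosome sequences.
#' @return Tibble `transcript_id`, `sequence`, `length`.
#' @export
spliced_sequences <- function(x, genome) {
  x <- as_transcripts(x)
  seqs <- .load_genome(genome)
  s <- transcript_summary(x)
  if (any(s$strand == ".")) {
    abort(paste0("transcript '", s$transcript_id[which(s$strand == ".")[1]],
                 "' has unknown strand; spliced sequence needs a strand"))
  }
  missing_chrom <- setdiff(unique(s$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  lens <- nchar(seqs)
  bad <- s$end > lens[s$chrom]
  if (any(bad)) {
    abort(paste0("transcript '", s$transcript_id[which(bad)[1]],
                 "' has exons beyond the end of ", s$chrom[which(bad)[1]]))
  }
  per <- split(seq_len(nrow(x)), x$transcript_id)[s$transcript_id]
  seq_out <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    idx <- per[[i]]
    raw <- paste(substring(seqs[[s$chrom[i]]], x$start[idx], x$end[idx]),
                 collapse = "")
    seq_out[i] <- if (s$strand[i] == "-") .revcomp(raw) else raw
  }
  tibble(transcript_id = s$transcript_id, sequence = seq_out,
         length = nchar(seq_out))
}

#' Longest putative ORF of a single sequence
#'
#' Scans the three sense-strand reading frames for the maximum-length
#' ATG-anchored ORF; ties are broken by the smallest start offset.
#'
#' @param sequence Nucleotide string over `{A, C, G, T, N}`.
#' @return A one-row tibble: `start_offset` (0-based, in transcript
#'   coordinates), `nt_length` (excluding the stop codon; 0 when no
#'   ATG-anchored ORF exists), `aa_length`, `has_stop`, `frame` (0/1/2).
#' @export
find_longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  best <- list(start_offset = NA_integer_, nt_length = 0L, aa_length = 0L,
               has_stop = FALSE, frame = NA_integer_)
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3
    if (n_cod < 1) next
    pos <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(s, pos, pos + 2L)
    atg <- which(cods == "ATG")
    if (length(atg) == 0) next
    stp <- which(cods %in% .STOP_CODONS)
    if (length(stp) > 0) {
      nxt_idx <- findInterval(atg, stp) + 1L
      nxt <- ifelse(nxt_idx <= length(stp), stp[nxt_idx], NA_integer_)
    } else {
      nxt <- rep(NA_integer_, length(atg))
    }
    has <- !is.na(nxt)
    len <- ifelse(has, (nxt - atg) * 3L, (n_cod - atg + 1L) * 3L)
    offs <- frame + (atg - 1L) * 3L
    k <- order(-len, offs)[1]
    if (len[k] > best$nt_length ||
        (len[k] == best$nt_length && len[k] > 0 &&
         (is.na(best$start_offset) || offs[k] < best$start_offset))) {
      best <- list(start_offset = offs[k], nt_length = as.integer(len[k]),
                   aa_length = as.integer(len[k] / 3L),
                   has_stop = has[k], frame = frame)
    }
  }
  as_tibble(best)
}

#' Longest putative ORF per transcript
#'
#' @param seqs Tibble from [spliced_sequences()] (columns `transcript_id`,
#'   `sequence`).
#' @return Tibble with one row per transcript: the [find_longest_orf()]
#'   columns plus `transcript_id`.
#' @export
longest_orfs <- function(seqs) {
  if (nrow(seqs) == 0) {
    return(tibble(transcript_id = character(), start_offset = integer(),
                  nt_length = integer(), aa_length = integer(),
                  has_stop = logical(), frame = integer()))
  }
  res <- purrr::map(seqs$sequence, find_longest_orf) |> bind_rows()
  dplyr::bind_cols(tibble(transcript_id = seqs$transcript_id), res)
}

#' Translate a putative ORF
#'
#' Standard genetic code; codons containing N (or any non-ACGT base)
#' translate to `X`. The stop codon is not included.
#'
#' @param sequence Transcript sense-strand sequence.
#' @param start_offset 0-based ORF start (the A of ATG).
#' @param nt_length ORF length in nt, excluding the stop codon; must be > 0.
#' @return Amino-acid string of length `nt_length / 3`.
#' @export
translate_orf <- function(sequence, start_offset, nt_length) {
  if (is.na(nt_length) || nt_length <= 0) {
    abort("cannot translate a zero-length ORF")
  }
  s <- toupper(substr(sequence, start_offset + 1L, start_offset + nt_length))
  pos <- 3L * (seq_len(nt_length %/% 3L) - 1L) + 1L
  cods <- substring(s, pos, pos + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Keep transcripts longer than a minimum exonic length
#'
#' Step 2 of the detection scan: retain transcripts with exonic length
#' strictly greater than `min_nt` (default 200 nt, the lncRNA length
#' definition).
#'
#' @param x Exon table.
#' @param min_nt Exclusive lower bound on exonic length.
#' @return Exon table of retained transcripts.
#' @export
extract_length <- function(x, min_nt = 200) {
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  x[x$transcript_id %in% s$transcript_id[s$exonic_length > min_nt], ]
}

#' Per-transcript ORF report
#'
#' @param x Exon table.
#' @param genome See [spliced_sequences()].
#' @return Tibble `transcript_id`, `start_offset`, `nt_length`, `aa_length`,
#'   `has_stop`, `frame`, `exonic_length`.
#' @export
orf_report <- function(x, genome) {
  seqs <- spliced_sequences(x, genome)
  out <- longest_orfs(seqs)
  out$exonic_length <- seqs$length[match(out$transcript_id, seqs$transcript_id)]
  out
}

#' Exclude transcripts with a long putative ORF
#'
#' Step 3 of the detection scan: retain transcripts whose longest putative
#' ORF is strictly shorter than `max_orf_nt` (default 300 nt = 100 aa, the
#' conventional coding-capacity bound; a 300 nt ORF is excluded).
#'
#' @param x Exon table.
#' @param genome See [spliced_sequences()].
#' @param max_orf_nt Exclusive upper bound on ORF length in nt.
#' @return Exon table of retained transcripts, with the full ORF report for
#'   *all* input transcripts attached as attribute `"orf_report"`.
#' @export
extract_orf <- function(x, genome, max_orf_nt = 300) {
  x <- as_transcripts(x)
  rep <- orf_report(x, genome)
  keep <- rep$transcript_id[rep$nt_length < max_orf_nt]
  out <- x[x$transcript_id %in% keep, ]
  attr(out, "orf_report") <- rep
  out
}
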