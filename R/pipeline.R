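# End-to-end orchestration: multi-exon filter -> classification vs merged
# reference -> high-quality selection (ROC-derived or fixed FPKM cutoff) ->
# five-step lncRNA scan (category, length, ORF, PhyloCSF, Pfam), with
# per-step retention accounting.

#' Pipeline configuration
#'
#' All tunable thresholds of the detection pipeline, with the conventional
#' defaults: candidate codes i/j/o/u/x, exonic length strictly > 200 nt,
#' longest putative ORF strictly < 300 nt, PhyloCSF score strictly < 0
#' decibans (ORF-too-short failures retained), Pfam independent E-value
#' significance at 1e-3, and FPKM >= 2.12 for novel assemblies -- or
#' `fpkm_cutoff = "auto"` to derive the cutoff from the data via the
#' closest-to-corner ROC rule ([derive_fpkm_threshold()]).
#'
#' @param candidate_codes Class codes eligible as lncRNA candidates (subset
#'   of i/j/o/u/x/s).
#' @param min_length_nt Exclusive minimum exonic length (nt).
#' @param max_orf_nt Exclusive maximum putative-ORF length (nt).
#' @param phylocsf_cutoff Strict PhyloCSF retention bound (decibans).
#' @param phylocsf_missing `"drop"` or `"keep"` for transcripts absent from
#'   the score file.
#' @param pfam_evalue Inclusive Pfam significance bound on the independent
#'   E-value.
#' @param fpkm_cutoff Numeric cutoff for novel assemblies, or `"auto"`.
#' @param multi_exon_only Drop single-exon assemblies first (default TRUE).
#' @return A list of class `lncscan_config`.
#' @export
pipeline_config <- function(candidate_codes = c("i", "j", "o", "u", "x"),
                            min_length_nt = 200,
                            max_orf_nt = 300,
                            phylocsf_cutoff = 0,
                            phylocsf_missing = "drop",
                            pfam_evalue = 1e-3,
                            fpkm_cutoff = 2.12,
                            multi_exon_only = TRUE) {
  if (!all(candidate_codes %in% c("i", "j", "o", "u", "x", "s"))) {
    abort("candidate_codes must be a subset of {i, j, o, u, x, s}")
  }
  if (min_length_nt < 0 || max_orf_nt <= 0 || pfam_evalue <= 0) {
    abort("thresholds must be positive")
  }
  if (!(identical(fpkm_cutoff, "auto") ||
        (is.numeric(fpkm_cutoff) && length(fpkm_cutoff) == 1 && fpkm_cutoff >= 0))) {
    abort("fpkm_cutoff must be a non-negative number or \"auto\"")
  }
  structure(list(
    candidate_codes = candidate_codes,
    min_length_nt = min_length_nt,
    max_orf_nt = max_orf_nt,
    phylocsf_cutoff = phylocsf_cutoff,
    phylocsf_missing = phylocsf_missing,
    pfam_evalue = pfam_evalue,
    fpkm_cutoff = fpkm_cutoff,
    multi_exon_only = multi_exon_only
  ), class = "lncscan_config")
}

.n_trx <- function(x) length(unique(x$transcript_id))

.acct_row <- function(step, input, retained) {
  tibble(step = step, input = input, retained = retained,
         filtered = input - retained,
         retained_fraction = if (input > 0) retained / input else NA_real_)
}

#' Run the novel-lncRNA detection pipeline
#'
#' Executes the full method on assembled transcripts: (1) optionally drop
#' single-exon assemblies; (2) classify against the merged reference
#' annotation; (3) select the high-quality set (`"="` kept unconditionally,
#' novel codes kept at `fpkm >= cutoff`, `"c"` dropped); then the five-step
#' scan: candidate categories, exonic length, longest putative ORF, PhyloCSF,
#' Pfam. The survivors are the novel lncRNA candidates.
#'
#' @param query Exon table or GTF path of assembled transcripts (with FPKM).
#' @param references Exon table, GTF path, or list of either; merged with
#'   [merge_annotations()].
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param phylocsf [read_phylocsf()] tibble or file path.
#' @param pfam [read_domtblout()] tibble or file path.
#' @param config [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `novel_lncrna.gtf`,
#'   `accounting.tsv`, `categories.tsv` and `classification.tsv`.
#' @return A list of class `lncscan_result`: `novel` (exon table),
#'   `novel_summary`, `classification`, `accounting`, `categories`,
#'   `orf_report`, `threshold` (the [optimal_threshold()] row when
#'   `fpkm_cutoff = "auto"`), `fpkm_cutoff`, `config`.
#' @export
run_pipeline <- function(query, references, genome, phylocsf, pfam,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "lncscan_config"))
  if (is.character(query)) query <- read_gtf(query)
  query <- as_transcripts(query)
  if (is.character(references) || is.data.frame(references)) {
    references <- list(references)
  }
  references <- lapply(references, function(r) if (is.character(r)) read_gtf(r) else r)
  reference <- merge_annotations(references)
  if (is.character(phylocsf)) phylocsf <- read_phylocsf(phylocsf)
  if (is.character(pfam)) pfam <- read_domtblout(pfam)

  acct <- list()
  n0 <- .n_trx(query)
  current <- if (config$multi_exon_only) filter_multi_exon(query) else query
  acct[[1]] <- .acct_row("multi_exon", n0, .n_trx(current))

  classification <- classify_transcripts(current, reference)

  threshold <- NULL
  cutoff <- config$fpkm_cutoff
  if (identical(cutoff, "auto")) {
    threshold <- derive_fpkm_threshold(current, classification)
    cutoff <- threshold$optimum_threshold
  }

  hq <- select_high_quality(current, classification, cutoff)
  acct[[2]] <- .acct_row("high_quality", .n_trx(current), .n_trx(hq))

  step1 <- extract_category(hq, classification, config$candidate_codes)
  acct[[3]] <- .acct_row("extract_category", .n_trx(hq), .n_trx(step1))

  step2 <- extract_length(step1, config$min_length_nt)
  acct[[4]] <- .acct_row("extract_length", .n_trx(step1), .n_trx(step2))

  step3 <- extract_orf(step2, genome, config$max_orf_nt)
  rep_orf <- attr(step3, "orf_report")
  acct[[5]] <- .acct_row("extract_orf", .n_trx(step2), .n_trx(step3))

  step4 <- phylocsf_filter(step3, phylocsf, config$phylocsf_cutoff,
                           config$phylocsf_missing)
  acct[[6]] <- .acct_row("extract_phylocsf", .n_trx(step3), .n_trx(step4))

  step5 <- pfam_filter(step4, pfam, config$pfam_evalue)
  acct[[7]] <- .acct_row("extract_pfam", .n_trx(step4), .n_trx(step5))

  accounting <- bind_rows(acct)
  final_cls <- classification[classification$transcript_id %in%
                                unique(step5$transcript_id), ]
  novel_summary <- transcript_summary(step5) |>
    left_join(final_cls, by = "transcript_id")
  if (nrow(rep_orf) > 0) {
    novel_summary <- left_join(
      novel_summary,
      rep_orf[, c("transcript_id", "nt_length", "aa_length", "has_stop")] |>
        rename(orf_nt_length = "nt_length", orf_aa_length = "aa_length"),
      by = "transcript_id")
  }

  res <- structure(list(
    novel = step5,
    novel_summary = novel_summary,
    classification = classification,
    accounting = accounting,
    categories = if (nrow(final_cls) > 0) categorize_summary(final_cls) else
      tibble(class_code = character(), n = integer(), percentage = numeric()),
    orf_report = rep_orf,
    threshold = threshold,
    fpkm_cutoff = cutoff,
    config = config
  ), class = "lncscan_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    novel_out <- step5
    novel_out$extra <- paste0(
      ifelse(nzchar(novel_out$extra), paste0(novel_out$extra, "; "), ""),
      "class_code \"",
      final_cls$class_code[match(novel_out$transcript_id, final_cls$transcript_id)],
      "\";")
    write_gtf(novel_out, file.path(out_dir, "novel_lncrna.gtf"))
    write.table(accounting, file.path(out_dir, "accounting.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$categories, file.path(out_dir, "categories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(classification, file.path(out_dir, "classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.lncscan_result <- function(x, ...) {
  cat("Novel lncRNA detection\n")
  cat(sprintf("  FPKM cutoff: %.4g%s\n", x$fpkm_cutoff,
              if (!is.null(x$threshold)) " (ROC-derived)" else ""))
  cat(sprintf("  novel lncRNA candidates: %d\n", .n_trx(x$novel)))
  cat("\nRetention accounting:\n")
  print(as.data.frame(x$accounting), row.names = FALSE)
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x `lncscan_result`.
#' @param ... Unused.
#' @return Per-candidate tibble: structure, expression, class code and ORF
#'   statistics of each novel lncRNA.
#' @export
tidy.lncscan_result <- function(x, ...) x$novel_summary

#' One-row summary of a pipeline result
#'
#' @param x `lncscan_result`.
#' @param ... Unused.
#' @return One-row tibble: input/retained counts per stage and the FPKM
#'   cutoff used.
#' @export
glance.lncscan_result <- function(x, ...) {
  a <- x$accounting
  tibble(
    n_input = a$input[1],
    n_multi_exon = a$retained[a$step == "multi_exon"],
    n_high_quality = a$retained[a$step == "high_quality"],
    n_candidates = a$retained[a$step == "extract_category"],
    n_novel = a$retained[a$step == "extract_pfam"],
    fpkm_cutoff = x$fpkm_cutoff,
    auc = if (!is.null(x$threshold)) x$threshold$auc else NA_real_
  )
}
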