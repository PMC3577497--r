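# Downstream reporting statistics: fold changes, BH-adjusted significance,
# Welch feature contrasts, and structural overlap between transcript sets.

#' Log2 fold change between two expression values
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; the pseudocount keeps
#' zero-FPKM transcripts finite.
#'
#' @param fpkm_a,fpkm_b Non-negative expression values (vectorised).
#' @param pseudocount Small positive constant, default `1e-6`.
#' @return Numeric vector of log2 fold changes.
#' @export
fold_change <- function(fpkm_a, fpkm_b, pseudocount = 1e-6) {
  if (any(fpkm_a < 0, na.rm = TRUE) || any(fpkm_b < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative")
  }
  log2((fpkm_a + pseudocount) / (fpkm_b + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential-expression calls from fold change and BH-adjusted p-values
#'
#' Combines externally produced per-transcript p-values with the package's
#' fold-change and multiple-testing layer. A transcript is significant when
#' its q-value is strictly below `alpha`.
#'
#' @param de Data frame with columns `transcript_id`, `fpkm_a`, `fpkm_b`,
#'   `p_value`.
#' @param alpha Strict q-value significance bound, default 0.05.
#' @param pseudocount Passed to [fold_change()].
#' @return Tibble with added `log2_fold_change`, `q_value`, `significant`.
#' @export
de_calls <- function(de, alpha = 0.05, pseudocount = 1e-6) {
  de <- as_tibble(de)
  de$log2_fold_change <- fold_change(de$fpkm_a, de$fpkm_b, pseudocount)
  de$q_value <- bh_adjust(de$p_value)
  de$significant <- de$q_value < alpha
  de
}

.feature_values <- function(x, feature, genome) {
  s <- transcript_summary(x)
  switch(feature,
    length = s$exonic_length,
    exon_count = s$n_exons,
    fpkm = s$fpkm,
    orf_length = {
      if (is.null(genome)) abort("feature 'orf_length' needs a genome")
      orf_report(x, genome)$nt_length
    },
    abort(paste0("unknown feature: ", feature))
  )
}

#' Welch two-sample comparison of a transcript feature
#'
#' Compares a structural or expression feature between two transcript sets
#' with the unequal-variance (Welch) two-sample t-test,
#' Welch-Satterthwaite degrees of freedom, two-sided p-value.
#'
#' @param set_a,set_b Exon tables.
#' @param feature One of `"length"` (exonic length), `"exon_count"`,
#'   `"orf_length"` (needs `genome`), `"fpkm"`.
#' @param genome Genome for `"orf_length"` (see [spliced_sequences()]).
#' @return One-row tibble: `feature`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
compare_features <- function(set_a, set_b,
                             feature = c("length", "exon_count", "orf_length", "fpkm"),
                             genome = NULL) {
  feature <- match.arg(feature)
  va <- .feature_values(as_transcripts(set_a), feature, genome)
  vb <- .feature_values(as_transcripts(set_b), feature, genome)
  if (length(va) < 2 || length(vb) < 2) {
    abort("each group needs at least 2 transcripts")
  }
  if (anyNA(va) || anyNA(vb)) abort("feature values contain missing data")
  if (var(va) == 0 && var(vb) == 0) {
    abort("both groups are constant; the Welch statistic is undefined")
  }
  tt <- t.test(va, vb, var.equal = FALSE)
  tibble(
    feature = feature, n_a = length(va), n_b = length(vb),
    mean_a = mean(va), mean_b = mean(vb),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

.structure_key <- function(e) {
  if (nrow(e$introns) > 0) {
    paste(e$chrom, e$strand, e$chain, sep = "|")
  } else {
    paste(e$chrom, e$strand, e$exons[1, 1], e$exons[1, 2], sep = "|")
  }
}

#' Structural overlap between two transcript sets
#'
#' Partitions `set_a` into exact structural matches against `set_b`
#' (identical chrom, strand and intron chain; identical exon interval for
#' single-exon transcripts), partial overlaps (>= 1 bp exonic overlap on
#' either strand, but not exact), and non-overlapping transcripts.
#'
#' @param set_a,set_b Exon tables.
#' @return One-row tibble `exact_match`, `partial_overlap`, `no_overlap`
#'   (counts over `set_a`'s transcripts), with the per-transcript categories
#'   attached as attribute `"detail"`.
#' @export
structure_overlap <- function(set_a, set_b) {
  ia <- .trx_index(set_a)
  ib <- .trx_index(set_b)
  b_keys <- vapply(ib$entries, .structure_key, character(1))
  category <- rep("no_overlap", nrow(ia$summary))
  hits <- .span_overlaps(ia$summary, ib$summary)
  for (i in seq_len(nrow(ia$summary))) {
    ea <- ia$entries[[i]]
    if (.structure_key(ea) %in% b_keys) {
      category[i] <- "exact_match"
      next
    }
    js <- hits[hits[, 1] == i, 2]
    for (j in js) {
      if (.exons_overlap(ea$exons, ib$entries[[j]]$exons)) {
        category[i] <- "partial_overlap"
        break
      }
    }
  }
  out <- tibble(
    exact_match = sum(category == "exact_match"),
    partial_overlap = sum(category == "partial_overlap"),
    no_overlap = sum(category == "no_overlap")
  )
  attr(out, "detail") <- tibble(transcript_id = ia$summary$transcript_id,
                                category = category)
  out
}
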