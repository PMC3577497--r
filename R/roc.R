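# Expression-quality filtering: an ROC over FPKM separates complete ("=")
# from partial ("c") assemblies; the closest-to-corner optimum of
#   argmin_i (1 - sensitivity_i)^2 + (1 - specificity_i)^2
# gives the FPKM cutoff used to discard partial transcripts and artefacts.

#' Build an ROC curve from positive and negative score samples
#'
#' The classification rule is *predict positive when value > threshold*
#' (strict). Sensitivity at threshold t is the fraction of positives > t;
#' specificity is the fraction of negatives <= t. Candidate thresholds are
#' the midpoints between consecutive distinct pooled values, with -Inf/+Inf
#' sentinels, so every achievable (sensitivity, specificity) operating point
#' appears exactly once.
#'
#' @param positive,negative Numeric vectors (e.g. FPKM of `"="` and `"c"`
#'   transcripts). Both must be non-empty and finite.
#' @return Tibble of class `lncr_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by increasing threshold.
#' @export
build_roc <- function(positive, negative) {
  if (length(positive) == 0 || length(negative) == 0) {
    abort("build_roc() needs non-empty positive and negative samples")
  }
  if (anyNA(positive) || anyNA(negative) ||
      any(!is.finite(positive)) || any(!is.finite(negative))) {
    abort("build_roc() samples must be finite and non-missing")
  }
  pooled <- sort(unique(c(positive, negative)))
  thr <- c(-Inf,
           if (length(pooled) > 1) (pooled[-1] + pooled[-length(pooled)]) / 2,
           Inf)
  sp <- sort(positive)
  sn <- sort(negative)
  # positives > t  <=>  n_pos - (count <= t)
  sens <- 1 - findInterval(thr, sp) / length(sp)
  spec <- findInterval(thr, sn) / length(sn)
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  class(out) <- c("lncr_roc", class(out))
  out
}

#' Area under an ROC curve
#'
#' Trapezoidal area under sensitivity vs (1 - specificity). With the
#' midpoint threshold set this equals the Mann-Whitney probability
#' P(X_pos > X_neg) + 0.5 P(X_pos = X_neg).
#'
#' @param roc An [build_roc()] curve.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Optimum threshold of an ROC curve (closest-to-corner rule)
#'
#' Minimises `(1 - sensitivity)^2 + (1 - specificity)^2` over the curve's
#' operating points: the point closest to the perfect-classification corner
#' (sensitivity = specificity = 1). Ties are broken toward the smallest
#' threshold (the most permissive filter).
#'
#' @param roc An [build_roc()] curve.
#' @return Tibble of class `lncr_threshold` with one row: `optimum_index`,
#'   `optimum_threshold`, `objective`, `sensitivity`, `specificity`, `auc`.
#' @export
optimal_threshold <- function(roc) {
  obj <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  i_star <- which.min(obj)  # first minimum = smallest threshold
  out <- tibble(
    optimum_index = i_star,
    optimum_threshold = roc$threshold[i_star],
    objective = obj[i_star],
    sensitivity = roc$sensitivity[i_star],
    specificity = roc$specificity[i_star],
    auc = roc_auc(roc)
  )
  class(out) <- c("lncr_threshold", class(out))
  out
}

#' Derive the optimum FPKM threshold from classified transcripts
#'
#' Trains the ROC on the FPKM of complete (`"="`, positives) versus partial
#' (`"c"`, negatives) transcripts and returns the closest-to-corner optimum.
#'
#' @param x Exon table with `fpkm`.
#' @param classification Output of [classify_transcripts()] for `x`.
#' @return As [optimal_threshold()], with the ROC curve attached as
#'   attribute `"roc"`.
#' @export
derive_fpkm_threshold <- function(x, classification) {
  s <- transcript_summary(x)
  s <- left_join(s, classification[, c("transcript_id", "class_code")],
                 by = "transcript_id")
  pos <- s$fpkm[s$class_code %in% "="]
  neg <- s$fpkm[s$class_code %in% "c"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("deriving an FPKM threshold needs both '=' and 'c' transcripts with FPKM")
  }
  if (anyNA(pos) || anyNA(neg)) {
    abort("deriving an FPKM threshold needs FPKM on every '='/'c' transcript")
  }
  roc <- build_roc(pos, neg)
  res <- optimal_threshold(roc)
  attr(res, "roc") <- roc
  res
}

#' Filter transcripts by expression
#'
#' Retains transcripts with `fpkm >= cutoff` (inclusive).
#'
#' @param x Exon table; every transcript must carry an FPKM value.
#' @param cutoff FPKM cutoff.
#' @return Exon table of retained transcripts.
#' @export
filter_by_fpkm <- function(x, cutoff) {
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  if (anyNA(s$fpkm)) {
    abort(paste0("transcript '", s$transcript_id[which(is.na(s$fpkm))[1]],
                 "' has no FPKM value"))
  }
  keep <- s$transcript_id[s$fpkm >= cutoff]
  x[x$transcript_id %in% keep, ]
}

#' Select the high-quality assembly set
#'
#' The high-quality set is the union of (a) assemblies that completely match
#' the reference (`"="`), kept without any expression requirement, and (b)
#' novel assemblies (class code not in `{"=", "c"}`) that satisfy
#' `fpkm >= cutoff`. Partial (`"c"`) assemblies are always excluded.
#'
#' @param x Exon table.
#' @param classification Output of [classify_transcripts()] for `x`.
#' @param cutoff FPKM cutoff for the novel assemblies.
#' @return Exon table of high-quality transcripts.
#' @export
select_high_quality <- function(x, classification, cutoff) {
  x <- as_transcripts(x)
  s <- left_join(transcript_summary(x),
                 classification[, c("transcript_id", "class_code")],
                 by = "transcript_id")
  novel <- s[!(s$class_code %in% c("=", "c")), ]
  if (anyNA(novel$fpkm)) {
    abort(paste0("transcript '", novel$transcript_id[which(is.na(novel$fpkm))[1]],
                 "' has no FPKM value"))
  }
  keep <- c(s$transcript_id[s$class_code %in% "="],
            novel$transcript_id[novel$fpkm >= cutoff])
  x[x$transcript_id %in% keep, ]
}

#' Simulate FPKM samples for complete and partial assemblies
#'
#' Draws log-normal FPKM values for the two assembly classes. The defaults
#' emulate the separability observed between complete and partial
#' transcripts in real assemblies: natural-scale means 29.67 and 4.86, and a
#' common `sdlog` of 1.638, the equal-variance log-normal spread for which
#' the FPKM ROC has AUC 0.7825.
#'
#' @param n_complete,n_partial Sample sizes.
#' @param mean_complete,mean_partial Natural-scale means.
#' @param sdlog Common log-scale standard deviation.
#' @return Tibble `fpkm`, `class` (`"complete"`/`"partial"`).
#' @export
simulate_fpkm <- function(n_complete, n_partial,
                          mean_complete = 29.67, mean_partial = 4.86,
                          sdlog = 1.638) {
  tibble(
    fpkm = c(rlnorm(n_complete, log(mean_complete) - sdlog^2 / 2, sdlog),
             rlnorm(n_partial, log(mean_partial) - sdlog^2 / 2, sdlog)),
    class = rep(c("complete", "partial"), c(n_complete, n_partial))
  )
}
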