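# GTF reading/writing and the exon-table representation.
#
# The package currency is a tidy exon table: one row per exon with columns
#   transcript_id, gene_id, chrom, start, end, strand, fpkm, source, extra
# Coordinates are 1-based inclusive (GTF convention) at every interface.

.EXON_COLS <- c("transcript_id", "gene_id", "chrom", "start", "end",
                "strand", "fpkm", "source", "extra")

#' Validate and normalise an exon table
#'
#' Checks the invariants every downstream function relies on: required
#' columns present, `start >= 1`, `end >= start`, exons of one transcript on a
#' single chromosome and strand, and non-overlapping exons per transcript
#' (overlap is an error, not a merge -- assemblers emit disjoint exons, so an
#' overlap signals upstream corruption). Exons are returned sorted by
#' transcript and start coordinate.
#'
#' @param x A data frame with at least `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` columns; `fpkm`, `source`, `extra` are added as
#'   `NA`/empty when missing.
#' @return A tibble with the canonical exon-table columns, sorted.
#' @export
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(101L, 301L), end = c(200L, 400L), strand = "+"
#' )
#' as_transcripts(tx)
as_transcripts <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(c("transcript_id", "gene_id", "chrom", "start", "end", "strand"),
                          names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("exon table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"fpkm" %in% names(x)) x$fpkm <- NA_real_
  if (!"source" %in% names(x)) x$source <- "lncscan"
  if (!"extra" %in% names(x)) x$extra <- ""
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$fpkm <- as.numeric(x$fpkm)
  x <- x[, c(.EXON_COLS, setdiff(names(x), .EXON_COLS))]
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$start)) || any(is.na(x$end))) abort("exon coordinates must be numeric")
  if (any(x$start < 1)) abort("exon start coordinates must be >= 1")
  if (any(x$end < x$start)) {
    bad <- x$transcript_id[which(x$end < x$start)[1]]
    abort(paste0("exon end < start for transcript '", bad, "'"))
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  x <- arrange(x, .data$transcript_id, .data$start, .data$end)
  per <- split(seq_len(nrow(x)), x$transcript_id)
  for (idx in per) {
    if (length(unique(x$chrom[idx])) > 1L || length(unique(x$strand[idx])) > 1L) {
      abort(paste0("transcript '", x$transcript_id[idx[1]],
                   "' has exons on multiple chromosomes or strands"))
    }
    if (length(idx) > 1L) {
      s <- x$start[idx]; e <- x$end[idx]
      if (any(s[-1] <= e[-length(e)])) {
        abort(paste0("transcript '", x$transcript_id[idx[1]],
                     "' has overlapping or duplicated exons"))
      }
    }
  }
  x
}

.parse_attr <- function(attrs, key) {
  # accepts both `key "value";` and `key value;`
  pattern <- paste0("(^|;)\\s*", key, "\\s+\"?([^\";]*)\"?\\s*(;|$)")
  m <- regexec(pattern, attrs)
  vapply(regmatches(attrs, m), function(g) {
    if (length(g) >= 3) g[3] else NA_character_
  }, character(1))
}

.strip_attrs <- function(attrs, keys) {
  for (key in keys) {
    attrs <- gsub(paste0("(^|;)\\s*", key, "\\s+\"?[^\";]*\"?\\s*(?=;|$)"),
                  "\\1", attrs, perl = TRUE)
  }
  attrs <- gsub(";\\s*;", ";", attrs)
  trimws(gsub("^\\s*;|;\\s*$", "", attrs))
}

#' Read transcript structures from a GTF file
#'
#' Reads a 9-column GTF (Cufflinks dialect: `transcript` and `exon` feature
#' rows carrying `transcript_id`/`gene_id` attributes). Transcript structures
#' are taken from `exon` rows only; other feature types contribute attributes
#' (notably `FPKM`) but not structure. Attribute values may be quoted or
#' unquoted; attributes not lifted into columns are preserved verbatim in the
#' `extra` column so that [write_gtf()] round-trips them.
#'
#' @param path Path to a GTF file (plain or gzipped).
#' @param attributes Character vector of attribute keys to lift into columns;
#'   `"FPKM"` (the default) is parsed as a number.
#' @return Exon table (see [as_transcripts()]); one block of rows per
#'   distinct `transcript_id`, exons sorted by start.
#' @export
read_gtf <- function(path, attributes = "FPKM") {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_transcripts(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated columns, found %d",
                  lineno[bad], nf[bad]))
  }
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed GTF line %d: non-numeric coordinates", lineno[bad]))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    abort(sprintf("malformed GTF line %d: end (%d) < start (%d)",
                  lineno[bad], end[bad], start[bad]))
  }
  attrs <- mat[, 9]
  tid <- .parse_attr(attrs, "transcript_id")
  gid <- .parse_attr(attrs, "gene_id")
  is_exon <- mat[, 3] == "exon"
  if (any(is_exon & is.na(tid))) {
    bad <- which(is_exon & is.na(tid))[1]
    abort(sprintf("malformed GTF line %d: exon without transcript_id attribute", lineno[bad]))
  }

  # requested attributes: first non-missing value over all rows of a transcript
  lifted <- list()
  for (key in attributes) {
    val <- .parse_attr(attrs, key)
    ok <- !is.na(tid) & !is.na(val)
    lifted[[key]] <- vapply(split(val[ok], tid[ok]), `[`, character(1), 1L)
  }

  ex <- which(is_exon)
  if (length(ex) > 0) {
    dup <- duplicated(paste(tid[ex], mat[ex, 1], start[ex], end[ex], sep = "\r"))
    if (any(dup)) {
      bad <- ex[which(dup)[1]]
      abort(sprintf("malformed GTF line %d: duplicate exon for transcript '%s'",
                    lineno[bad], tid[bad]))
    }
  }
  out <- tibble(
    transcript_id = tid[ex],
    gene_id = ifelse(is.na(gid[ex]), "", gid[ex]),
    chrom = mat[ex, 1],
    start = start[ex],
    end = end[ex],
    strand = ifelse(mat[ex, 7] %in% c("+", "-"), mat[ex, 7], "."),
    source = mat[ex, 2],
    extra = .strip_attrs(attrs[ex], c("transcript_id", "gene_id", attributes))
  )
  fp <- lifted[["FPKM"]]
  out$fpkm <- if (!is.null(fp)) suppressWarnings(as.numeric(fp[out$transcript_id])) else NA_real_
  for (key in setdiff(attributes, "FPKM")) {
    val <- lifted[[key]][out$transcript_id]
    out[[key]] <- unname(ifelse(is.na(val), NA_character_, val))
  }
  as_transcripts(out)
}

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, trim = TRUE, scientific = FALSE, digits = 15)
  }, character(1))
}

#' Write an exon table to a GTF file
#'
#' Emits one `transcript` row (the transcript span) followed by its `exon`
#' rows, with `gene_id`, `transcript_id`, `FPKM` (when present) and any
#' preserved `extra` attribute text. `read_gtf(write_gtf(x))` reproduces
#' structures, ids, strand and FPKM.
#'
#' @param x Exon table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  x <- as_transcripts(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(x) == 0) return(invisible(path))
  fp <- .fmt_num(x$fpkm)
  base_attr <- paste0("gene_id \"", x$gene_id, "\"; transcript_id \"", x$transcript_id, "\";",
                      ifelse(nzchar(fp), paste0(" FPKM \"", fp, "\";"), ""),
                      ifelse(nzchar(x$extra), paste0(" ", x$extra,
                                                     ifelse(grepl(";\\s*$", x$extra), "", ";")), ""))
  per <- split(seq_len(nrow(x)), x$transcript_id)
  # preserve first-appearance transcript order
  per <- per[unique(x$transcript_id)]
  out <- character(0)
  for (idx in per) {
    i1 <- idx[1]
    tx_line <- paste(x$chrom[i1], x$source[i1], "transcript",
                     min(x$start[idx]), max(x$end[idx]), ".", x$strand[i1], ".",
                     base_attr[i1], sep = "\t")
    exon_lines <- paste(x$chrom[idx], x$source[idx], "exon",
                        x$start[idx], x$end[idx], ".", x$strand[idx], ".",
                        base_attr[idx], sep = "\t")
    out <- c(out, tx_line, exon_lines)
  }
  writeLines(out, con)
  invisible(path)
}

#' Summaries of a GTF / exon table
#'
#' @param x Exon table or GTF path.
#' @return A tibble with one row: transcript, gene and exon counts plus
#'   exonic-length distribution summaries.
#' @export
gtf_stats <- function(x) {
  if (is.character(x)) x <- read_gtf(x)
  x <- as_transcripts(x)
  s <- transcript_summary(x)
  tibble(
    n_transcripts = nrow(s),
    n_genes = length(unique(s$gene_id)),
    n_exons = nrow(x),
    n_multi_exon = sum(s$n_exons > 1),
    mean_exons = if (nrow(s)) mean(s$n_exons) else NA_real_,
    median_length = if (nrow(s)) median(s$exonic_length) else NA_real_,
    mean_length = if (nrow(s)) mean(s$exonic_length) else NA_real_,
    min_length = if (nrow(s)) min(s$exonic_length) else NA_integer_,
    max_length = if (nrow(s)) max(s$exonic_length) else NA_integer_
  )
}
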