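# Self-contained synthetic datasets with planted ground truth: a toy genome,
# a reference annotation, assembled-query transcripts covering every class
# code, FPKM values, a PhyloCSF score file and a Pfam domtblout -- everything
# the pipeline consumes, generated deterministically from a seed and
# self-verified (planted class codes and ORF lengths are re-derived with the
# package's own statistics before the fixture is returned).

#' Fixture specification
#'
#' Counts and distribution parameters for [generate_fixture()]. The defaults
#' describe a 200-transcript assembly: complete matches and contained
#' partials (the ROC training classes), low-FPKM artefacts, mRNA-like novel
#' transcripts that must be caught by the ORF, PhyloCSF or Pfam filter, and
#' lncRNA-like novel transcripts across the five candidate codes. FPKM is
#' log-normal per class (see [simulate_fpkm()] for the complete/partial
#' parameterisation); novel plants are redrawn to stay at or above
#' `novel_fpkm_floor` so expression never confounds the planted truth, and
#' artefacts are uniform below the expression cutoff.
#'
#' @param seed Integer seed; identical spec + seed gives byte-identical files.
#' @param n_chrom Number of toy chromosomes.
#' @param n_complete,n_contained Counts of `"="` and `"c"` plants.
#' @param n_lnc_per_code lncRNA-like plants per candidate code (i/j/o/u/x).
#' @param n_mrna_orf,n_mrna_phylocsf,n_mrna_pfam mRNA-like novel plants
#'   killed by, respectively, a planted ORF >= 300 nt, a positive PhyloCSF
#'   score, and a significant Pfam hit.
#' @param n_low_fpkm Intergenic artefact plants below the expression cutoff.
#' @param mean_complete,mean_partial,sdlog FPKM log-normal parameters.
#' @param novel_fpkm_floor Minimum FPKM for novel (lncRNA/mRNA) plants.
#' @param artifact_fpkm_max Maximum FPKM for low-expression artefacts.
#' @param pfam_evalue_sig Significant-hit E-value range (log10 bounds).
#' @return A list of class `lncscan_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_chrom = 3L,
                         n_complete = 80L,
                         n_contained = 50L,
                         n_lnc_per_code = 4L,
                         n_mrna_orf = 10L,
                         n_mrna_phylocsf = 5L,
                         n_mrna_pfam = 5L,
                         n_low_fpkm = 30L,
                         mean_complete = 29.67,
                         mean_partial = 4.86,
                         sdlog = 1.638,
                         novel_fpkm_floor = 5,
                         artifact_fpkm_max = 1.8,
                         pfam_evalue_sig = c(-30, -8)) {
  counts <- c(n_complete, n_contained, n_lnc_per_code, n_mrna_orf,
              n_mrna_phylocsf, n_mrna_pfam, n_low_fpkm)
  if (any(counts < 0)) abort("fixture counts must be >= 0")
  structure(as.list(environment()), class = "lncscan_fixture_spec")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Remove every occurrence of `pattern` by mutating its middle base.
.scrub <- function(s, pattern, replacement_mid) {
  repeat {
    hits <- gregexpr(pattern, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(s)
    for (h in hits) substr(s, h + 1L, h + 1L) <- replacement_mid
  }
}

#' Plant a sequence with an exact longest-ORF length
#'
#' Builds a random nucleotide sequence whose longest ATG-anchored ORF (per
#' [find_longest_orf()] semantics) is exactly `orf_nt_length` (0 = no ORF at
#' all). The background is scrubbed of ATG, the ORF body uses A-free codons
#' (which can contain neither a start nor a stop), and the planted ORF is
#' sealed with a TAA stop; the result is self-verified before it is
#' returned.
#'
#' @param sequence_length Total sequence length; must allow
#'   `orf_nt_length + 3` planted bases.
#' @param orf_nt_length Target ORF length in nt (multiple of 3, excluding
#'   the stop codon), or 0.
#' @param seed Optional seed for reproducibility of a single call.
#' @return Nucleotide string of length `sequence_length`.
#' @export
plant_orf <- function(sequence_length, orf_nt_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (orf_nt_length %% 3 != 0) abort("orf_nt_length must be a multiple of 3")
  if (orf_nt_length > 0 && orf_nt_length + 3 > sequence_length) {
    abort("sequence_length too small for the requested ORF")
  }
  safe_codons <- apply(expand.grid(c("C", "G", "T"), c("C", "G", "T"),
                                   c("C", "G", "T")), 1, paste, collapse = "")
  for (attempt in 1:20) {
    s <- .scrub(.random_bases(sequence_length), "ATG", "C")
    if (orf_nt_length > 0) {
      core <- paste0("ATG",
                     paste(sample(safe_codons, orf_nt_length / 3 - 1,
                                  replace = TRUE), collapse = ""),
                     "TAA")
      start <- sample.int(sequence_length - nchar(core) + 1L, 1L)
      substr(s, start, start + nchar(core) - 1L) <- core
      # a boundary-crossing ATG can only involve bases outside the core
      repeat {
        hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
        spurious <- hits[hits != -1 & hits != start]
        if (length(spurious) == 0) break
        for (h in spurious) {
          mut <- setdiff(h:(h + 2L), start:(start + nchar(core) - 1L))[1]
          substr(s, mut, mut) <- "C"
        }
      }
    }
    got <- find_longest_orf(s)
    if (got$nt_length == orf_nt_length) return(s)
  }
  abort("failed to plant the requested ORF (constraint infeasible)")
}

.exon_df <- function(tid, gid, chrom, starts, ends, strand, fpkm = NA_real_,
                     source = "fixture") {
  tibble(transcript_id = tid, gene_id = gid, chrom = chrom,
         start = as.integer(starts), end = as.integer(ends),
         strand = strand, fpkm = fpkm, source = source, extra = "")
}

# A reference gene model: 3-4 exons; the first intron is stretched when an
# intronic plant must fit inside it.
.make_gene <- function(chrom, at, strand, long_first_intron = FALSE) {
  n_ex <- sample(3:4, 1)
  ex_len <- sample(150:350, n_ex, replace = TRUE)
  in_len <- sample(300:700, n_ex - 1, replace = TRUE)
  if (long_first_intron) in_len[1] <- sample(1600:2200, 1)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- at
  for (k in seq_len(n_ex)) {
    starts[k] <- pos
    ends[k] <- pos + ex_len[k] - 1L
    pos <- ends[k] + (if (k < n_ex) in_len[k] else 0L) + 1L
  }
  list(starts = starts, ends = ends, strand = strand, chrom = chrom,
       span = c(starts[1], ends[n_ex]))
}

.trunc_lnorm <- function(n, mean_nat, sdlog, floor = -Inf, ceiling = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rlnorm(1, log(mean_nat) - sdlog^2 / 2, sdlog)
      if (v >= floor && v <= ceiling) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Lays out reference genes along toy chromosomes and plants one query
#' transcript per slot with a known class code, FPKM stratum, longest-ORF
#' length and coding-potential evidence. Every planted class code and ORF
#' length is re-derived with [classify_transcripts()] /
#' [find_longest_orf()] before returning; a mismatch is an error, so the
#' fixture is a trustworthy oracle for pipeline tests.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `reference.gtf`, `query.gtf`, `phylocsf.tsv`, `pfam_domtbl.txt`,
#'   `truth.tsv` and returns their paths in `$files`.
#' @return A list of class `lncscan_fixture`: `query`, `reference` (exon
#'   tables), `genome` (named character vector), `phylocsf`, `pfam`
#'   (tibbles), `truth` (transcript_id, plant_class, intended_class_code,
#'   fpkm, orf_nt, intended_final), `spec`, and `files` when written.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "lncscan_fixture_spec"))
  set.seed(spec$seed)

  plants <- c(rep("complete", spec$n_complete),
              rep("contained", spec$n_contained),
              rep(paste0("lnc_", c("i", "j", "o", "u", "x")),
                  each = spec$n_lnc_per_code),
              rep("mrna_orf", spec$n_mrna_orf),
              rep("mrna_phylocsf", spec$n_mrna_phylocsf),
              rep("mrna_pfam", spec$n_mrna_pfam),
              rep("low_fpkm", spec$n_low_fpkm))
  n_plants <- length(plants)
  if (n_plants == 0) {
    empty <- as_transcripts(.exon_df(character(0), character(0), character(0),
                                     integer(0), integer(0), character(0)))
    fx <- structure(list(
      query = empty, reference = empty,
      genome = setNames(character(0), character(0)),
      phylocsf = tibble(transcript_id = character(), score = numeric(),
                        status = character()),
      pfam = tibble(transcript_id = character(), domain_name = character(),
                    domain_accession = character(), full_evalue = numeric(),
                    independent_evalue = numeric(), bit_score = numeric()),
      truth = tibble(transcript_id = character(), plant_class = character(),
                     intended_class_code = character(), orf_nt = integer(),
                     intended_final = character(), fpkm = numeric()),
      spec = spec, files = NULL), class = "lncscan_fixture")
    if (!is.null(out_dir)) fx <- .write_fixture(fx, out_dir)
    return(fx)
  }
  plants <- sample(plants)  # shuffle genomic order of plant classes

  chrom_names <- paste0("chr", seq_len(spec$n_chrom))
  cursor <- setNames(rep(1000L, spec$n_chrom), chrom_names)
  ref_rows <- list(); qry_rows <- list(); truth_rows <- list()
  orf_targets <- integer(0)  # per query transcript needing a planted ORF

  needs_ref <- c("complete", "contained", "lnc_i", "lnc_j", "lnc_o", "lnc_x")
  ref_id <- 0L

  for (i in seq_len(n_plants)) {
    cls <- plants[i]
    chrom <- chrom_names[(i - 1L) %% spec$n_chrom + 1L]
    at <- cursor[chrom] + sample(600:1200, 1)
    strand <- sample(c("+", "-"), 1)
    qid <- sprintf("TQ%04d", i)
    qgene <- sprintf("GQ%04d", i)
    intended <- NULL; q <- NULL; orf_nt <- NA_integer_

    if (cls %in% needs_ref) {
      ref_id <- ref_id + 1L
      g <- .make_gene(chrom, at, strand, long_first_intron = cls == "lnc_i")
      rid <- sprintf("TR%04d", ref_id)
      ref_rows[[length(ref_rows) + 1L]] <-
        .exon_df(rid, sprintf("GR%04d", ref_id), chrom, g$starts, g$ends, strand)
      n_ex <- length(g$starts)
      if (cls == "complete") {
        qs <- g$starts; qe <- g$ends
        qs[1] <- qs[1] + sample(0:40, 1)
        qe[n_ex] <- qe[n_ex] - sample(0:40, 1)
        q <- .exon_df(qid, qgene, chrom, qs, qe, strand)
        intended <- "="
      } else if (cls == "contained") {
        qs <- g$starts[1:2]; qe <- g$ends[1:2]
        qs[1] <- qs[1] + sample(10:60, 1)
        qe[2] <- qe[2] - sample(10:60, 1)
        q <- .exon_df(qid, qgene, chrom, qs, qe, strand)
        intended <- "c"
      } else if (cls == "lnc_i") {
        base <- g$ends[1] + 1L  # first intron start
        qs <- c(base + 100L, base + 370L)
        qe <- c(base + 249L, base + 519L)
        q <- .exon_df(qid, qgene, chrom, qs, qe, strand)
        intended <- "i"
      } else if (cls == "lnc_j") {
        qs <- c(g$span[1] - sample(150:250, 1), g$starts[2])
        qe <- c(g$ends[1], g$starts[2] + sample(100:140, 1))
        q <- .exon_df(qid, qgene, chrom, qs, qe, strand)
        intended <- "j"
      } else {  # lnc_o / lnc_x
        e1s <- g$starts[1] - sample(80:140, 1)
        e1e <- g$starts[1] + sample(60:100, 1)
        e2s <- e1e + sample(150:250, 1)
        if (e2s == g$starts[2]) e2s <- e2s + 3L
        e2e <- e2s + sample(120:180, 1)
        qstrand <- if (cls == "lnc_x") setdiff(c("+", "-"), strand) else strand
        q <- .exon_df(qid, qgene, chrom, c(e1s, e2s), c(e1e, e2e), qstrand)
        intended <- if (cls == "lnc_x") "x" else "o"
      }
    } else {
      # intergenic plants: u-code lncRNAs, mRNA-like novels, artefacts
      if (cls == "mrna_orf") {
        ex_len <- sample(250:350, 3, replace = TRUE)
      } else {
        ex_len <- sample(140:220, 2, replace = TRUE)
      }
      in_len <- sample(200:500, length(ex_len) - 1, replace = TRUE)
      starts <- integer(0); ends <- integer(0); pos <- at
      for (k in seq_along(ex_len)) {
        starts <- c(starts, pos); ends <- c(ends, pos + ex_len[k] - 1L)
        pos <- ends[k] + (if (k < length(ex_len)) in_len[k] else 0L) + 1L
      }
      q <- .exon_df(qid, qgene, chrom, starts, ends, strand)
      intended <- "u"
    }

    qry_rows[[length(qry_rows) + 1L]] <- q
    exonic <- sum(q$end - q$start + 1L)

    # ORF target for every plant that can reach the ORF step
    if (startsWith(cls, "lnc_")) {
      orf_nt <- sample(c(0L, 45L, 120L, 210L, 270L), 1)
    } else if (cls == "mrna_orf") {
      orf_nt <- 3L * sample(100:((exonic - 3L) %/% 3L), 1)
    } else if (cls %in% c("mrna_phylocsf", "mrna_pfam")) {
      orf_nt <- sample(c(150L, 210L, 270L), 1)
    }
    orf_targets[qid] <- orf_nt

    truth_rows[[length(truth_rows) + 1L]] <- tibble(
      transcript_id = qid, plant_class = cls, intended_class_code = intended,
      orf_nt = orf_nt,
      intended_final = switch(cls,
        complete = "high_quality_known",
        contained = "filtered_partial",
        low_fpkm = "filtered_expression",
        mrna_orf = "filtered_orf",
        mrna_phylocsf = "filtered_phylocsf",
        mrna_pfam = "filtered_pfam",
        "novel_lncRNA")
    )
    all_ends <- c(q$end, if (cls %in% needs_ref) g$span[2] else integer(0))
    cursor[chrom] <- max(all_ends)
  }

  reference <- as_transcripts(bind_rows(ref_rows))
  query <- as_transcripts(bind_rows(qry_rows))
  truth <- bind_rows(truth_rows)
  truth <- truth[match(sort(truth$transcript_id), truth$transcript_id), ]

  # FPKM per plant class
  s <- spec
  fpkm_for <- function(cls, n) {
    switch(cls,
      complete = .trunc_lnorm(n, s$mean_complete, s$sdlog),
      contained = .trunc_lnorm(n, s$mean_partial, s$sdlog),
      low_fpkm = runif(n, 0.05, s$artifact_fpkm_max),
      .trunc_lnorm(n, s$mean_complete, s$sdlog, floor = s$novel_fpkm_floor))
  }
  truth$fpkm <- NA_real_
  for (cls in unique(truth$plant_class)) {
    idx <- which(truth$plant_class == cls)
    truth$fpkm[idx] <- round(fpkm_for(cls, length(idx)), 4)
  }
  query$fpkm <- truth$fpkm[match(query$transcript_id, truth$transcript_id)]

  # genome: random background, planted spliced sequences written in place
  genome <- setNames(character(spec$n_chrom), chrom_names)
  chrom_len <- pmax(cursor + 2000L, 5000L)
  chars <- lapply(chrom_names, function(cn) {
    strsplit(.random_bases(chrom_len[cn]), "")[[1]]
  })
  names(chars) <- chrom_names
  qsum <- transcript_summary(query)
  for (i in seq_len(nrow(truth))) {
    tid <- truth$transcript_id[i]
    target <- truth$orf_nt[i]
    if (is.na(target)) next
    exonic <- qsum$exonic_length[qsum$transcript_id == tid]
    sense <- plant_orf(exonic, target)
    genomic <- if (qsum$strand[qsum$transcript_id == tid] == "-") .revcomp(sense) else sense
    ex <- query[query$transcript_id == tid, ]
    bases <- strsplit(genomic, "")[[1]]
    off <- 0L
    for (k in seq_len(nrow(ex))) {
      w <- ex$end[k] - ex$start[k] + 1L
      chars[[ex$chrom[k]]][ex$start[k]:ex$end[k]] <- bases[(off + 1L):(off + w)]
      off <- off + w
    }
  }
  for (cn in chrom_names) genome[cn] <- paste(chars[[cn]], collapse = "")

  # PhyloCSF records for every novel-candidate plant
  cand <- truth[truth$plant_class %in% c(paste0("lnc_", c("i", "j", "o", "u", "x")),
                                         "mrna_orf", "mrna_phylocsf", "mrna_pfam"), ]
  phylo <- NULL
  if (nrow(cand) > 0) {
    score <- numeric(nrow(cand)); status <- character(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (startsWith(cand$plant_class[i], "lnc_") || cand$plant_class[i] == "mrna_pfam") {
        if (startsWith(cand$plant_class[i], "lnc_") && cand$orf_nt[i] < 75) {
          score[i] <- NA_real_; status[i] <- "orf_too_short"
        } else {
          score[i] <- round(runif(1, -60, -2), 2); status[i] <- "scored"
        }
      } else {
        score[i] <- round(runif(1, 20, 400), 2); status[i] <- "scored"
      }
    }
    phylo <- tibble(transcript_id = cand$transcript_id, score = score,
                    status = status)
  } else {
    phylo <- tibble(transcript_id = character(), score = numeric(),
                    status = character())
  }

  # Pfam hits: significant for mrna plants, weak for a third of lncRNA plants
  pf_rows <- list()
  for (i in seq_len(nrow(cand))) {
    cls <- cand$plant_class[i]
    if (cls %in% c("mrna_pfam", "mrna_orf")) {
      ev <- 10^runif(1, spec$pfam_evalue_sig[1], spec$pfam_evalue_sig[2])
      pf_rows[[length(pf_rows) + 1L]] <- tibble(
        transcript_id = cand$transcript_id[i],
        domain_name = sample(c("zf-C2H2", "Pkinase", "WD40", "Globin"), 1),
        domain_accession = sprintf("PF%05d.1", sample(1:20000, 1)),
        full_evalue = ev, independent_evalue = ev,
        bit_score = round(runif(1, 30, 300), 1))
    } else if (startsWith(cls, "lnc_") && runif(1) < 0.3) {
      ev <- 10^runif(1, -1, 0.7)  # always insignificant
      pf_rows[[length(pf_rows) + 1L]] <- tibble(
        transcript_id = cand$transcript_id[i],
        domain_name = "DUF1234",
        domain_accession = sprintf("PF%05d.1", sample(1:20000, 1)),
        full_evalue = ev, independent_evalue = ev,
        bit_score = round(runif(1, 5, 15), 1))
    }
  }
  pfam <- if (length(pf_rows)) bind_rows(pf_rows) else
    tibble(transcript_id = character(), domain_name = character(),
           domain_accession = character(), full_evalue = numeric(),
           independent_evalue = numeric(), bit_score = numeric())

  fx <- structure(list(query = query, reference = reference, genome = genome,
                       phylocsf = phylo, pfam = pfam, truth = truth,
                       spec = spec, files = NULL),
                  class = "lncscan_fixture")
  .verify_fixture(fx)
  if (!is.null(out_dir)) fx <- .write_fixture(fx, out_dir)
  fx
}

# Re-derive every planted property with the package's own statistics.
.verify_fixture <- function(fx) {
  if (nrow(fx$truth) == 0) return(invisible(fx))
  cls <- classify_transcripts(fx$query, fx$reference)
  got <- cls$class_code[match(fx$truth$transcript_id, cls$transcript_id)]
  if (!identical(got, fx$truth$intended_class_code)) {
    bad <- which(got != fx$truth$intended_class_code)[1]
    abort(paste0("fixture self-check failed: ", fx$truth$transcript_id[bad],
                 " classified '", got[bad], "', planted '",
                 fx$truth$intended_class_code[bad], "'"))
  }
  planted <- fx$truth[!is.na(fx$truth$orf_nt), ]
  if (nrow(planted) > 0) {
    seqs <- spliced_sequences(
      fx$query[fx$query$transcript_id %in% planted$transcript_id, ], fx$genome)
    orfs <- longest_orfs(seqs)
    got_orf <- orfs$nt_length[match(planted$transcript_id, orfs$transcript_id)]
    if (!identical(as.integer(got_orf), as.integer(planted$orf_nt))) {
      bad <- which(got_orf != planted$orf_nt)[1]
      abort(paste0("fixture self-check failed: ", planted$transcript_id[bad],
                   " has ORF ", got_orf[bad], " nt, planted ",
                   planted$orf_nt[bad]))
    }
  }
  invisible(fx)
}

.write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    reference = file.path(out_dir, "reference.gtf"),
    query = file.path(out_dir, "query.gtf"),
    phylocsf = file.path(out_dir, "phylocsf.tsv"),
    pfam = file.path(out_dir, "pfam_domtbl.txt"),
    truth = file.path(out_dir, "truth.tsv")
  )
  writeLines(as.character(unlist(lapply(names(fx$genome), function(cn) {
    c(paste0(">", cn),
      substring(fx$genome[[cn]],
                seq(1, nchar(fx$genome[[cn]]), 70),
                pmin(seq(1, nchar(fx$genome[[cn]]), 70) + 69,
                     nchar(fx$genome[[cn]]))))
  }))), paths$genome)
  write_gtf(fx$reference, paths$reference)
  write_gtf(fx$query, paths$query)
  writeLines(c("# PhyloCSF scores (decibans)",
               vapply(seq_len(nrow(fx$phylocsf)), function(i) {
                 val <- if (fx$phylocsf$status[i] == "scored") {
                   sprintf("%.2f", fx$phylocsf$score[i])
                 } else "abort: ORF too short (< 25 aa)"
                 paste(fx$phylocsf$transcript_id[i], val, sep = "\t")
               }, character(1))), paths$phylocsf)
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ----------  ----- -------------------- ---------- -----   ------- ------ ----- --- ---  --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    vapply(seq_len(nrow(fx$pfam)), function(i) {
      h <- fx$pfam[i, ]
      sprintf("%-20s %-11s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f synthetic fixture domain",
              h$domain_name, h$domain_accession, 200L, h$transcript_id, "-",
              100L, h$full_evalue, h$bit_score, 0.1, 1L, 1L, h$full_evalue,
              h$independent_evalue, h$bit_score, 0.1, 1L, 90L, 5L, 95L, 1L,
              100L, 0.95)
    }, character(1))), paths$pfam)
  write.table(fx$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fx$files <- paths
  fx
}
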