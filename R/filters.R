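#' Filter configuration for editing-site discovery
#'
#' Bundles every threshold of the discovery cascade with its default:
#' candidate loci need an adenosine reference base with guanosine as the sole
#' alternative allele, more than 4 reads (\code{min_reads = 5}) at base
#' quality >= 25, and moderate strand bias (Fisher p >= 0.01); DNA variants
#' are accepted when homozygous A>G with more than 4 reads and calling
#' quality >= 50; the zero-confidence filter keeps sites whose DNA scores at
#' least 10 at \code{alpha = 0.05}; matched discovery prunes loci with
#' 0.5 < OR < 2.0 or Fisher p > 0.05.
#'
#' @param min_base_quality minimum base quality for a read to be counted
#'   (applied when parsing mpileup text; count tables are assumed
#'   pre-filtered).
#' @param min_reads minimum RNA read count at a candidate locus ("more than
#'   4" reads, hence 5).
#' @param strand_bias_alpha candidate loci need strand-bias p >= this value.
#' @param zero_conf_threshold minimum DNA zero-confidence score.
#' @param zero_conf_alpha confidence parameter of the binomial upper bound.
#' @param or_high,or_low odds-ratio thresholds for tumor-enriched
#'   (\code{OR >= or_high}) and normal-enriched (\code{OR <= or_low}) calls.
#' @param fisher_alpha matched-sample Fisher p must be <= this value.
#' @param dna_min_reads,dna_min_qual depth and calling-quality floor for
#'   accepted DNA variants.
#' @param include_tc_strand also admit T-reference/C-alternative loci as the
#'   antisense representation of A>G (for stranded libraries); off by
#'   default.
#' @param third_allele_tolerance maximum tolerated fraction of reads carrying
#'   an allele other than the reference or G; 0 enforces "one alternative
#'   allele" strictly.
#' @return An object of class \code{credo_filter_config} (a named list).
#' @export
filter_config <- function(min_base_quality = 25L,
                          min_reads = 5L,
                          strand_bias_alpha = 0.01,
                          zero_conf_threshold = 10.0,
                          zero_conf_alpha = 0.05,
                          or_high = 2.0,
                          or_low = 0.5,
                          fisher_alpha = 0.05,
                          dna_min_reads = 5L,
                          dna_min_qual = 50,
                          include_tc_strand = FALSE,
                          third_allele_tolerance = 0) {
  cfg <- list(min_base_quality = min_base_quality, min_reads = min_reads,
              strand_bias_alpha = strand_bias_alpha,
              zero_conf_threshold = zero_conf_threshold,
              zero_conf_alpha = zero_conf_alpha,
              or_high = or_high, or_low = or_low, fisher_alpha = fisher_alpha,
              dna_min_reads = dna_min_reads, dna_min_qual = dna_min_qual,
              include_tc_strand = isTRUE(include_tc_strand),
              third_allele_tolerance = third_allele_tolerance)
  num <- c("min_reads", "strand_bias_alpha", "zero_conf_threshold",
           "or_high", "or_low", "fisher_alpha", "dna_min_reads", "dna_min_qual")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("`", f, "` must be a single positive number", call. = FALSE)
  if (cfg$zero_conf_alpha <= 0 || cfg$zero_conf_alpha >= 1)
    stop("`zero_conf_alpha` must be in (0, 1)", call. = FALSE)
  if (!(cfg$or_low < 1 && 1 < cfg$or_high))
    stop("need or_low < 1 < or_high", call. = FALSE)
  if (cfg$third_allele_tolerance < 0 || cfg$third_allele_tolerance >= 1)
    stop("`third_allele_tolerance` must be in [0, 1)", call. = FALSE)
  structure(cfg, class = "credo_filter_config")
}

#' @export
print.credo_filter_config <- function(x, ...) {
  cat("credo filter configuration\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

count_cols <- c("a_plus", "a_minus", "c_plus", "c_minus",
                "g_plus", "g_minus", "t_plus", "t_minus")

validate_pileup <- function(pileup) {
  need <- c("chrom", "pos", "ref", count_cols)
  miss <- setdiff(need, names(pileup))
  if (length(miss))
    stop("pileup table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cnt <- as.matrix(pileup[count_cols])
  bad <- !(toupper(pileup$ref) %in% c("A", "C", "G", "T", "N")) |
    pileup$pos < 1 | apply(!is.finite(cnt) | cnt < 0, 1L, any)
  if (any(bad)) {
    warning("skipping ", sum(bad), " malformed pileup row(s): ",
            paste(utils::head(which(bad), 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "", call. = FALSE)
    pileup <- pileup[!bad, , drop = FALSE]
  }
  pileup$ref <- toupper(pileup$ref)
  pileup
}

#' Extract A-to-G candidate loci from RNA allele counts
#'
#' Keeps loci with an adenosine reference base whose only non-reference
#' allele with nonzero count is guanosine, total (ref + alt) read count of at
#' least \code{config$min_reads}, a nonzero alternative count, and
#' strand-bias p >= \code{config$strand_bias_alpha}. With
#' \code{include_tc_strand} the antisense representation (T reference, sole
#' alternative C) is also admitted, normalised to ref/alt counts with
#' strands swapped and flagged \code{strand = "antisense"}.
#'
#' @param pileup data frame with columns \code{chrom}, \code{pos},
#'   \code{ref} and per-strand base counts \code{a_plus}, \code{a_minus},
#'   ..., \code{t_minus} (reads already filtered to the base-quality floor).
#' @param config a [filter_config()].
#' @return Data frame of candidate records: \code{chrom}, \code{pos},
#'   \code{ref}, \code{strand}, stranded ref/alt counts, totals and
#'   \code{strand_bias_p}.
#' @export
extract_ag_candidates <- function(pileup, config = filter_config()) {
  pileup <- validate_pileup(pileup)
  sense <- pileup$ref == "A"
  keep <- sense
  if (config$include_tc_strand) keep <- keep | pileup$ref == "T"
  p <- pileup[keep, , drop = FALSE]
  sense <- p$ref == "A"
  rec <- data.frame(
    chrom = p$chrom, pos = p$pos, ref = p$ref,
    strand = ifelse(sense, "sense", "antisense"),
    ref_plus  = ifelse(sense, p$a_plus,  p$t_minus),
    ref_minus = ifelse(sense, p$a_minus, p$t_plus),
    alt_plus  = ifelse(sense, p$g_plus,  p$c_minus),
    alt_minus = ifelse(sense, p$g_minus, p$c_plus),
    other = ifelse(sense,
                   p$c_plus + p$c_minus + p$t_plus + p$t_minus,
                   p$a_plus + p$a_minus + p$g_plus + p$g_minus),
    stringsAsFactors = FALSE)
  rec$ref_n <- rec$ref_plus + rec$ref_minus
  rec$alt_n <- rec$alt_plus + rec$alt_minus
  total_all <- rec$ref_n + rec$alt_n + rec$other
  ok <- rec$alt_n > 0 &
    rec$other <= config$third_allele_tolerance * total_all &
    (rec$ref_n + rec$alt_n) >= config$min_reads
  rec <- rec[ok, , drop = FALSE]
  rec$strand_bias_p <- if (nrow(rec)) vapply(seq_len(nrow(rec)), function(i)
    strand_bias_p(rec$ref_plus[i], rec$ref_minus[i],
                  rec$alt_plus[i], rec$alt_minus[i]), numeric(1)) else numeric(0)
  rec <- rec[rec$strand_bias_p >= config$strand_bias_alpha, , drop = FALSE]
  rec$other <- NULL
  rownames(rec) <- NULL
  rec
}

#' Accept called DNA variants for subtraction
#'
#' From parsed variant calls keeps only homozygous-alternative A>G variants
#' supported by at least \code{config$dna_min_reads} reads ("more than 4")
#' with calling quality >= \code{config$dna_min_qual}. These are the
#' high-quality germline variants later subtracted from the RNA candidate
#' loci of the same sample.
#'
#' @param variants data frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{qual}, \code{genotype} (\code{"hom"} /
#'   \code{"het"}), \code{depth}.
#' @param config a [filter_config()].
#' @return The accepted subset, rows with missing genotype or depth dropped
#'   with a warning.
#' @export
accept_dna_variants <- function(variants, config = filter_config()) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "genotype", "depth")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- is.na(variants$genotype) | is.na(variants$depth)
  if (any(bad)) {
    warning(sum(bad), " variant record(s) without genotype or depth skipped",
            call. = FALSE)
    variants <- variants[!bad, , drop = FALSE]
  }
  keep <- toupper(variants$ref) == "A" & toupper(variants$alt) == "G" &
    variants$genotype == "hom" &
    variants$depth >= config$dna_min_reads &
    !is.na(variants$qual) & variants$qual >= config$dna_min_qual
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_key <- function(x) paste(x$chrom, x$pos, sep = ":")

#' Remove loci called as DNA variants
#'
#' Prunes from the RNA candidate records every locus whose (chromosome,
#' position) coincides with an accepted DNA A>G variant of the same sample.
#'
#' @param records candidate records (from [extract_ag_candidates()] or
#'   later stages).
#' @param variants accepted variants (from [accept_dna_variants()]).
#' @return The records whose site matches no variant.
#' @export
subtract_dna_variants <- function(records, variants) {
  if (nrow(records) == 0L || is.null(variants) || nrow(variants) == 0L)
    return(records)
  out <- records[!(site_key(records) %in% site_key(variants)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach matching DNA allele counts to RNA candidate records
#'
#' Joins the DNA pileup of the same sample to the candidate loci, extracting
#' reference (A) and alternative (G) DNA read counts; loci absent from the
#' DNA pileup get zero counts (and will fail the zero-confidence filter: no
#' reads give no confidence). For antisense records the T/C counts are used.
#'
#' @param records candidate records.
#' @param dna_pileup DNA count table in the same format as the RNA pileup.
#' @return \code{records} with added \code{dna_ref} and \code{dna_alt}
#'   columns.
#' @export
attach_dna_counts <- function(records, dna_pileup) {
  records$dna_ref <- rep(0, nrow(records))
  records$dna_alt <- rep(0, nrow(records))
  if (nrow(records) == 0L) return(records)
  dna_pileup <- validate_pileup(dna_pileup)
  idx <- match(site_key(records), site_key(dna_pileup))
  hit <- !is.na(idx)
  if (any(hit)) {
    d <- dna_pileup[idx[hit], , drop = FALSE]
    sense <- records$strand[hit] == "sense"
    records$dna_ref[hit] <- ifelse(sense, d$a_plus + d$a_minus,
                                   d$t_plus + d$t_minus)
    records$dna_alt[hit] <- ifelse(sense, d$g_plus + d$g_minus,
                                   d$c_plus + d$c_minus)
  }
  records
}

#' Zero-confidence filter on DNA read counts
#'
#' Scores each record's DNA counts with [zero_confidence_score()] (x =
#' alternative G reads, n = total DNA reads) and keeps records scoring at
#' least \code{config$zero_conf_threshold}. Records with zero DNA coverage
#' score 0 and are removed: absence of reads carries no confidence. In
#' matched mode the caller applies this per sample and keeps a site only when
#' the DNA of both the normal and the tumor sample passes.
#'
#' @param records candidate records carrying \code{dna_ref} and
#'   \code{dna_alt} columns (see [attach_dna_counts()]).
#' @param config a [filter_config()].
#' @return Passing records with a \code{dna_zero_conf} column added.
#' @export
zero_confidence_filter <- function(records, config = filter_config()) {
  if (!all(c("dna_ref", "dna_alt") %in% names(records)))
    stop("records lack DNA counts; call attach_dna_counts() first",
         call. = FALSE)
  n <- records$dna_ref + records$dna_alt
  score <- numeric(nrow(records))
  pos <- n > 0
  score[pos] <- zero_confidence_score(records$dna_alt[pos], n[pos],
                                      config$zero_conf_alpha)
  records$dna_zero_conf <- score
  out <- records[score >= config$zero_conf_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

classify_direction <- function(or_raw, fisher_p, config) {
  ifelse(!is.na(or_raw) & or_raw >= config$or_high & fisher_p <= config$fisher_alpha,
         "tumor_enriched",
  ifelse(!is.na(or_raw) & or_raw <= config$or_low & fisher_p <= config$fisher_alpha,
         "normal_enriched", "insignificant"))
}

#' Matched tumor-normal discovery at shared candidate loci
#'
#' For every locus present in both the normal and tumor record sets, builds
#' the 2x2 table with rows (normal, tumor) and columns (RNA reference
#' count, RNA alternative count), computes the raw and Haldane-corrected
#' odds ratio (oriented so OR > 1 means a higher alternative fraction in
#' tumor) and the two-sided Fisher exact p, and classifies the direction:
#' \code{tumor_enriched} when OR >= 2 and p <= 0.05, \code{normal_enriched}
#' when OR <= 0.5 and p <= 0.05, otherwise \code{insignificant} (pruned
#' downstream).
#'
#' @param normal,tumor per-sample records that passed
#'   [zero_confidence_filter()].
#' @param config a [filter_config()].
#' @return One row per shared locus: site columns, normal/tumor ref and alt
#'   counts, per-sample strand-bias p and zero-confidence scores,
#'   \code{or_raw}, \code{or_haldane}, \code{fisher_p}, \code{direction}.
#' @export
matched_discovery <- function(normal, tumor, config = filter_config()) {
  if (nrow(normal) == 1L && nrow(tumor) == 1L &&
      site_key(normal) != site_key(tumor))
    stop("normal and tumor records address different sites", call. = FALSE)
  keyn <- site_key(normal); keyt <- site_key(tumor)
  idx <- match(keyn, keyt)
  hit <- !is.na(idx)
  n <- normal[hit, , drop = FALSE]
  t <- tumor[idx[hit], , drop = FALSE]
  out <- data.frame(
    chrom = n$chrom, pos = n$pos, ref = n$ref, strand = n$strand,
    normal_ref = n$ref_n, normal_alt = n$alt_n,
    tumor_ref = t$ref_n, tumor_alt = t$alt_n,
    normal_strand_bias_p = n$strand_bias_p, tumor_strand_bias_p = t$strand_bias_p,
    normal_zero_conf = n$dna_zero_conf, tumor_zero_conf = t$dna_zero_conf,
    stringsAsFactors = FALSE)
  m <- nrow(out)
  out$or_raw <- out$or_haldane <- out$fisher_p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    tb <- c(out$normal_ref[i], out$normal_alt[i],
            out$tumor_ref[i], out$tumor_alt[i])
    out$or_raw[i] <- odds_ratio(tb)
    out$or_haldane[i] <- odds_ratio(tb, "haldane")
    out$fisher_p[i] <- fisher_exact_2x2(tb)
  }
  out$direction <- classify_direction(out$or_raw, out$fisher_p, config)
  rownames(out) <- NULL
  out
}

#' Single-sample RNA-versus-DNA discovery
#'
#' When only one sample is available, a locus is judged a confident editing
#' site when the DNA zero-confidence score is at least
#' \code{config$zero_conf_threshold} and the odds ratio of the RNA-versus-DNA
#' 2x2 table (rows RNA / DNA, columns reference / alternative, oriented so
#' OR > 1 means a higher alternative fraction in RNA) is at least
#' \code{config$or_high}. The Fisher p of the same table is reported.
#'
#' @param records candidate records with DNA counts attached.
#' @param config a [filter_config()].
#' @return The records with \code{dna_zero_conf}, \code{or_raw},
#'   \code{or_haldane}, \code{fisher_p} and logical \code{accepted} columns.
#' @export
single_sample_discovery <- function(records, config = filter_config()) {
  if (!all(c("dna_ref", "dna_alt") %in% names(records)))
    stop("records lack DNA counts; call attach_dna_counts() first",
         call. = FALSE)
  n <- records$dna_ref + records$dna_alt
  records$dna_zero_conf <- 0
  records$dna_zero_conf[n > 0] <-
    zero_confidence_score(records$dna_alt[n > 0], n[n > 0],
                          config$zero_conf_alpha)
  m <- nrow(records)
  records$or_raw <- records$or_haldane <- records$fisher_p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    # rows RNA (alt, ref) / DNA (alt, ref): cross product rises with RNA alt
    tb <- c(records$alt_n[i], records$ref_n[i],
            records$dna_alt[i], records$dna_ref[i])
    records$or_raw[i] <- odds_ratio(tb)
    records$or_haldane[i] <- odds_ratio(tb, "haldane")
    records$fisher_p[i] <- fisher_exact_2x2(tb)
  }
  records$accepted <- records$dna_zero_conf >= config$zero_conf_threshold &
    !is.na(records$or_raw) & records$or_raw >= config$or_high
  rownames(records) <- NULL
  records
}
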