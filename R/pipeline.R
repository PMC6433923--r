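# Build per-sample site records at a given set of candidate loci, pulling
# RNA counts from the sample's pileup (zero counts when the locus is absent);
# a locus may qualify as a candidate in only one of the matched samples, but
# the matched 2x2 table needs the RNA counts from both.
site_records_at <- function(rna_pileup, sites, config) {
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      strand = character(), ref_plus = integer(),
                      ref_minus = integer(), alt_plus = integer(),
                      alt_minus = integer(), ref_n = integer(),
                      alt_n = integer(), strand_bias_p = numeric(),
                      stringsAsFactors = FALSE))
  rna_pileup <- validate_pileup(rna_pileup)
  idx <- match(site_key(sites), site_key(rna_pileup))
  rec <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    strand = sites$strand,
                    ref_plus = 0L, ref_minus = 0L,
                    alt_plus = 0L, alt_minus = 0L,
                    stringsAsFactors = FALSE)
  hit <- !is.na(idx)
  if (any(hit)) {
    p <- rna_pileup[idx[hit], , drop = FALSE]
    sense <- rec$strand[hit] == "sense"
    rec$ref_plus[hit]  <- ifelse(sense, p$a_plus,  p$t_minus)
    rec$ref_minus[hit] <- ifelse(sense, p$a_minus, p$t_plus)
    rec$alt_plus[hit]  <- ifelse(sense, p$g_plus,  p$c_minus)
    rec$alt_minus[hit] <- ifelse(sense, p$g_minus, p$c_plus)
  }
  rec$ref_n <- rec$ref_plus + rec$ref_minus
  rec$alt_n <- rec$alt_plus + rec$alt_minus
  rec$strand_bias_p <- 1
  nz <- rec$alt_n > 0 & (rec$ref_n + rec$alt_n) > 0
  rec$strand_bias_p[nz] <- vapply(which(nz), function(i)
    strand_bias_p(rec$ref_plus[i], rec$ref_minus[i],
                  rec$alt_plus[i], rec$alt_minus[i]), numeric(1))
  rec
}

#' Matched tumor-normal discovery for one individual
#'
#' Runs the full per-individual cascade: extract A>G candidate loci from the
#' RNA of each matched sample, pool the candidate loci of the pair (a
#' tumor-specific editing site has no alternative reads in the normal RNA,
#' yet its normal counts are needed for the matched 2x2 table), subtract
#' each sample's accepted DNA variants, attach DNA counts and apply the
#' zero-confidence filter per sample, then test the loci surviving in both
#' samples with the matched odds-ratio / Fisher comparison. Per-stage
#' survivor counts are recorded.
#'
#' @param rna_normal,rna_tumor,dna_normal,dna_tumor pileup-format count
#'   tables of the four assays.
#' @param variants_normal,variants_tumor DNA variant-call tables (may be
#'   \code{NULL}).
#' @param config a [filter_config()].
#' @return A list with \code{candidates} (the [matched_discovery()] table,
#'   including insignificant loci) and \code{stage_counts} (data frame of
#'   stage name and surviving locus count).
#' @export
discover_individual <- function(rna_normal, rna_tumor, dna_normal, dna_tumor,
                                variants_normal = NULL, variants_tumor = NULL,
                                config = filter_config()) {
  cand_n <- extract_ag_candidates(rna_normal, config)
  cand_t <- extract_ag_candidates(rna_tumor, config)
  pool <- unique(rbind(cand_n[c("chrom", "pos", "ref", "strand")],
                       cand_t[c("chrom", "pos", "ref", "strand")]))
  stages <- data.frame(stage = "rna_candidates_union", n = nrow(pool),
                       stringsAsFactors = FALSE)
  rec_n <- site_records_at(rna_normal, pool, config)
  rec_t <- site_records_at(rna_tumor, pool, config)
  # the strand-bias criterion must hold in every sample with alternative
  # reads: an artifact-bearing sample must not re-enter via the pooled loci
  rec_n <- rec_n[rec_n$strand_bias_p >= config$strand_bias_alpha, , drop = FALSE]
  rec_t <- rec_t[rec_t$strand_bias_p >= config$strand_bias_alpha, , drop = FALSE]

  acc_n <- if (is.null(variants_normal)) NULL else
    accept_dna_variants(variants_normal, config)
  acc_t <- if (is.null(variants_tumor)) NULL else
    accept_dna_variants(variants_tumor, config)
  rec_n <- subtract_dna_variants(rec_n, acc_n)
  rec_t <- subtract_dna_variants(rec_t, acc_t)
  shared <- intersect(site_key(rec_n), site_key(rec_t))
  stages <- rbind(stages, data.frame(stage = "after_dna_variant_subtraction",
                                     n = length(shared)))

  rec_n <- zero_confidence_filter(attach_dna_counts(rec_n, dna_normal), config)
  rec_t <- zero_confidence_filter(attach_dna_counts(rec_t, dna_tumor), config)
  shared <- intersect(site_key(rec_n), site_key(rec_t))
  stages <- rbind(stages, data.frame(stage = "after_zero_confidence_both",
                                     n = length(shared)))

  cand <- matched_discovery(rec_n, rec_t, config)
  stages <- rbind(stages,
                  data.frame(stage = "significant_direction",
                             n = sum(cand$direction != "insignificant")))
  list(candidates = cand, stage_counts = stages)
}

#' Run matched discovery over a whole simulated or assembled cohort
#'
#' Applies [discover_individual()] to every individual of a cohort bundle
#' (the structure returned by [simulate_cohort()], or one assembled from
#' files with the reader functions) and stacks the per-individual calls.
#'
#' @param cohort a list with \code{individuals}, \code{rna}, \code{dna} and
#'   optionally \code{variants}, as produced by [simulate_cohort()].
#' @param config a [filter_config()].
#' @return A list with \code{candidates} (all per-individual calls, with an
#'   \code{individual} column; insignificant loci included) and
#'   \code{stage_counts} (stacked per-individual stage logs).
#' @export
discover_cohort <- function(cohort, config = filter_config()) {
  res <- lapply(cohort$individuals, function(id) {
    di <- discover_individual(
      rna_normal = cohort$rna$normal[[id]],
      rna_tumor = cohort$rna$tumor[[id]],
      dna_normal = cohort$dna$normal[[id]],
      dna_tumor = cohort$dna$tumor[[id]],
      variants_normal = cohort$variants$normal[[id]],
      variants_tumor = cohort$variants$tumor[[id]],
      config = config)
    di$candidates$individual <- rep(id, nrow(di$candidates))
    di$stage_counts$individual <- rep(id, nrow(di$stage_counts))
    di
  })
  list(candidates = do.call(rbind, lapply(res, `[[`, "candidates")),
       stage_counts = do.call(rbind, lapply(res, `[[`, "stage_counts")))
}

#' Pre-filter candidate loci of a cohort
#'
#' The union over individuals and samples of the raw A>G candidate loci
#' (before DNA-variant subtraction and the zero-confidence filter), used as
#' the baseline when assessing how much the statistical filters reduce
#' overlap with known SNPs.
#'
#' @inheritParams discover_cohort
#' @return Data frame of distinct loci (\code{chrom}, \code{pos},
#'   \code{ref}).
#' @export
prefilter_candidates <- function(cohort, config = filter_config()) {
  pieces <- lapply(cohort$individuals, function(id) {
    rbind(extract_ag_candidates(cohort$rna$normal[[id]], config)[
            c("chrom", "pos", "ref")],
          extract_ag_candidates(cohort$rna$tumor[[id]], config)[
            c("chrom", "pos", "ref")])
  })
  out <- unique(do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}
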