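#' Configuration of the synthetic matched-cohort simulator
#'
#' Defines the data-generating conditions for a matched tumor-normal cohort
#' with planted ground truth: true editing sites show alternative (G) reads
#' in RNA only; germline A/G SNPs show them in DNA and RNA of both tissues
#' (about 50\% when heterozygous, about 100\% when homozygous); strand
#' artifacts place all alternative RNA reads on one strand; sequencing error
#' sprinkles alternative reads everywhere. Per-assay depths are negative
#' binomial. The DNA variant caller is modelled with a detection sensitivity
#' below 1, producing the missed-SNP false-positive mode the zero-confidence
#' filter targets. Survival times are exponential with an elevated hazard for
#' individuals edited at designated clinically linked sites.
#'
#' @param n_individuals cohort size.
#' @param n_sites number of simulated A-reference loci.
#' @param editing_site_fraction fraction of sites that are true
#'   tumor-enriched editing sites.
#' @param normal_editing_site_fraction fraction that are true normal-enriched
#'   editing sites (edited in normal tissue instead).
#' @param snp_site_fraction fraction that are germline A/G SNP sites (half
#'   heterozygous-carrier, half homozygous-carrier sites).
#' @param artifact_site_fraction fraction that are strand-artifact sites.
#' @param tumor_edit_level,normal_edit_level mean alternative-allele fraction
#'   in RNA of the edited tissue / the other tissue at true editing sites.
#' @param rna_depth_mean,dna_depth_mean negative-binomial mean depth per
#'   assay.
#' @param depth_dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed).
#' @param seq_error_rate per-base probability of an A read being miscalled
#'   as G.
#' @param edit_carrier_prob_range range of the per-site carrier probability
#'   (drawn uniformly per editing site, so recurrence varies across sites).
#' @param snp_carrier_prob per-individual probability of carrying a planted
#'   SNP.
#' @param artifact_prob per-sample probability that an artifact site shows
#'   the artifact.
#' @param artifact_level alternative-allele fraction at expressed artifacts.
#' @param dna_caller_sensitivity probability that a carried SNP is emitted in
#'   the sample's DNA variant calls.
#' @param snp_decoy_fraction extra dbSNP positions (relative to the planted
#'   SNP count) drawn from clean background sites.
#' @param adar_shift multiplicative tumor ADAR-expression shift in edited
#'   individuals.
#' @param hazard_ratio_edited hazard multiplier for individuals edited at a
#'   clinically linked site.
#' @param baseline_hazard exponential death hazard per day.
#' @param censor_time administrative censoring time (days).
#' @param n_clinical_sites number of tumor-enriched editing sites linked to
#'   survival.
#' @param seed integer random seed; the simulation is fully deterministic
#'   given the seed.
#' @return An object of class \code{credo_sim_config}.
#' @export
sim_config <- function(n_individuals = 20L,
                       n_sites = 5000L,
                       editing_site_fraction = 0.02,
                       normal_editing_site_fraction = 0,
                       snp_site_fraction = 0.04,
                       artifact_site_fraction = 0.01,
                       tumor_edit_level = 0.4,
                       normal_edit_level = 0,
                       rna_depth_mean = 60,
                       dna_depth_mean = 60,
                       depth_dispersion = 10,
                       seq_error_rate = 0.001,
                       edit_carrier_prob_range = c(0.2, 0.8),
                       snp_carrier_prob = 0.5,
                       artifact_prob = 0.3,
                       artifact_level = 0.3,
                       dna_caller_sensitivity = 0.9,
                       snp_decoy_fraction = 0.2,
                       adar_shift = 2,
                       hazard_ratio_edited = 3,
                       baseline_hazard = 1 / 1500,
                       censor_time = 3000,
                       n_clinical_sites = 4L,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- cfg$editing_site_fraction + cfg$normal_editing_site_fraction +
    cfg$snp_site_fraction + cfg$artifact_site_fraction
  probs <- c("editing_site_fraction", "normal_editing_site_fraction",
             "snp_site_fraction", "artifact_site_fraction",
             "tumor_edit_level", "normal_edit_level", "seq_error_rate",
             "snp_carrier_prob", "artifact_prob", "artifact_level",
             "dna_caller_sensitivity")
  for (f in probs)
    if (any(cfg[[f]] < 0) || any(cfg[[f]] > 1))
      stop("`", f, "` must be in [0, 1]", call. = FALSE)
  if (fr > 1)
    stop("site-class fractions sum to more than 1", call. = FALSE)
  if (cfg$n_individuals < 1 || cfg$n_sites < 1)
    stop("need at least one individual and one site", call. = FALSE)
  if (any(cfg$edit_carrier_prob_range < 0) ||
      any(cfg$edit_carrier_prob_range > 1) ||
      diff(cfg$edit_carrier_prob_range) < 0)
    stop("`edit_carrier_prob_range` must be an increasing range in [0, 1]",
         call. = FALSE)
  structure(cfg, class = "credo_sim_config")
}

# split a count vector into plus-strand counts; artifact columns go all-plus
split_strands <- function(counts, all_plus = FALSE) {
  plus <- stats::rbinom(length(counts), counts, 0.5)
  if (any(all_plus)) plus[all_plus] <- counts[all_plus]
  cbind(plus = plus, minus = counts - plus)
}

#' Simulate a matched tumor-normal cohort with known ground truth
#'
#' Generates, deterministically given the seed, everything the discovery
#' pipeline consumes: per-individual RNA and DNA allele-count tables for the
#' normal and tumor sample, per-sample DNA variant calls, a known-SNP
#' position set (planted SNPs plus decoys), an ADAR expression matrix and a
#' survival table, together with the truth labels needed to score calls.
#'
#' @param config a [sim_config()].
#' @return A list with elements \code{config}, \code{individuals},
#'   \code{sites}, \code{rna} / \code{dna} (each
#'   \code{$normal} / \code{$tumor}: per-individual pileup-format count
#'   tables), \code{variants} (per-tissue, per-individual call tables),
#'   \code{snp_set}, \code{expression}, \code{survival} and \code{truth}
#'   (site classes, per-individual edited matrix, clinically linked sites).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "credo_sim_config"))
    stop("`config` must come from sim_config()", call. = FALSE)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  ns <- config$n_sites; ni <- config$n_individuals
  individuals <- sprintf("ind%03d", seq_len(ni))
  sites <- data.frame(
    chrom = paste0("chr", sample(1:22, ns, replace = TRUE)),
    pos = sample.int(2e8L, ns),
    ref = "A", stringsAsFactors = FALSE)

  n_et <- round(config$editing_site_fraction * ns)
  n_en <- round(config$normal_editing_site_fraction * ns)
  n_snp <- round(config$snp_site_fraction * ns)
  n_het <- floor(n_snp / 2); n_hom <- n_snp - n_het
  n_art <- round(config$artifact_site_fraction * ns)
  class <- rep("clean_background", ns)
  class[seq_len(n_et)] <- "true_editing_tumor_enriched"
  class[n_et + seq_len(n_en)] <- "true_editing_normal_enriched"
  class[n_et + n_en + seq_len(n_het)] <- "germline_snp_het"
  class[n_et + n_en + n_het + seq_len(n_hom)] <- "germline_snp_hom"
  class[n_et + n_en + n_snp + seq_len(n_art)] <- "strand_artifact"
  is_edit <- class %in% c("true_editing_tumor_enriched",
                          "true_editing_normal_enriched")
  is_snp <- class %in% c("germline_snp_het", "germline_snp_hom")
  is_art <- class == "strand_artifact"

  carrier_prob <- numeric(ns)
  carrier_prob[is_edit] <- stats::runif(sum(is_edit),
                                        config$edit_carrier_prob_range[1],
                                        config$edit_carrier_prob_range[2])
  clinical <- logical(ns)
  et_idx <- which(class == "true_editing_tumor_enriched")
  clinical[utils::head(et_idx, config$n_clinical_sites)] <- TRUE

  # per-individual status matrices (sites x individuals)
  edited <- matrix(FALSE, ns, ni)
  edited[is_edit, ] <- stats::runif(sum(is_edit) * ni) <
    carrier_prob[is_edit]
  snp_carrier <- matrix(FALSE, ns, ni)
  snp_carrier[is_snp, ] <- stats::runif(sum(is_snp) * ni) <
    config$snp_carrier_prob

  # RNA alternative fraction by tissue (before sequencing error)
  rna_frac <- function(tissue) {
    f <- matrix(0, ns, ni)
    lev_t <- if (tissue == "tumor") config$tumor_edit_level else config$normal_edit_level
    lev_n <- if (tissue == "tumor") config$normal_edit_level else config$tumor_edit_level
    f[class == "true_editing_tumor_enriched", ] <- lev_t
    f[class == "true_editing_normal_enriched", ] <- lev_n
    f[is_edit, ] <- f[is_edit, ] * edited[is_edit, ]
    f[class == "germline_snp_het", ] <- 0.5 * snp_carrier[class == "germline_snp_het", ]
    f[class == "germline_snp_hom", ] <- 1.0 * snp_carrier[class == "germline_snp_hom", ]
    f
  }
  dna_frac <- matrix(0, ns, ni)
  dna_frac[class == "germline_snp_het", ] <- 0.5 * snp_carrier[class == "germline_snp_het", ]
  dna_frac[class == "germline_snp_hom", ] <- 1.0 * snp_carrier[class == "germline_snp_hom", ]

  e <- config$seq_error_rate
  make_pileup <- function(frac, depth_mean, artifact_on) {
    lapply(seq_len(ni), function(i) {
      depth <- stats::rnbinom(ns, size = config$depth_dispersion,
                              mu = depth_mean)
      f <- frac[, i]
      f[artifact_on[, i]] <- pmax(f[artifact_on[, i]], config$artifact_level)
      p_alt <- f * (1 - e) + (1 - f) * e
      alt <- stats::rbinom(ns, depth, p_alt)
      ref <- depth - alt
      rs <- split_strands(ref)
      as <- split_strands(alt, all_plus = artifact_on[, i])
      data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                 a_plus = rs[, 1], a_minus = rs[, 2],
                 c_plus = 0L, c_minus = 0L,
                 g_plus = as[, 1], g_minus = as[, 2],
                 t_plus = 0L, t_minus = 0L, stringsAsFactors = FALSE)
    })
  }
  no_art <- matrix(FALSE, ns, ni)
  art_on <- function() {
    m <- matrix(FALSE, ns, ni)
    m[is_art, ] <- stats::runif(sum(is_art) * ni) < config$artifact_prob
    m
  }
  rna <- list(normal = make_pileup(rna_frac("normal"), config$rna_depth_mean, art_on()),
              tumor = make_pileup(rna_frac("tumor"), config$rna_depth_mean, art_on()))
  dna <- list(normal = make_pileup(dna_frac, config$dna_depth_mean, no_art),
              tumor = make_pileup(dna_frac, config$dna_depth_mean, no_art))
  names(rna$normal) <- names(rna$tumor) <- individuals
  names(dna$normal) <- names(dna$tumor) <- individuals

  # DNA variant calls: carried SNPs that the caller detects in that sample
  make_variants <- function(tissue) {
    out <- lapply(seq_len(ni), function(i) {
      pile <- dna[[tissue]][[i]]
      depth <- pile$a_plus + pile$a_minus + pile$g_plus + pile$g_minus
      called <- snp_carrier[, i] & depth > 0 &
        stats::runif(ns) < config$dna_caller_sensitivity
      idx <- which(called)
      if (length(idx) == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          qual = numeric(), genotype = character(),
                          depth = integer(), stringsAsFactors = FALSE))
      data.frame(chrom = sites$chrom[idx], pos = sites$pos[idx],
                 ref = "A", alt = "G",
                 qual = pmin(99, 3 * depth[idx]),
                 genotype = ifelse(class[idx] == "germline_snp_hom",
                                   "hom", "het"),
                 depth = depth[idx], stringsAsFactors = FALSE)
    })
    names(out) <- individuals
    out
  }
  variants <- list(normal = make_variants("normal"),
                   tumor = make_variants("tumor"))

  n_decoy <- round(config$snp_decoy_fraction * n_snp)
  decoy_pool <- which(class == "clean_background")
  decoys <- sample(decoy_pool, min(n_decoy, length(decoy_pool)))
  snp_idx <- sort(c(which(is_snp), decoys))
  snp_set <- sites[snp_idx, c("chrom", "pos")]
  rownames(snp_set) <- NULL

  edited_any <- colSums(edited) > 0
  genes <- c("ADAR", "ADARB1", "ADARB2")
  expression <- expand.grid(gene = genes, individual = individuals,
                            tissue = c("normal", "tumor"),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expression$value <- stats::rlnorm(nrow(expression), log(100), 0.3)
  shift <- expression$tissue == "tumor" &
    expression$individual %in% individuals[edited_any]
  expression$value[shift] <- expression$value[shift] * config$adar_shift

  edited_clinical <- colSums(edited[clinical, , drop = FALSE]) > 0
  hazard <- config$baseline_hazard *
    ifelse(edited_clinical, config$hazard_ratio_edited, 1)
  t_death <- stats::rexp(ni, hazard)
  survival <- data.frame(individual = individuals,
                         time = pmin(t_death, config$censor_time),
                         event = as.integer(t_death <= config$censor_time),
                         stringsAsFactors = FALSE)

  list(config = config, individuals = individuals, sites = sites,
       rna = rna, dna = dna, variants = variants, snp_set = snp_set,
       expression = expression, survival = survival,
       truth = list(
         site_class = data.frame(chrom = sites$chrom, pos = sites$pos,
                                 ref = sites$ref, class = class,
                                 carrier_prob = carrier_prob,
                                 clinical = clinical,
                                 stringsAsFactors = FALSE),
         edited = edited,
         edited_any = stats::setNames(edited_any, individuals),
         edited_clinical = stats::setNames(edited_clinical, individuals)))
}

#' Score pipeline calls against the simulation truth
#'
#' Compares a set of called sites with the planted truth labels:
#' sensitivity is the fraction of true editing sites called, the false
#' discovery rate is the fraction of calls that are not true editing sites,
#' and false calls are broken down by their generating mechanism (missed
#' SNP, sequencing error on clean background, strand artifact).
#'
#' @param called data frame of called sites (\code{chrom}, \code{pos}).
#' @param truth the \code{truth} element of a [simulate_cohort()] result.
#' @return A list with \code{sensitivity}, \code{fdr} (\code{NA} when
#'   nothing was called), \code{n_called}, \code{n_true_editing} and
#'   \code{false_calls_by_class} (named integer vector).
#' @export
score_calls <- function(called, truth) {
  tc <- truth$site_class
  key <- paste(tc$chrom, tc$pos, sep = ":")
  called_key <- unique(paste(called$chrom, called$pos, sep = ":"))
  is_called <- key %in% called_key
  is_edit <- tc$class %in% c("true_editing_tumor_enriched",
                             "true_editing_normal_enriched")
  n_true <- sum(is_edit)
  n_called <- length(called_key)
  false_mask <- is_called & !is_edit
  list(sensitivity = if (n_true) sum(is_called & is_edit) / n_true else NA_real_,
       fdr = if (n_called) sum(false_mask) / n_called else NA_real_,
       n_called = n_called,
       n_true_editing = n_true,
       false_calls_by_class = c(
         snp_driven = sum(false_mask & grepl("^germline_snp", tc$class)),
         artifact_driven = sum(false_mask & tc$class == "strand_artifact"),
         error_driven = sum(false_mask & tc$class == "clean_background")))
}
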