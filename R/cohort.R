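#' Aggregate per-individual calls into cohort sites
#'
#' Groups the significant (non-insignificant) per-individual candidate calls
#' by locus, counts the distinct individuals carrying each call (overall and
#' per direction class), and extracts the recurrent subset: sites identified
#' in more than \code{min_individuals} individuals (default 4, i.e. at least
#' 5). Duplicate (individual, site) entries are deduplicated with a warning.
#'
#' @param candidates data frame of per-individual calls with columns
#'   \code{individual}, \code{chrom}, \code{pos}, \code{ref},
#'   \code{direction}.
#' @param min_individuals recurrence threshold; a site is recurrent when
#'   \code{sample_count > min_individuals}.
#' @return A list with \code{sites} (every aggregated site: \code{chrom},
#'   \code{pos}, \code{ref}, \code{sample_count}, \code{n_tumor_enriched},
#'   \code{n_normal_enriched}, \code{individuals} comma-joined) and
#'   \code{recurrent} (the recurrent subset).
#' @export
aggregate_recurrence <- function(candidates, min_individuals = 4L) {
  need <- c("individual", "chrom", "pos", "ref", "direction")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sig <- candidates[candidates$direction != "insignificant", , drop = FALSE]
  dupkey <- paste(sig$individual, sig$chrom, sig$pos, sep = "\r")
  if (anyDuplicated(dupkey)) {
    warning("duplicate (individual, site) call(s) deduplicated", call. = FALSE)
    sig <- sig[!duplicated(dupkey), , drop = FALSE]
  }
  if (nrow(sig) == 0L) {
    empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        sample_count = integer(), n_tumor_enriched = integer(),
                        n_normal_enriched = integer(), individuals = character(),
                        stringsAsFactors = FALSE)
    return(list(sites = empty, recurrent = empty))
  }
  key <- site_key(sig)
  ord <- order(sig$chrom, sig$pos)
  sig <- sig[ord, , drop = FALSE]; key <- key[ord]
  first <- !duplicated(key)
  sites <- data.frame(
    chrom = sig$chrom[first], pos = sig$pos[first], ref = sig$ref[first],
    sample_count = as.integer(tapply(sig$individual, key, function(x)
      length(unique(x)))[key[first]]),
    n_tumor_enriched = as.integer(tapply(sig$direction == "tumor_enriched",
                                         key, sum)[key[first]]),
    n_normal_enriched = as.integer(tapply(sig$direction == "normal_enriched",
                                          key, sum)[key[first]]),
    individuals = as.character(tapply(sig$individual, key, function(x)
      paste(sort(unique(as.character(x))), collapse = ","))[key[first]]),
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(sites = sites,
       recurrent = sites[sites$sample_count > min_individuals, , drop = FALSE])
}

#' dbSNP-overlap fraction of called sites
#'
#' Fraction of sites whose (chromosome, position) lies in a known-SNP set.
#' Known SNPs act as negative controls: an editing call coinciding with a
#' catalogued germline SNP is likely a DNA variant missed by the variant
#' caller, so a better discovery set overlaps the SNP set less. The overlap
#' is an assessment only; SNP-coincident sites are never removed from the
#' results. With \code{stratify_by_recurrence} the fraction is additionally
#' reported per recurrence stratum, both for sites seen in exactly k and in
#' at least k individuals.
#'
#' @param sites cohort site table (needs \code{chrom}, \code{pos}, and
#'   \code{sample_count} for stratification).
#' @param snps data frame of SNP positions with \code{chrom} and \code{pos}
#'   (see [read_snp_positions()]).
#' @param stratify_by_recurrence also compute per-stratum fractions.
#' @return A list with \code{overall} (fraction in [0,1], \code{NA} for an
#'   empty site list) and, when stratified, \code{by_recurrence}: a data
#'   frame of \code{stratum}, \code{n_sites}, \code{pct_in_dbsnp} (exactly
#'   k) and \code{n_sites_ge}, \code{pct_in_dbsnp_ge} (at least k).
#' @export
dbsnp_overlap_rate <- function(sites, snps, stratify_by_recurrence = FALSE) {
  snp_keys <- if (is.null(snps) || nrow(snps) == 0L) character(0) else
    unique(paste(snps$chrom, snps$pos, sep = ":"))
  if (nrow(sites) == 0L)
    return(list(overall = NA_real_,
                by_recurrence = if (stratify_by_recurrence)
                  data.frame(stratum = integer(), n_sites = integer(),
                             pct_in_dbsnp = numeric(), n_sites_ge = integer(),
                             pct_in_dbsnp_ge = numeric()) else NULL))
  hit <- site_key(sites) %in% snp_keys
  out <- list(overall = mean(hit))
  if (stratify_by_recurrence) {
    if (!"sample_count" %in% names(sites))
      stop("stratification needs a `sample_count` column", call. = FALSE)
    ks <- sort(unique(sites$sample_count))
    out$by_recurrence <- do.call(rbind, lapply(ks, function(k) {
      eq <- sites$sample_count == k; ge <- sites$sample_count >= k
      data.frame(stratum = k,
                 n_sites = sum(eq), pct_in_dbsnp = 100 * mean(hit[eq]),
                 n_sites_ge = sum(ge), pct_in_dbsnp_ge = 100 * mean(hit[ge]))
    }))
  }
  out
}

#' Annotate cohort sites with overlapping gene intervals
#'
#' Attaches gene names and region classes by interval overlap against a
#' BED-derived feature table (half-open 0-based intervals, converted to the
#' sites' 1-based coordinates). Sites overlapping several features report
#' all of them, joined in name order.
#'
#' @param sites cohort site table (\code{chrom}, \code{pos}).
#' @param features data frame with \code{chrom}, \code{start}, \code{end}
#'   (BED half-open), \code{name}, and optionally \code{region}.
#' @return \code{sites} with \code{gene} and \code{region} columns
#'   (\code{""} when no feature overlaps).
#' @export
annotate_sites <- function(sites, features) {
  need <- c("chrom", "start", "end", "name")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"region" %in% names(features)) features$region <- ""
  if (is.unsorted(order(features$chrom, features$start))) {
    message("feature table sorted internally")
  }
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  sites$gene <- ""; sites$region <- ""
  for (i in seq_len(nrow(sites))) {
    # 1-based site position p overlaps half-open [start, end) iff start < p <= end
    ov <- which(features$chrom == sites$chrom[i] &
                features$start < sites$pos[i] &
                sites$pos[i] <= features$end)
    if (length(ov)) {
      ov <- ov[order(features$name[ov])]
      sites$gene[i] <- paste(features$name[ov], collapse = ";")
      sites$region[i] <- paste(features$region[ov], collapse = ";")
    }
  }
  sites
}
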