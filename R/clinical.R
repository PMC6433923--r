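#' Split the cohort into edited and non-edited groups per site
#'
#' For each cohort site, the edited group contains the individuals in which
#' the site passed all filters with a significant direction (optionally
#' restricted to tumor-enriched calls); every other cohort individual is
#' non-edited. Sites edited in nobody are flagged untestable.
#'
#' @param cohort_sites aggregated site table (see [aggregate_recurrence()]).
#' @param candidates per-individual call table with \code{individual},
#'   \code{chrom}, \code{pos}, \code{direction}.
#' @param individuals character vector of all cohort individual identifiers.
#' @param tumor_enriched_only count only tumor-enriched calls as edited.
#' @return A list (one element per site, named \code{chrom:pos}) of lists
#'   with \code{site} (a one-row data frame), \code{edited},
#'   \code{non_edited} and \code{testable}.
#' @export
assign_edited_groups <- function(cohort_sites, candidates, individuals,
                                 tumor_enriched_only = FALSE) {
  individuals <- unique(as.character(individuals))
  sig <- candidates[candidates$direction != "insignificant", , drop = FALSE]
  if (tumor_enriched_only)
    sig <- sig[sig$direction == "tumor_enriched", , drop = FALSE]
  sig_key <- site_key(sig)
  out <- lapply(seq_len(nrow(cohort_sites)), function(i) {
    key <- paste(cohort_sites$chrom[i], cohort_sites$pos[i], sep = ":")
    edited <- sort(unique(as.character(sig$individual[sig_key == key])))
    edited <- intersect(edited, individuals)
    list(site = cohort_sites[i, , drop = FALSE],
         edited = edited,
         non_edited = setdiff(individuals, edited),
         testable = length(edited) > 0L)
  })
  names(out) <- paste(cohort_sites$chrom, cohort_sites$pos, sep = ":")
  out
}

#' Combine several sites into a single editing marker
#'
#' An individual is called edited by the combined marker when it is edited
#' at at least one member site, so the marker's edited set is the union of
#' the member sites' edited sets. Used when individually infrequent sites
#' are pooled for survival analysis.
#'
#' @param assignments list of per-site assignments from
#'   [assign_edited_groups()] (the members of the marker).
#' @param individuals all cohort individual identifiers.
#' @return A list with \code{member_sites}, \code{edited},
#'   \code{non_edited} and \code{testable}.
#' @export
combined_marker <- function(assignments, individuals) {
  individuals <- unique(as.character(individuals))
  edited <- sort(unique(unlist(lapply(assignments, `[[`, "edited"))))
  edited <- intersect(edited, individuals)
  list(member_sites = names(assignments),
       edited = edited,
       non_edited = setdiff(individuals, edited),
       testable = length(edited) > 0L)
}

#' Flag ADAR differential expression within the edited group
#'
#' For each ADAR-family gene, runs Welch's test of tumor versus normal
#' expression restricted to the edited individuals of a site; the site is
#' flagged differentially expressed when any gene reaches \code{p < alpha}.
#' Per-gene p-values are always returned so other aggregation rules can be
#' applied.
#'
#' @param assignment one site's assignment from [assign_edited_groups()].
#' @param expression long-format data frame with columns \code{gene},
#'   \code{individual}, \code{tissue} (\code{"normal"} / \code{"tumor"}),
#'   \code{value} (pre-normalised expression).
#' @param genes genes to test; default the ADAR family.
#' @param alpha per-gene significance level.
#' @return A list with \code{flag}, \code{p_values} (named per gene,
#'   \code{NA} when undefined) and \code{n_edited}.
#' @export
adar_de_flag <- function(assignment, expression,
                         genes = c("ADAR", "ADARB1", "ADARB2"),
                         alpha = 0.05) {
  edited <- assignment$edited
  p <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (length(edited) >= 2L) {
    sub <- expression[expression$individual %in% edited, , drop = FALSE]
    for (g in genes) {
      tum <- sub$value[sub$gene == g & sub$tissue == "tumor"]
      nor <- sub$value[sub$gene == g & sub$tissue == "normal"]
      p[g] <- welch_test(tum, nor)$p.value
    }
  }
  list(flag = any(!is.na(p) & p < alpha), p_values = p,
       n_edited = length(edited))
}

#' Survival association of an editing marker
#'
#' Log-rank test of edited versus non-edited individuals via
#' [km_logrank()], with Bonferroni correction for the number of markers
#' tested (\code{corrected = min(1, nominal * n_tests)}).
#'
#' @param marker a per-site assignment or [combined_marker()] result
#'   (needs \code{edited} and \code{non_edited}).
#' @param survival_data data frame with \code{individual}, \code{time}
#'   (days), \code{event} (1 = death observed, 0 = censored).
#' @param n_tests number of markers tested, for the Bonferroni correction.
#' @return A list with \code{p.value} (nominal log-rank),
#'   \code{p.bonferroni}, \code{chisq}, \code{curves},
#'   \code{n_edited}, \code{n_non_edited} and \code{ok}.
#' @export
survival_association <- function(marker, survival_data, n_tests = 1L) {
  undefined <- list(p.value = NA_real_, p.bonferroni = NA_real_,
                    chisq = NA_real_, curves = NULL,
                    n_edited = length(marker$edited),
                    n_non_edited = length(marker$non_edited), ok = FALSE)
  if (length(marker$edited) == 0L || length(marker$non_edited) == 0L)
    return(undefined)
  idx <- match(c(marker$edited, marker$non_edited), survival_data$individual)
  if (any(is.na(idx)))
    stop("survival data missing for individual(s): ",
         paste(utils::head(c(marker$edited, marker$non_edited)[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  sd <- survival_data[idx, , drop = FALSE]
  grp <- rep(c("edited", "non_edited"),
             c(length(marker$edited), length(marker$non_edited)))
  lr <- km_logrank(sd$time, sd$event, grp)
  if (!lr$ok) { undefined$curves <- lr$curves; return(undefined) }
  list(p.value = lr$p.value,
       p.bonferroni = bonferroni_p(lr$p.value, n_tests),
       chisq = lr$chisq, curves = lr$curves,
       n_edited = length(marker$edited),
       n_non_edited = length(marker$non_edited), ok = TRUE)
}

#' Bonferroni-corrected p-value
#'
#' \code{min(1, p * n_tests)}; monotone in \code{p} and capped at 1.
#'
#' @param p nominal p-value(s).
#' @param n_tests number of tests.
#' @return Corrected p-value(s).
#' @export
bonferroni_p <- function(p, n_tests) {
  if (any(n_tests < 1)) stop("`n_tests` must be >= 1", call. = FALSE)
  pmin(1, p * n_tests)
}
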