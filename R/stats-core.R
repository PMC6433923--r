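#' Exact one-sided binomial upper confidence bound
#'
#' Computes the exact (Clopper-Pearson) one-sided \code{100*(1-alpha)}\% upper
#' confidence bound \eqn{U} on the success probability after observing
#' \code{x} successes in \code{n} Bernoulli trials: the value of \eqn{p}
#' solving \eqn{P(X \le x \mid p) = \alpha}. For \code{x = 0} this reduces to
#' the closed form \eqn{1 - \alpha^{1/n}}; for \code{x = n} the bound is 1.
#'
#' In the editing pipeline \code{x} is the number of alternative (G) reads and
#' \code{n} the total read depth at a site in DNA; a small \eqn{U} means high
#' confidence that the DNA genuinely lacks the alternative allele.
#'
#' @param x non-negative integer count(s) of successes (alternative reads),
#'   \code{0 <= x <= n}. Vectorised.
#' @param n positive integer total trial count(s) (read depth). Vectorised.
#' @param alpha confidence parameter in (0,1); default 0.05.
#' @return Numeric vector of upper bounds in (0, 1].
#' @seealso [zero_confidence_score()]
#' @examples
#' binomial_upper_bound(0, 5)        # 1 - 0.05^(1/5) ~ 0.4507
#' binomial_upper_bound(10, 10)      # 1: every read alternative
#' @export
binomial_upper_bound <- function(x, n, alpha = 0.05) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  if (length(x) == 0L || length(n) == 0L)
    return(numeric(0))
  k <- vapply(list(x, n), function(v) {
    if (any(!is.finite(v)) || any(v != floor(v)))
      stop("`x` and `n` must be finite integers", call. = FALSE)
    TRUE
  }, logical(1))
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(x < 0) || any(x > n)) stop("require 0 <= x <= n", call. = FALSE)
  xn <- cbind(x = as.numeric(x), n = as.numeric(n))
  # Clopper-Pearson upper bound via the beta quantile identity:
  # P(X <= x | p) = alpha  <=>  p = qbeta(1 - alpha, x + 1, n - x)
  u <- ifelse(xn[, "x"] == xn[, "n"], 1,
              stats::qbeta(1 - alpha, xn[, "x"] + 1, xn[, "n"] - xn[, "x"]))
  unname(u)
}

#' Zero-confidence score
#'
#' The zero-confidence score of a site is \eqn{-10 \log_{10}(U)} where
#' \eqn{U} is the exact one-sided upper confidence bound on the
#' alternative-allele probability given \code{x} alternative reads out of
#' \code{n} total reads (see [binomial_upper_bound()]). High scores mean high
#' confidence that the underlying DNA carries no alternative allele: with
#' \code{alpha = 0.05} and zero alternative reads, depths 5, 10 and 30 score
#' 3.46, 5.87 and 10.22. The discovery pipeline keeps sites scoring at least
#' 10 in the DNA of both matched samples.
#'
#' @inheritParams binomial_upper_bound
#' @return Numeric vector of scores in \eqn{-10 \log_{10}} units, >= 0
#'   (0 exactly when \code{x == n}).
#' @examples
#' zero_confidence_score(0, c(5, 10, 30))  # 3.46, 5.87, 10.22
#' @export
zero_confidence_score <- function(x, n, alpha = 0.05) {
  -10 * log10(binomial_upper_bound(x, n, alpha))
}

#' Smallest depth whose zero-alternative score reaches a threshold
#'
#' Solves for the minimum read depth \code{n} such that
#' \code{zero_confidence_score(0, n, alpha) >= threshold}; with the default
#' score cutoff of 10 and \code{alpha = 0.05} this is 29 reads, the minimum
#' DNA coverage at which a site with zero alternative reads can pass the
#' zero-confidence filter.
#'
#' @param threshold positive score threshold in \eqn{-10\log_{10}} units.
#' @param alpha confidence parameter in (0,1).
#' @return The smallest integer depth reaching the threshold.
#' @examples
#' min_depth_for_score(10)    # 29
#' @export
min_depth_for_score <- function(threshold, alpha = 0.05) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  # score(0, n) = -10*log10(1 - alpha^(1/n)) >= t  <=>  1 - alpha^(1/n) <= 10^(-t/10)
  u_max <- 10^(-threshold / 10)
  if (u_max >= 1 - alpha) return(1L)   # already satisfied at n = 1
  n <- ceiling(log(alpha) / log1p(-u_max))
  # guard the closed form against boundary rounding
  while (n > 1L && zero_confidence_score(0, n - 1, alpha) >= threshold) n <- n - 1L
  while (zero_confidence_score(0, n, alpha) < threshold) n <- n + 1L
  as.integer(n)
}

check_2x2 <- function(table) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L)))
      stop("`table` must be a 2x2 matrix or a vector of 4 counts", call. = FALSE)
    table <- as.vector(t(table))  # row-major: a, b, c, d
  }
  if (length(table) != 4L || any(!is.finite(table)) ||
      any(table < 0) || any(table != floor(table)))
    stop("2x2 table needs four finite non-negative integer counts", call. = FALSE)
  if (sum(table) == 0)
    stop("2x2 table is all zero; test undefined", call. = FALSE)
  as.numeric(table)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test on a 2x2 count table with rows
#' \code{(a, b)} / \code{(c, d)}. The two-sided p-value sums the point
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table (up to a relative tolerance of
#' 1e-7 on ties, the standard convention). One-sided alternatives refer to
#' the (1,1) cell: \code{"greater"} tests enrichment of \code{a}.
#'
#' @param table 2x2 integer matrix, or a length-4 vector \code{c(a, b, c, d)}
#'   in row-major order.
#' @param alternative one of \code{"two.sided"}, \code{"greater"},
#'   \code{"less"}.
#' @return The exact p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tb <- check_2x2(table)
  a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  pr <- stats::dhyper(support, r1, r2, c1)
  obs <- pr[support == a]
  p <- switch(alternative,
    two.sided = sum(pr[pr <= obs * (1 + 1e-7)]),
    greater   = sum(pr[support >= a]),
    less      = sum(pr[support <= a]))
  min(1, p)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio \eqn{(a d)/(b c)} of the table
#' \code{(a, b)} / \code{(c, d)}. Under the \code{"raw"} policy a zero
#' denominator with positive numerator yields \code{Inf} (so threshold
#' comparisons such as \code{OR >= 2} treat a completely one-sided table as
#' passing) and a zero numerator and denominator yields \code{NA} (undefined).
#' The \code{"haldane"} policy adds 0.5 to every cell first, giving a finite
#' value for reporting.
#'
#' @inheritParams fisher_exact_2x2
#' @param policy \code{"raw"} (default, used for filtering) or
#'   \code{"haldane"} (Haldane-Anscombe correction, used for reporting).
#' @return A non-negative ratio, possibly \code{Inf} or \code{NA}.
#' @examples
#' odds_ratio(c(10, 2, 3, 15))               # 25
#' odds_ratio(c(30, 0, 15, 15), "haldane")   # 61
#' @export
odds_ratio <- function(table, policy = c("raw", "haldane")) {
  policy <- match.arg(policy)
  tb <- check_2x2(table)
  if (policy == "haldane") tb <- tb + 0.5
  num <- tb[1] * tb[4]; den <- tb[2] * tb[3]
  if (den == 0) {
    if (num == 0) return(NA_real_)
    return(Inf)
  }
  num / den
}

#' Strand-bias p-value
#'
#' Two-sided Fisher exact test on the strand-by-allele table
#' \code{(ref+, ref-)} / \code{(alt+, alt-)}. A site is considered free of
#' strand bias when the p-value is at least the configured threshold
#' (default 0.01): genuine variants spread their alternative reads over both
#' strands, while alignment artifacts concentrate them on one.
#'
#' @param ref_plus,ref_minus reference-allele read counts on the forward and
#'   reverse strand.
#' @param alt_plus,alt_minus alternative-allele read counts by strand.
#' @return The two-sided exact p-value.
#' @export
strand_bias_p <- function(ref_plus, ref_minus, alt_plus, alt_minus) {
  fisher_exact_2x2(c(ref_plus, ref_minus, alt_plus, alt_minus))
}

#' Welch's two-sample t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value, as used to flag differential ADAR
#' expression between tumor and normal samples of the edited group. When a
#' group has fewer than two values, or both groups are constant, the test is
#' undefined and \code{NA} statistics are returned with \code{ok = FALSE}.
#'
#' @param group_a,group_b numeric vectors of measurements.
#' @return A list with \code{statistic}, \code{df}, \code{p.value} and
#'   \code{ok} (whether the test was defined).
#' @export
welch_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  undefined <- list(statistic = NA_real_, df = NA_real_,
                    p.value = NA_real_, ok = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L) return(undefined)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(statistic = 0, df = NA_real_, p.value = 1, ok = TRUE))
    return(undefined)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, ok = TRUE)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard two-group
#' log-rank chi-square statistic (1 df, hypergeometric variance at tied event
#' times), used to test whether editing status is associated with patient
#' survival.
#'
#' @param time non-negative follow-up times (days).
#' @param event logical or 0/1; \code{TRUE} when the death was observed,
#'   \code{FALSE} when censored.
#' @param group vector with exactly two distinct levels (e.g. edited /
#'   non-edited), each present at least once.
#' @return A list with \code{curves} (a data frame of \code{group},
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{survival}),
#'   \code{chisq}, \code{p.value} and \code{ok} (\code{FALSE} with \code{NA}
#'   statistics when no event occurred at all).
#' @export
km_logrank <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("`time`, `event` and `group` must have equal length", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("`time` must be finite and non-negative", call. = FALSE)
  event <- as.integer(as.logical(event))
  if (any(is.na(event)) || any(is.na(group)))
    stop("`event` and `group` must not contain missing values; exactly two groups are required",
         call. = FALSE)
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L || any(tabulate(group, nlevels(group)) == 0L))
    stop("`group` must contain exactly two non-empty groups", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv,
    stringsAsFactors = FALSE)
  if (sum(event) == 0L)
    return(list(curves = curves, chisq = NA_real_, p.value = NA_real_, ok = FALSE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  list(curves = curves,
       chisq = unname(sd$chisq),
       p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       ok = TRUE)
}
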