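---
title: "Statistical methods for confident RNA-editing discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for confident RNA-editing discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credo)
```

## The problem

A-to-I RNA editing, catalysed by the ADAR enzyme family, converts adenosine
to inosine in transcripts; sequencers read inosine as guanosine, so genuine
editing appears as an A>G mismatch that is present in RNA-seq reads but
absent from the same individual's DNA. Naive discovery from RNA-seq alone is
dominated by false positives: unfiltered germline A/G variants, sites whose
DNA coverage is too thin to rule a variant out, strand-concentrated
alignment artifacts, and plain sequencing error. `credo` implements a
cascade of exact statistical filters over matched normal–tumor allele
counts, aggregates calls across a cohort, and carries the surviving sites
into downstream ADAR-expression and survival analyses.

## The zero-confidence filter

The key statistic scores how confidently the DNA at a site lacks the
alternative allele. With $x$ alternative (G) reads out of $n$ DNA reads, let
$U$ be the exact one-sided $100(1-\alpha)\%$ upper confidence bound on the
alternative-allele probability — the Clopper–Pearson-style bound solving
$P(X \le x \mid p = U) = \alpha$, i.e. `qbeta(1 - alpha, x + 1, n - x)`,
which at $x = 0$ reduces to $1 - \alpha^{1/n}$. The zero-confidence score is

$$ Z = -10 \log_{10} U, $$

so high scores mean high confidence in a truly editing-free genome at the
site. With $\alpha = 0.05$ and no alternative reads, depths 5, 10 and 30
score 3.46, 5.87 and 10.22:

```{r}
zero_confidence_score(0, c(5, 10, 30))
min_depth_for_score(10)
```

The discovery cutoff of $Z \ge 10$ at $\alpha = 0.05$ therefore demands at
least 29 clean DNA reads in **both** matched samples. This is the filter's
point: a site with 10 clean DNA reads looks identical to one with 100, yet
only the latter meaningfully excludes a missed germline variant. The exact
bound is adopted because it reproduces the worked scores above exactly; a
likelihood-based bound would differ in the third decimal at these depths.
A site entirely absent from the DNA pileup ($n = 0$) fails the filter by
definition — absence of evidence carries no confidence.

## Candidate extraction and per-sample filters

Per sample, a locus is an A>G candidate when the reference base is
adenosine, guanosine is the only non-reference allele observed (a strict
rule; `third_allele_tolerance` relaxes it), the locus has more than 4 reads
at base quality ≥ 25, and the strand-by-allele Fisher exact test shows no
bias at $p \ge 0.01$. For stranded libraries `include_tc_strand` admits the
antisense T>C representation, normalised to ref/alt counts with strands
swapped. High-quality homozygous A>G DNA variants (more than 4 reads,
calling quality ≥ 50) called in the same sample are subtracted before the
zero-confidence filter.

All 2×2 tests are exact (hypergeometric enumeration); no chi-square
approximation is used anywhere, because candidate tables are routinely
sparse. The two-sided p sums point probabilities not exceeding the observed
table's, with the standard $1 + 10^{-7}$ relative tie tolerance.

## Matched discovery

For a locus surviving in both matched samples, the 2×2 table rows are
(normal, tumor) and columns are (RNA reference count, RNA alternative
count). The odds ratio is oriented so OR > 1 means a higher edited fraction
in tumor; loci with $0.5 < \mathrm{OR} < 2.0$ or Fisher $p > 0.05$ are
classed insignificant and pruned, the rest are tumor- or normal-enriched.
Two deliberate conventions:

* **Zero cells.** Filtering uses the raw cross-product ratio with
  $\infty$ semantics (a completely tumor-specific site passes OR ≥ 2);
  reported tables also carry the Haldane–Anscombe value (+0.5 per cell) so
  downstream consumers see finite numbers. Both are emitted.
* **Pooled loci.** A tumor-specific site has no alternative reads in normal
  RNA, so candidate loci are pooled across the pair and the matched table
  uses both samples' counts. The strand-bias criterion is enforced on both
  samples at the pooled loci: without this, a sample failing the bias filter
  re-enters the comparison whenever its partner has a single stray error
  read, and artifact sites leak through.

Sidedness of the Fisher tests is two-sided by default (conservative and
symmetric between the two enrichment directions), with one-sided
alternatives available.

In single-sample mode the table is (RNA, DNA) × (ref, alt), oriented so
OR > 1 means RNA enrichment, and a site is accepted when $Z \ge 10$ on the
DNA counts and OR ≥ 2.

## Cohort aggregation and the dbSNP negative control

Significant per-individual calls are grouped by locus; a site is recurrent
when seen in more than 4 individuals. Recurrence counts an individual once
regardless of direction, and the two direction tallies are kept separately.
Known-SNP overlap is the false-positive proxy: an editing call coinciding
with a catalogued SNP is most likely a missed DNA variant, so a better call
set overlaps less. The overlap is reported overall and per recurrence
stratum — both "exactly k individuals" and "at least k", since either
stratification is a reasonable reading — and SNP-coincident sites are
annotated, never removed, because known editing sites do occur in SNP
catalogues. Matching is positional (chromosome + position) by default.

## Downstream clinical association

Per site, individuals split into edited (significant call) and non-edited
groups. ADAR differential expression is Welch's unequal-variance test of
tumor versus normal expression within the edited group, per gene over a
configurable ADAR set (default ADAR, ADARB1, ADARB2), flagging the site if
any gene has $p < 0.05$; per-gene p-values are always reported because the
any-gene rule inflates the per-site rate to $1 - 0.95^g$ under the null.
Survival association is the standard two-group log-rank test (hypergeometric
variance at tied event times, via the `survival` package) on Kaplan–Meier
groups, Bonferroni-corrected with an explicit `n_tests` — explicit because
the number of markers actually tested is an analysis decision, not something
the package can infer. Individually infrequent sites can be pooled into a
combined marker whose edited set is the union of the members' edited sets;
marker composition is explicit user input.

## The synthetic cohort generator

`simulate_cohort()` produces a matched cohort with known truth so the whole
cascade is testable end to end. Defaults describe the reference study
condition used throughout the tests: 20 individuals, 5,000 A-reference loci,
2% true tumor-enriched editing sites edited at level 0.4 in tumor and 0.0 in
normal, 4% germline A/G SNP sites (half het, half hom carriers), 1% strand
artifact sites, negative-binomial depth with mean 60 and size 10 for both
assays (over-dispersion mimicking exome capture and expression variation),
and an A→G miscall rate of 0.001. Choices made where no canonical value
exists, fixed once:

* Per-site carrier probabilities for editing sites are uniform on
  (0.2, 0.8), so recurrence genuinely varies and the recurrence filter has
  something to do.
* The DNA variant caller is modelled with sensitivity 0.9 — some carried
  SNPs are absent from the VCF, which is precisely the failure mode the
  zero-confidence filter exists for (a missed het SNP still shows ~50% G in
  its DNA reads and scores near 0).
* Artifact sites place all alternative RNA reads on one strand at fraction
  0.3, appearing in 30% of samples independently.
* Sequencing error is emitted only toward G, the confusable channel for
  this problem; the one-alternative-allele rule is exercised by dedicated
  unit fixtures instead.
* Tumor ADAR expression of edited individuals is shifted ×2 (log-normal
  baseline), planting ADAR-DE positives; survival is exponential with
  baseline hazard 1/1500 per day, administrative censoring at 3,000 days,
  and hazard ratio 3 for individuals edited at 4 designated clinical sites.

What the generator does **not** emulate: alignment and mapping error,
splice-junction artifacts, reference bias, position-in-read effects,
non-independent error (PCR duplicates), or realistic linkage between SNPs.
Passing the end-to-end tests therefore shows the statistical cascade behaves
as designed under its own model assumptions, not that real-data error modes
are all covered — upstream hygiene (duplicate marking, realignment,
recalibration) remains the user's responsibility.

A useful observed behaviour of the reference condition: low-depth artifact
occurrences occasionally pass the exact strand-bias test (which has little
power below ~10 alternative reads) and enter the aggregate call set, but
they are sample-specific and the recurrence filter removes them — the
recurrent set is clean. That is the recurrence filter's purpose.

## Numerical and degenerate-input conventions

* All-zero 2×2 tables are rejected; an OR with zero numerator and
  denominator is `NA` (undefined), distinct from `Inf`.
* Welch's test with a group smaller than 2, or two distinct constant
  groups, returns an undefined marker rather than a p-value; equal constant
  groups return $p = 1$.
* Log-rank with no events at all returns an undefined marker; empty groups
  are an error.
* Scores and bounds are computed in full double precision; two-decimal
  rounding is for display only.
* Coordinates are 1-based closed throughout (VCF/pileup convention); BED
  input is converted on read.
* Simulation, discovery and aggregation are deterministic given the seed,
  and the simulator restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite exercises the exact-test enumeration exhaustively for all
2×2 tables with total ≤ 40, calibrates the Welch and log-rank null at
10,000 replicates (n = 10 and 100 per group respectively), and runs the
full pipeline at the reference condition above (20 × 5,000, fixed seed)
plus smaller cohorts for property checks; these sizes give stable Monte
Carlo estimates while keeping a complete run in the order of a minute.
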