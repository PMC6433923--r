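small_cfg <- function(...) {
  sim_config(n_individuals = 4L, n_sites = 250L, seed = 99L, ...)
}

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  a <- simulate_cohort(small_cfg())
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  b <- simulate_cohort(small_cfg())
  expect_identical(a$rna, b$rna)
  expect_identical(a$variants, b$variants)
  expect_identical(a$survival, b$survival)
  expect_equal(rnorm(1), before)   # caller RNG stream untouched
  c <- simulate_cohort(sim_config(n_individuals = 4L, n_sites = 250L,
                                  seed = 100L))
  expect_false(identical(a$rna, c$rna))
})

test_that("a null world yields no candidate loci anywhere", {
  sim <- simulate_cohort(small_cfg(editing_site_fraction = 0,
                                   snp_site_fraction = 0,
                                   artifact_site_fraction = 0,
                                   seq_error_rate = 0))
  res <- discover_cohort(sim)
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(nrow(prefilter_candidates(sim)), 0L)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(editing_site_fraction = 0.7, snp_site_fraction = 0.5),
               "sum")
  expect_error(sim_config(seq_error_rate = 1.5), "seq_error_rate")
  expect_error(sim_config(n_individuals = 0), "at least one")
  expect_error(sim_config(edit_carrier_prob_range = c(0.9, 0.1)), "range")
  expect_error(simulate_cohort(list()), "sim_config")
})

test_that("planted structure shows up where it should", {
  sim <- simulate_cohort(small_cfg())
  tc <- sim$truth$site_class
  expect_equal(sum(tc$class == "true_editing_tumor_enriched"),
               round(0.02 * 250))
  # planted SNP positions are all in the SNP set; decoys extend it
  snp_pos <- tc$pos[grepl("^germline_snp", tc$class)]
  expect_true(all(snp_pos %in% sim$snp_set$pos))
  expect_gt(nrow(sim$snp_set), length(snp_pos))
  # hom SNP carriers are nearly pure G in DNA, het carriers near half
  hom <- which(tc$class == "germline_snp_hom")
  i_carrier <- NULL
  for (i in seq_along(sim$individuals)) {
    # reconstruct carrier status from the DNA counts themselves
    d <- sim$dna$normal[[i]]
    frac <- (d$g_plus + d$g_minus) /
      pmax(1, d$a_plus + d$a_minus + d$g_plus + d$g_minus)
    expect_true(all(frac[hom] < 0.05 | frac[hom] > 0.9))
  }
  # editing never reaches DNA: non-SNP sites stay alternative-free up to error
  clean_dna <- unlist(lapply(sim$dna$tumor, function(d) {
    idx <- !grepl("^germline_snp", tc$class)
    (d$g_plus + d$g_minus)[idx] / pmax(1, (d$a_plus + d$a_minus +
                                           d$g_plus + d$g_minus))[idx]
  }))
  expect_lt(max(clean_dna), 0.2)
})

test_that("sensitivity rises with the editing level", {
  res_for <- function(level) {
    sim <- simulate_cohort(sim_config(n_individuals = 6L, n_sites = 400L,
                                      tumor_edit_level = level, seed = 5L))
    agg <- aggregate_recurrence(discover_cohort(sim)$candidates, 0L)
    score_calls(agg$sites, sim$truth)
  }
  lo <- res_for(0.05); hi <- res_for(0.45)
  expect_gt(hi$sensitivity, lo$sensitivity)
})

test_that("covered germline SNPs never survive the DNA filters", {
  sim <- simulate_cohort(small_cfg(snp_site_fraction = 0.2,
                                   dna_caller_sensitivity = 1))
  agg <- aggregate_recurrence(discover_cohort(sim)$candidates, 0L)
  sc <- score_calls(agg$sites, sim$truth)
  expect_equal(unname(sc$false_calls_by_class["snp_driven"]), 0L)
})

test_that("call scoring arithmetic on degenerate call sets", {
  truth <- list(site_class = data.frame(
    chrom = "chr1", pos = 1:10, ref = "A",
    class = c(rep("true_editing_tumor_enriched", 4),
              rep("clean_background", 6)), stringsAsFactors = FALSE))
  perfect <- score_calls(data.frame(chrom = "chr1", pos = 1:4), truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdr, 0)
  none <- score_calls(data.frame(chrom = character(), pos = integer()), truth)
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$fdr))
  all_called <- score_calls(data.frame(chrom = "chr1", pos = 1:10), truth)
  expect_equal(all_called$sensitivity, 1)
  expect_equal(all_called$fdr, 1 - 0.4)
})
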