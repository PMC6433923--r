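calls <- function(individual, pos, direction = "tumor_enriched",
                  chrom = "chr1") {
  data.frame(individual = individual, chrom = chrom, pos = pos, ref = "A",
             direction = direction, stringsAsFactors = FALSE)
}

test_that("recurrence aggregation counts distinct individuals per site", {
  cand <- rbind(calls(paste0("i", 1:5), 100L),
                calls(paste0("i", 1:4), 200L),
                calls("i9", 300L, "insignificant"))
  agg <- aggregate_recurrence(cand, 4L)
  expect_equal(agg$sites$pos, c(100L, 200L))
  expect_equal(agg$sites$sample_count, c(5L, 4L))
  expect_equal(agg$recurrent$pos, 100L)          # 4 of the cohort is too few

  single <- aggregate_recurrence(calls(c("a", "b", "c"), c(1L, 2L, 3L)), 0L)
  expect_equal(single$sites$sample_count, rep(1L, 3))
  expect_equal(nrow(single$recurrent), 3L)
})

test_that("direction tallies are kept separately and duplicates collapse", {
  cand <- rbind(calls(c("i1", "i2"), 100L),
                calls("i3", 100L, "normal_enriched"),
                calls("i1", 100L))                # duplicate individual/site
  expect_warning(agg <- aggregate_recurrence(cand, 0L), "deduplicated")
  expect_equal(agg$sites$sample_count, 3L)
  expect_equal(agg$sites$n_tumor_enriched, 2L)
  expect_equal(agg$sites$n_normal_enriched, 1L)
})

test_that("aggregation is permutation-invariant over individuals", {
  set.seed(8)
  cand <- calls(sample(paste0("i", 1:12), 40, TRUE),
                sample(c(10L, 20L, 30L, 40L), 40, TRUE))
  cand <- cand[!duplicated(cand[c("individual", "pos")]), ]
  a <- aggregate_recurrence(cand, 2L)$sites
  b <- aggregate_recurrence(cand[sample(nrow(cand)), ], 2L)$sites
  expect_equal(a, b)
})

test_that("dbSNP overlap is a fraction, with stratum sizes summing to the total", {
  sites <- data.frame(chrom = "chr1", pos = 1:10,
                      sample_count = c(1, 1, 1, 1, 2, 2, 3, 3, 3, 6))
  snps <- data.frame(chrom = "chr1", pos = c(1L, 5L, 7L))
  ov <- dbsnp_overlap_rate(sites, snps, stratify_by_recurrence = TRUE)
  expect_equal(ov$overall, 0.3)
  expect_equal(sum(ov$by_recurrence$n_sites), nrow(sites))
  expect_equal(ov$by_recurrence$n_sites_ge[1], nrow(sites))
  expect_equal(dbsnp_overlap_rate(sites, snps[0, ])$overall, 0)
  expect_true(is.na(dbsnp_overlap_rate(sites[0, ], snps)$overall))
})

test_that("individual-specific SNP artifacts concentrate at low recurrence", {
  # SNP-driven calls recur in one individual each; true sites in many
  snp_sites <- data.frame(chrom = "chr1", pos = 1:30, sample_count = 1L)
  true_sites <- data.frame(chrom = "chr1", pos = 101:115,
                           sample_count = rep(c(5L, 8L, 12L), 5))
  sites <- rbind(snp_sites, true_sites)
  snps <- data.frame(chrom = "chr1", pos = 1:30)
  ov <- dbsnp_overlap_rate(sites, snps, TRUE)$by_recurrence
  expect_true(all(diff(ov$pct_in_dbsnp_ge) <= 0))
})

test_that("gene annotation honors the half-open BED convention", {
  feats <- data.frame(chrom = "chr1", start = c(99L, 150L, 155L),
                      end = c(150L, 200L, 160L),
                      name = c("GENEB", "GENEA", "GENEC"),
                      region = c("exon", "3utr", "exon"),
                      stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1", pos = c(100L, 150L, 157L, 500L))
  ann <- annotate_sites(sites, feats)
  expect_equal(ann$gene, c("GENEB", "GENEB", "GENEA;GENEC", ""))
  expect_equal(ann$region[3], "3utr;exon")
  # position 151 leaves GENEB (end exclusive -> 150 is its last base)
  expect_equal(annotate_sites(data.frame(chrom = "chr1", pos = 151L),
                              feats)$gene, "GENEA")
})
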