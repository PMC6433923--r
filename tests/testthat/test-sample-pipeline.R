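cfg <- filter_config()

test_that("candidate extraction enforces the A>G, depth and strand rules", {
  keep <- extract_ag_candidates(ag_pileup(10, 10, 5, 5), cfg)
  expect_equal(nrow(keep), 1L)
  expect_equal(keep$ref_n, 20L)
  expect_equal(keep$alt_n, 10L)

  # exactly 4 reads is too few ("more than 4")
  expect_equal(nrow(extract_ag_candidates(ag_pileup(2, 1, 1, 0), cfg)), 0L)
  expect_equal(nrow(extract_ag_candidates(ag_pileup(2, 1, 1, 1), cfg)), 1L)

  # a third allele disqualifies the locus under the strict rule
  third <- ag_pileup(10, 10, 5, 5); third$c_plus <- 1L
  expect_equal(nrow(extract_ag_candidates(third, cfg)), 0L)
  lax <- filter_config(third_allele_tolerance = 0.1)
  expect_equal(nrow(extract_ag_candidates(third, lax)), 1L)

  # all alternative reads on one strand fail the bias filter
  expect_equal(nrow(extract_ag_candidates(ag_pileup(30, 30, 20, 0), cfg)), 0L)

  # non-A reference bases and alt-free loci are never candidates
  expect_equal(nrow(extract_ag_candidates(
    pileup_row(ref = "C", c_plus = 20L, g_plus = 10L), cfg)), 0L)
  expect_equal(nrow(extract_ag_candidates(ag_pileup(30, 30, 0, 0), cfg)), 0L)
})

test_that("antisense T>C loci are admitted only when configured", {
  tc <- pileup_row(ref = "T", t_plus = 12L, t_minus = 11L,
                   c_plus = 4L, c_minus = 5L)
  expect_equal(nrow(extract_ag_candidates(tc, cfg)), 0L)
  cfg_tc <- filter_config(include_tc_strand = TRUE)
  got <- extract_ag_candidates(tc, cfg_tc)
  expect_equal(got$strand, "antisense")
  # antisense normalisation swaps alleles and strands
  expect_equal(got$ref_plus, 11L)   # T on minus reads the sense-A plus strand
  expect_equal(got$alt_n, 9L)
})

test_that("malformed pileup rows are skipped with a warning", {
  bad <- rbind(ag_pileup(10, 10, 5, 5, pos = 1L),
               ag_pileup(10, 10, 5, 5, pos = 2L))
  bad$a_plus[2] <- -3L
  expect_warning(got <- extract_ag_candidates(bad, cfg), "malformed")
  expect_equal(got$pos, 1L)
})

test_that("DNA variant acceptance follows the quality, depth and genotype rules", {
  v <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
                  qual = c(99, 99, 99, 49, 99),
                  genotype = c("hom", "hom", "het", "hom", "hom"),
                  depth = c(30, 4, 30, 30, 5), stringsAsFactors = FALSE)
  acc <- accept_dna_variants(v, cfg)
  expect_equal(acc$pos, c(1L, 5L))   # depth 4, het, qual 49 all rejected
  v2 <- v; v2$alt[1] <- "T"
  expect_equal(accept_dna_variants(v2, cfg)$pos, 5L)
  v3 <- v; v3$depth[1] <- NA
  expect_warning(accept_dna_variants(v3, cfg), "skipped")
})

test_that("DNA-variant subtraction is an exact positional set difference", {
  rec <- extract_ag_candidates(do.call(rbind, lapply(1:10, function(p)
    ag_pileup(10, 10, 5, 5, pos = p))), cfg)
  v <- data.frame(chrom = "chr1", pos = c(2L, 5L, 9L))
  out <- subtract_dna_variants(rec, v)
  expect_equal(out$pos, setdiff(1:10, c(2, 5, 9)))
  expect_equal(subtract_dna_variants(out, v), out)          # idempotent
  expect_equal(subtract_dna_variants(rec, v[0, , drop = FALSE]), rec)
  other_chrom <- data.frame(chrom = "chr2", pos = 1L)
  expect_equal(nrow(subtract_dna_variants(rec, other_chrom)), 10L)
})

test_that("zero-confidence filter engages exactly at the 29-read boundary", {
  rec <- extract_ag_candidates(do.call(rbind, lapply(1:4, function(p)
    ag_pileup(20, 20, 10, 10, pos = p))), cfg)
  dna <- do.call(rbind, mapply(function(p, n) {
    r <- pileup_row(pos = p); r$a_plus <- n; r
  }, 1:4, c(30L, 10L, 29L, 28L), SIMPLIFY = FALSE))
  rec <- attach_dna_counts(rec, dna)
  out <- zero_confidence_filter(rec, cfg)
  expect_equal(out$pos, c(1L, 3L))                 # 30 and 29 pass; 10, 28 fail
  expect_equal(out$dna_zero_conf[1], 10.22, tolerance = 0.002)

  # a locus absent from the DNA pileup has no confidence at all
  rec0 <- attach_dna_counts(
    extract_ag_candidates(ag_pileup(20, 20, 10, 10, pos = 99L), cfg),
    pileup_row(pos = 1L, a_plus = 50L))
  expect_equal(nrow(zero_confidence_filter(rec0, cfg)), 0L)
})

test_that("matched discovery classifies direction and is reciprocal", {
  mk <- function(ref, alt, pos = 1L) {
    r <- extract_ag_candidates(ag_pileup(ceiling(ref / 2), floor(ref / 2),
                                         ceiling(alt / 2), floor(alt / 2),
                                         pos = pos), cfg)
    if (nrow(r) == 0L)   # alt-free record built via the pooled-site path
      r <- credo:::site_records_at(
        ag_pileup(ceiling(ref / 2), floor(ref / 2), 0, 0, pos = pos),
        data.frame(chrom = "chr1", pos = pos, ref = "A", strand = "sense"),
        cfg)
    r$dna_ref <- 50L; r$dna_alt <- 0L
    zero_confidence_filter(r, cfg)
  }
  res <- matched_discovery(mk(30, 0), mk(15, 15), cfg)
  expect_identical(res$or_raw, Inf)
  expect_equal(res$or_haldane, 61)
  expect_lt(res$fisher_p, 0.05)
  expect_equal(res$fisher_p, enum_fisher_p(30, 0, 15, 15), tolerance = 1e-12)
  expect_equal(res$direction, "tumor_enriched")

  flat <- matched_discovery(mk(10, 10), mk(10, 10), cfg)
  expect_equal(flat$or_raw, 1)
  expect_equal(flat$fisher_p, 1)
  expect_equal(flat$direction, "insignificant")

  mirror <- matched_discovery(mk(15, 15), mk(30, 0), cfg)
  expect_equal(mirror$direction, "normal_enriched")

  ab <- matched_discovery(mk(12, 7), mk(9, 14), cfg)
  ba <- matched_discovery(mk(9, 14), mk(12, 7), cfg)
  expect_equal(ab$or_raw * ba$or_raw, 1, tolerance = 1e-12)

  expect_error(matched_discovery(mk(10, 10, pos = 1L), mk(10, 10, pos = 2L)),
               "different sites")
})

test_that("single-sample mode needs both the score and the RNA enrichment", {
  mk <- function(rna_ref, rna_alt, dna_ref, dna_alt) {
    r <- extract_ag_candidates(
      ag_pileup(ceiling(rna_ref / 2), floor(rna_ref / 2),
                ceiling(rna_alt / 2), floor(rna_alt / 2)), cfg)
    r$dna_ref <- dna_ref; r$dna_alt <- dna_alt
    single_sample_discovery(r, cfg)
  }
  ok <- mk(20, 10, 40, 0)
  expect_equal(ok$dna_zero_conf, 11.42, tolerance = 0.002)
  expect_identical(ok$or_raw, Inf)
  expect_true(ok$accepted)

  shallow <- mk(20, 10, 25, 0)       # 25 DNA reads sit below the 29 boundary
  expect_lt(shallow$dna_zero_conf, 10)
  expect_false(shallow$accepted)

  weak <- mk(40, 2, 40, 2)           # OR below 2: not enriched in RNA
  expect_lt(weak$or_raw, 2)
  expect_false(weak$accepted)
})

test_that("independent filters commute", {
  set.seed(5)
  pile <- do.call(rbind, lapply(1:60, function(p)
    ag_pileup(rpois(1, 15), rpois(1, 15),
              rpois(1, 3), sample(0:6, 1), pos = p)))
  # depth-then-bias equals bias-then-depth: survivors as a set
  lax <- filter_config(min_reads = 1L, strand_bias_alpha = 1e-9)
  depth_only <- filter_config(strand_bias_alpha = 1e-9)
  bias_only <- filter_config(min_reads = 1L)
  both <- extract_ag_candidates(pile, cfg)$pos
  via_depth <- extract_ag_candidates(pile, depth_only)
  via_depth <- via_depth[via_depth$strand_bias_p >= cfg$strand_bias_alpha, ]
  via_bias <- extract_ag_candidates(pile, bias_only)
  via_bias <- via_bias[(via_bias$ref_n + via_bias$alt_n) >= cfg$min_reads, ]
  expect_setequal(both, via_depth$pos)
  expect_setequal(both, via_bias$pos)
})
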