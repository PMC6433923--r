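inds <- paste0("i", 1:10)

mk_calls <- function(individual, pos, direction = "tumor_enriched") {
  data.frame(individual = individual, chrom = "chr1", pos = pos, ref = "A",
             direction = direction, stringsAsFactors = FALSE)
}

test_that("edited/non-edited split covers the cohort exactly", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A")
  cand <- rbind(mk_calls(c("i1", "i2", "i3"), 100L),
                mk_calls("i4", 200L, "insignificant"))
  asg <- assign_edited_groups(sites, cand, inds)
  expect_equal(asg[["chr1:100"]]$edited, c("i1", "i2", "i3"))
  expect_setequal(c(asg[["chr1:100"]]$edited, asg[["chr1:100"]]$non_edited),
                  inds)
  expect_false(asg[["chr1:200"]]$testable)

  only_t <- assign_edited_groups(
    sites, rbind(mk_calls("i1", 100L), mk_calls("i2", 100L, "normal_enriched")),
    inds, tumor_enriched_only = TRUE)
  expect_equal(only_t[["chr1:100"]]$edited, "i1")
})

test_that("a combined marker is the union of its member edited sets", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L), ref = "A")
  cand <- rbind(mk_calls(c("i1", "i2"), 100L), mk_calls(c("i2", "i5"), 200L))
  asg <- assign_edited_groups(sites, cand, inds)
  cm <- combined_marker(asg, inds)
  expect_equal(cm$edited, c("i1", "i2", "i5"))
  expect_setequal(c(cm$edited, cm$non_edited), inds)
})

expr_for <- function(individuals, tumor_factor = 1) {
  g <- expand.grid(gene = c("ADAR", "ADARB1", "ADARB2"),
                   individual = individuals, tissue = c("normal", "tumor"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$value <- 100 + seq_len(nrow(g)) %% 7          # deterministic spread
  g$value[g$tissue == "tumor"] <- g$value[g$tissue == "tumor"] * tumor_factor
  g
}

test_that("ADAR differential-expression flag reacts to a planted tumor shift", {
  asg <- list(edited = paste0("i", 1:6), non_edited = paste0("i", 7:10))
  up <- adar_de_flag(asg, expr_for(inds, tumor_factor = 2))
  expect_true(up$flag)
  expect_true(all(up$p_values < 0.05))
  flat <- adar_de_flag(asg, expr_for(inds, tumor_factor = 1))
  expect_false(flat$flag)
  tiny <- adar_de_flag(list(edited = "i1"), expr_for(inds))
  expect_false(tiny$flag)
  expect_true(all(is.na(tiny$p_values)))
})

surv_for <- function(time_edited, time_other) {
  data.frame(individual = inds,
             time = c(rep(time_edited, 5), rep(time_other, 5)),
             event = 1L, stringsAsFactors = FALSE)
}

test_that("survival association applies the log-rank test and Bonferroni cap", {
  marker <- list(edited = inds[1:5], non_edited = inds[6:10])
  same <- survival_association(marker,
                               data.frame(individual = inds,
                                          time = rep(c(2, 5, 9, 4, 7), 2),
                                          event = 1L), n_tests = 207L)
  expect_equal(same$p.value, 1)
  expect_equal(same$p.bonferroni, 1)

  split <- survival_association(marker, surv_for(1, 100), n_tests = 10L)
  expect_lt(split$p.value, 0.05)
  expect_equal(split$p.bonferroni, min(1, split$p.value * 10))

  empty <- survival_association(list(edited = character(), non_edited = inds),
                                surv_for(1, 2))
  expect_false(empty$ok)
})

test_that("Bonferroni arithmetic is monotone, capped, and matches the printed value", {
  expect_equal(signif(bonferroni_p(2.2e-7, 207L), 2), 4.6e-5)
  expect_equal(bonferroni_p(0.2, 10L), 1)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni_p(p, 7L)) >= 0))
  expect_error(bonferroni_p(0.5, 0L), "n_tests")
})

test_that("editing-linked hazard is detected with good power on simulated cohorts", {
  set.seed(23)
  hits <- replicate(60, {
    edited <- rbinom(40, 1, 0.4)
    t <- rexp(40, 0.002 * ifelse(edited == 1, 3, 1))
    marker <- list(edited = paste0("p", which(edited == 1)),
                   non_edited = paste0("p", which(edited == 0)))
    sv <- data.frame(individual = paste0("p", 1:40),
                     time = pmin(t, 3000), event = as.integer(t <= 3000))
    if (length(marker$edited) && length(marker$non_edited))
      survival_association(marker, sv)$p.value < 0.05
    else NA
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})
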