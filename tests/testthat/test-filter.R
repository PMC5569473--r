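test_that("inclusion thresholds are inclusive and partition exactly", {
  calls <- make_calls(c("A", "B", "C", "D"),
                      start = c(0, 0, 0, 0),
                      end = c(5263, 9000, 5000, 4999),
                      cn_state = 1, marker_count = c(7, 4, 5, 5))
  parts <- filter_calls(calls, filter_policy())
  expect_equal(parts$kept$individual_id, c("A", "C"))   # 5263/7 and 5000/5
  expect_equal(parts$dropped$individual_id, c("B", "D"))
  expect_equal(nrow(parts$kept) + nrow(parts$dropped), nrow(calls))
  expect_equal(nrow(merge(parts$kept, parts$dropped)), 0)
  # one-line predicate oracle for the inclusive boundary
  oracle <- calls$marker_count >= 5 & calls$span >= 5000
  expect_equal(calls$individual_id[oracle], parts$kept$individual_id)
  # idempotence
  again <- filter_calls(parts$kept, filter_policy())
  expect_equal(again$kept, parts$kept)
  expect_equal(nrow(again$dropped), 0)
  # disabled policy == thresholds of 1
  off <- filter_calls(calls, filter_policy(enabled = FALSE))
  min1 <- filter_calls(calls, filter_policy(1, 1))
  expect_equal(off$kept, min1$kept)
})

test_that("locus genotyping defaults to CN 2 and honours unfiltered mode", {
  samples <- make_samples(300, 300)
  carriers <- samples$id[samples$status == "case"]
  # every case carries a sub-threshold 4-marker call over the locus
  calls <- make_calls(carriers, start = 0, end = 3000, cn_state = 1,
                      marker_count = 4)
  filtered <- genotype_locus(calls, "L1", "chr1", 0, 5000, "deletion",
                             samples, policy = filter_policy())
  unfiltered <- genotype_locus(calls, "L1", "chr1", 0, 5000, "deletion",
                               samples,
                               policy = filter_policy(enabled = FALSE))
  t_f <- build_allele_table(filtered, samples)
  t_u <- build_allele_table(unfiltered, samples)
  expect_equal(t_f$a, 0L)
  expect_equal(t_u$a, 300L)
  expect_equal(t_u$a - t_f$a, 300L)
  # individual with no overlapping call is reference
  cn <- locus_genotypes(unfiltered, samples)
  expect_true(all(cn[samples$status == "control"] == 2L))
})

test_that("conflicting overlapping calls raise an ambiguity error", {
  samples <- make_samples(1, 1)
  calls <- make_calls(c("P001", "P001"), start = 0, end = 8000,
                      cn_state = c(0, 1), marker_count = 10)
  expect_error(
    genotype_locus(calls, "L1", "chr1", 0, 8000, "deletion", samples),
    "conflicting.*P001")
  # same state twice is not a conflict
  calls2 <- make_calls(c("P001", "P001"), start = 0, end = 8000,
                       cn_state = 1, marker_count = 10)
  lc <- genotype_locus(calls2, "L1", "chr1", 0, 8000, "deletion", samples)
  expect_equal(unname(lc$genotypes["P001"]), 1L)
})

test_that("reciprocal overlap rule matches calls to the canonical locus", {
  samples <- make_samples(3, 1)
  calls <- make_calls(c("P001", "P002", "P003"),
                      start = c(0, 0, 20000),
                      end = c(10000, 2000, 30000),
                      cn_state = 1, marker_count = 10)
  lc <- genotype_locus(calls, "L1", "chr1", 0, 10000, "deletion", samples,
                       policy = filter_policy(enabled = FALSE))
  # P002's 2 kb call covers only 20% of the locus; P003 is disjoint
  expect_equal(names(lc$genotypes), "P001")
})

test_that("batch heterogeneity screen matches the closed-form chi-squared", {
  samples <- make_samples(0 + 200, 200, batches = c("b1", "b2"))
  # identical carrier frequency in both batches: p ~ 1
  ids <- samples$id
  carriers <- c(ids[samples$batch == "b1"][1:50],
                ids[samples$batch == "b2"][1:50])
  lc <- cnv_locus("L1", "chr1", 0, 5000, "deletion",
                  genotypes = stats::setNames(rep(1L, 100), carriers))
  res <- batch_heterogeneity(lc, samples)
  expect_true(res$applicable)
  expect_gt(res$p, 0.999)

  # 50/100 vs 10/100 carriers: textbook 2x2 Pearson chi-squared
  samples2 <- make_samples(100, 100, batches = c("b1"))
  samples2$batch <- rep(c("b1", "b2"), each = 100)
  carriers2 <- c(samples2$id[1:50], samples2$id[101:110])
  lc2 <- cnv_locus("L1", "chr1", 0, 5000, "deletion",
                   genotypes = stats::setNames(rep(1L, 60), carriers2))
  res2 <- batch_heterogeneity(lc2, samples2)
  a <- 50; b <- 50; c_ <- 10; d <- 90; n <- 200
  stat <- n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(res2$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res2$flagged)

  # single batch: not applicable
  res3 <- batch_heterogeneity(lc, make_samples(10, 10, batches = "b1"))
  expect_false(res3$applicable)
  expect_true(is.na(res3$p))
})

test_that("a simulated batch shift on the miscall log-odds is flagged", {
  sp <- locus_spec("L1", "deletion", 0.3, 1, marker_mean = 1,
                   marker_spacing_bp = 6000)
  flagged <- vapply(1:20, function(rep) {
    model <- error_model(alpha_del = -3, beta = 0,
                         batch_effects = c(b2 = 2))
    set.seed(1000 + rep)
    cn <- stats::setNames(draw_genotypes(0.1, 1000, "deletion"),
                          sprintf("I%04d", 1:1000))
    truth <- cnv_locus("L1", "chr1", 0, 6000, "deletion", genotypes = cn)
    samples <- data.frame(id = names(cn), status = "case",
                          batch = rep(c("b1", "b2"), each = 500),
                          stringsAsFactors = FALSE)
    res <- corrupt_to_array_calls(truth, sp, model,
                                  batch = stats::setNames(samples$batch,
                                                          samples$id),
                                  seed = 1000 + rep)
    observed <- cnv_locus("L1", "chr1", 0, 6000, "deletion",
                          genotypes = res$observed)
    batch_heterogeneity(observed, samples)$flagged
  }, logical(1))
  expect_gte(sum(flagged), 18)
})
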