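test_that("allele dosages map copy numbers to 0-2 CNV alleles", {
  expect_equal(allele_dosage(2, "deletion"), 0L)
  expect_equal(allele_dosage(0, "deletion"), 2L)   # homozygous deletion
  expect_equal(allele_dosage(c(2, 3, 4), "duplication"), c(0L, 1L, 2L))
  expect_error(allele_dosage(3, "deletion"), "inconsistent")
  expect_error(allele_dosage(1, "duplication"), "inconsistent")
  expect_warning(d <- allele_dosage(5, "duplication"), "clamped")
  expect_equal(d, 2L)
})

test_that("allele tables sum dosages over cases and controls", {
  samples <- make_samples(2, 2)
  ref <- cnv_locus("L", "chr1", 0, 100, "deletion")
  t0 <- build_allele_table(ref, samples)
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0L, 4L, 0L, 4L))
  lc <- cnv_locus("L", "chr1", 0, 100, "deletion",
                  genotypes = c(P001 = 1L))
  t1 <- build_allele_table(lc, make_samples(1, 1))
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(1L, 1L, 0L, 2L))
  expect_error(build_allele_table(ref, make_samples(2, 2)[1:2, ]),
               "cases and controls")
})

test_that("odds ratio and Woolf interval reproduce published rows", {
  r <- odds_ratio_ci(allele_table(861, 95, 6026, 1570))
  expect_equal(round(r$or, 2), 2.36)
  expect_equal(round(r$ci_low, 2), 1.90)
  expect_equal(round(r$ci_high, 2), 2.94)

  r2 <- odds_ratio_ci(allele_table(776, 180, 5288, 2308))
  expect_equal(round(c(r2$or, r2$ci_low, r2$ci_high), 2),
               c(1.88, 1.59, 2.23))

  null <- odds_ratio_ci(allele_table(10, 10, 10, 10))
  expect_equal(null$or, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)

  expect_error(odds_ratio_ci(allele_table(0, 10, 10, 10)), "zero cell")
  h <- odds_ratio_ci(allele_table(0, 10, 10, 10), zero_rule = "haldane")
  expect_true(is.finite(h$or) && h$or > 0)

  # row swap inverts the estimate
  set.seed(3)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    a <- odds_ratio_ci(do.call(allele_table, as.list(cells)))$or
    b <- odds_ratio_ci(allele_table(cells[3], cells[4], cells[1],
                                    cells[2]))$or
    expect_equal(a * b, 1, tolerance = 1e-12)
  }
})

test_that("Pearson chi-squared matches the closed form and published p", {
  expect_equal(chi2_allelic(allele_table(861, 95, 6026, 1570))$p.value,
               2.84e-15, tolerance = 0.03)
  expect_equal(chi2_allelic(allele_table(776, 180, 5288, 2308))$p.value,
               1.22e-13, tolerance = 0.03)
  expect_equal(chi2_allelic(allele_table(801, 765, 947, 847))$p.value,
               0.34, tolerance = 0.02)
  eq <- chi2_allelic(allele_table(7, 7, 13, 13))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  expect_error(chi2_allelic(allele_table(0, 0, 5, 5)), "zero margin")

  set.seed(8)
  for (i in 1:20) {
    cells <- sample(1:80, 4, replace = TRUE)
    t <- do.call(allele_table, as.list(cells))
    m <- matrix(cells, 2, byrow = TRUE)
    # statistic equals the chi-squared(1) survival function route exactly
    mine <- chi2_allelic(t)
    expect_equal(mine$p.value,
                 pchisq(mine$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # and both variants agree with the standard contingency-table test
    expect_equal(mine$p.value,
                 suppressWarnings(chisq.test(m, correct = FALSE))$p.value,
                 tolerance = 1e-10)
    expect_equal(chi2_allelic(t, yates = TRUE)$p.value,
                 suppressWarnings(chisq.test(m, correct = TRUE))$p.value,
                 tolerance = 1e-10)
    # invariance under transposition and row/column swaps
    expect_equal(mine$statistic,
                 chi2_allelic(allele_table(cells[1], cells[3], cells[2],
                                           cells[4]))$statistic,
                 tolerance = 1e-12)
    expect_equal(mine$statistic,
                 chi2_allelic(allele_table(cells[2], cells[1], cells[4],
                                           cells[3]))$statistic,
                 tolerance = 1e-12)
  }
})

test_that("exact test equals brute-force enumeration and published values", {
  expect_equal(round(fisher_exact(allele_table(2, 954, 12, 7584)), 1), 0.7)
  expect_equal(round(fisher_exact(allele_table(2, 954, 3, 7593)), 1), 0.1)
  expect_equal(fisher_exact(allele_table(0, 0, 5, 5)), 1)
  expect_equal(fisher_exact(allele_table(0, 5, 0, 5)), 1)

  # brute-force oracle: enumerate all tables with the observed margins and
  # their probabilities from factorials directly
  brute <- function(a, b, c_, d) {
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d; n <- r1 + r2
    lp <- function(x) {
      lchoose(c1, x) + lchoose(c2, r1 - x) - lchoose(n, r1)
    }
    xs <- max(0, r1 - c2):min(r1, c1)
    probs <- exp(lp(xs))
    sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
  }
  set.seed(17)
  for (i in 1:40) {
    cells <- sample(0:50, 4, replace = TRUE)
    if (sum(cells) == 0 || sum(cells) > 200) next
    t <- do.call(allele_table, as.list(cells))
    p <- fisher_exact(t)
    expect_equal(p, min(1, brute(cells[1], cells[2], cells[3], cells[4])),
                 tolerance = 1e-12)
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("exact and chi-squared tests converge on large tables", {
  base <- c(52, 48, 50, 50)
  for (k in c(10, 30, 50)) {
    t <- do.call(allele_table, as.list(base * k))
    pf <- fisher_exact(t)
    pc <- chi2_allelic(t)$p.value
    expect_equal(pf, pc, tolerance = 0.1)
  }
})
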