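test_that("match score reproduces the exhaustive truth table", {
  # oracle over CN 0-4, written out by hand from the scoring rule:
  # rows = array CN 0..4, cols = MLPA CN 0..4
  oracle <- matrix(c(
    2, 1, 0, 0, 0,
    1, 2, 0, 0, 0,
    0, 0, 2, 0, 0,
    0, 0, 0, 2, 1,
    0, 0, 0, 1, 2), 5, 5, byrow = TRUE)
  for (a in 0:4) for (m in 0:4) {
    expect_equal(match_score(a, m), oracle[a + 1, m + 1],
                 info = sprintf("array=%d mlpa=%d", a, m))
  }
  # symmetry
  for (a in 0:4) for (m in 0:4) {
    expect_equal(match_score(a, m), match_score(m, a))
  }
  expect_error(match_score(-1, 0), ">= 0")
})

test_that("locus concordance summarises scores and validation", {
  rec <- data.frame(
    individual_id = sprintf("I%03d", 1:135), locus_id = "UXS1",
    array_cn = c(rep(1L, 85), rep(1L, 50)),
    mlpa_cn = c(rep(1L, 85), rep(2L, 50)), stringsAsFactors = FALSE)
  rec$score <- match_score(rec$array_cn, rec$mlpa_cn)
  res <- locus_concordance(rec, "deletion")
  expect_equal(round(res$discordance_rate, 3), 0.370)
  expect_true(res$validated)

  rec2 <- rec; rec2$mlpa_cn <- c(rep(1L, 87), rep(2L, 48))
  rec2$score <- match_score(rec2$array_cn, rec2$mlpa_cn)
  res2 <- locus_concordance(rec2, "deletion")
  expect_equal(res2$discordance_rate, 48 / 135, tolerance = 1e-12)

  # MLPA finding only reference states never validates the locus
  rec3 <- rec; rec3$mlpa_cn <- 2L
  rec3$score <- match_score(rec3$array_cn, rec3$mlpa_cn)
  expect_false(locus_concordance(rec3, "deletion")$validated)
  # mean score 2 <=> discordance 0
  rec4 <- rec; rec4$mlpa_cn <- rec4$array_cn
  rec4$score <- match_score(rec4$array_cn, rec4$mlpa_cn)
  res4 <- locus_concordance(rec4, "deletion")
  expect_equal(res4$mean_score, 2)
  expect_equal(res4$discordance_rate, 0)
  expect_error(locus_concordance(rec[0, ], "deletion"), "empty")
})

test_that("match records pair array and MLPA genotypes per individual", {
  lc <- cnv_locus("TRB", "chr7", 0, 13136, "deletion",
                  genotypes = c(P1 = 0L, P2 = 1L))
  mlpa <- data.frame(individual_id = c("P1", "P2", "P3"), locus_id = "TRB",
                     cn = c(0L, 2L, 2L), stringsAsFactors = FALSE)
  rec <- match_records(lc, mlpa)
  expect_equal(rec$array_cn, c(0L, 1L, 2L))  # P3 defaults to reference
  expect_equal(rec$score, c(2L, 0L, 2L))
  expect_error(match_records(lc, mlpa[mlpa$locus_id == "x", ]), "no MLPA")
})

test_that("Mann-Whitney exact enumeration and approximation behave", {
  # {2,2,2} vs {0,0,0}: U = 9; 2 of the C(6,3) = 20 assignments are as
  # extreme (all large values in one group), so the exact two-sided p = 0.1
  res <- mann_whitney(c(2, 2, 2), c(0, 0, 0))
  expect_equal(res$U, 9)
  expect_equal(res$p.value, 0.1)
  # identical distributions: p = 1
  expect_equal(mann_whitney(c(0, 1, 2), c(0, 1, 2))$p.value, 1)
  expect_equal(mann_whitney(rep(1, 20), rep(1, 25), exact = FALSE)$p.value, 1)
  # tie-free exact case agrees with the reference implementation
  set.seed(5)
  x <- sample(1:100, 8); y <- sample(101:200, 6)
  expect_equal(mann_whitney(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  # large tied samples: tie-corrected normal approximation matches
  xs <- rep(0:2, times = c(10, 15, 9))
  ys <- rep(0:2, times = c(5, 12, 20))
  expect_equal(mann_whitney(xs, ys, exact = FALSE)$p.value,
               wilcox.test(xs, ys, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("per-type validation summary reports rates and the rank test", {
  loci <- data.frame(
    locus_id = sprintf("L%02d", 1:28),
    cnv_type = rep(c("deletion", "duplication"), c(11, 17)),
    n_assayed = 10,
    mean_score = c(rep(1.8, 8), rep(0.5, 3), rep(1.6, 2), rep(0.2, 15)),
    discordance_rate = 0.2,
    validated = c(rep(TRUE, 8), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 15)),
    stringsAsFactors = FALSE)
  res <- type_validation_summary(loci)
  expect_equal(round(res$by_type$pct_validated), c(73, 12))
  expect_equal(res$by_type$n_validated, c(8L, 2L))
  expect_lt(res$p, 0.05)
  # one type absent: table only
  res_del <- type_validation_summary(loci[loci$cnv_type == "deletion", ])
  expect_true(is.na(res_del$p))
  expect_equal(res_del$by_type$n_loci, c(11L, 0L))
})

test_that("discordance estimates the configured miscall rate on synthetic data", {
  n <- 10000
  set.seed(31)
  cn <- stats::setNames(draw_genotypes(0.3, n, "deletion"),
                        sprintf("I%05d", 1:n))
  truth <- cnv_locus("L1", "chr1", 0, 5000, "deletion", genotypes = cn)
  sp <- locus_spec("L1", "deletion", 0.3, 1, marker_mean = 1,
                   marker_spacing_bp = 5000)
  rate <- 0.12
  res <- corrupt_to_array_calls(truth, sp, error_model(
    alpha_del = qlogis(rate), beta = 1), seed = 31)
  observed <- cnv_locus("L1", "chr1", 0, 5000, "deletion",
                        genotypes = res$observed)
  mlpa <- emit_mlpa(truth, 0, seed = 31)  # exact reference
  rec <- match_records(observed, mlpa)
  conc <- locus_concordance(rec, "deletion")
  expect_lt(abs(conc$discordance_rate - rate),
            3 * sqrt(rate * (1 - rate) / n))
})

test_that("deletions outscore duplications when alpha_del < alpha_dup", {
  model <- error_model(alpha_del = -2, alpha_dup = 1, beta = 0)
  mean_score_of <- function(ty, seed) {
    set.seed(seed)
    q <- 0.3
    g <- draw_genotypes(q, 1000, ty)
    cn <- stats::setNames(g, sprintf("I%04d", 1:1000))
    lc <- cnv_locus(paste0(ty, seed), "chr1", 0, 5000, ty, genotypes = cn)
    sp <- locus_spec(lc$locus_id, ty, q, 1, marker_mean = 1,
                     marker_spacing_bp = 5000)
    res <- corrupt_to_array_calls(lc, sp, model, seed = seed)
    obs <- cnv_locus(lc$locus_id, "chr1", 0, 5000, ty,
                     genotypes = res$observed)
    rec <- match_records(obs, emit_mlpa(lc, 0, seed = seed))
    locus_concordance(rec, ty)$mean_score
  }
  del_scores <- vapply(1:5, function(s) mean_score_of("deletion", s),
                       numeric(1))
  dup_scores <- vapply(1:5, function(s) mean_score_of("duplication", s),
                       numeric(1))
  expect_true(all(del_scores > dup_scores))
})
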