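# Allelic case-control association statistics on 2x2 allele-count tables.

#' CNV allele dosage of a copy-number genotype
#'
#' Number of CNV alleles a diploid individual carries: `2 - cn` at a
#' deletion locus and `min(cn - 2, 2)` at a duplication locus (a biallelic
#' duplication-allele model; states above CN 4 are clamped with a warning).
#'
#' @param cn Integer copy number(s), >= 0.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @return Integer dosage(s) in \[0, 2\].
#' @export
allele_dosage <- function(cn, cnv_type) {
  cnv_type <- match.arg(cnv_type, c("deletion", "duplication"))
  cn <- as.integer(cn)
  if (any(cn < 0)) stop("copy number must be >= 0")
  if (cnv_type == "deletion") {
    if (any(cn > 2)) {
      stop("copy number > 2 is inconsistent with a deletion locus")
    }
    2L - cn
  } else {
    if (any(cn < 2)) {
      stop("copy number < 2 is inconsistent with a duplication locus")
    }
    if (any(cn > 4)) {
      warning("copy number > 4 clamped to dosage 2 (biallelic model)")
    }
    pmin(cn - 2L, 2L)
  }
}

#' Construct a 2x2 allele-count table
#'
#' @param a Risk alleles in cases.
#' @param b Non-risk alleles in cases.
#' @param c Risk alleles in controls.
#' @param d Non-risk alleles in controls.
#' @return An object of class `allele_table`.
#' @export
allele_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("allele counts must be non-negative integers")
  }
  structure(as.list(cells), class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("risk", "non-risk")))
  print(m)
  invisible(x)
}

#' Build the allele table of a locus
#'
#' Sums CNV allele dosages over cases and controls; each group contributes
#' `2 * n` alleles in total, with individuals absent from the locus's
#' genotype map contributing dosage 0 (reference CN 2).
#'
#' @param locus A [cnv_locus()].
#' @param samples Sample sheet data.frame (`id`, `status`).
#' @return An [allele_table()].
#' @export
build_allele_table <- function(locus, samples) {
  if (!any(samples$status == "case") || !any(samples$status == "control")) {
    stop("both cases and controls are required")
  }
  cn <- locus_genotypes(locus, samples)
  dos <- allele_dosage(cn, locus$cnv_type)
  a <- sum(dos[samples$status == "case"])
  c_ <- sum(dos[samples$status == "control"])
  n_case <- sum(samples$status == "case")
  n_ctrl <- sum(samples$status == "control")
  allele_table(a, 2L * n_case - a, c_, 2L * n_ctrl - c_)
}

#' Allelic odds ratio with Woolf confidence interval
#'
#' Point estimate `(a d) / (b c)` and the Woolf (log-scale normal) interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell leaves
#' the estimate undefined; the Haldane-Anscombe rule (add 0.5 to every cell,
#' for the estimate and interval only, never for tests) can be enabled via
#' `zero_rule = "haldane"`.
#'
#' @param t An [allele_table()].
#' @param conf Confidence level (default 0.95).
#' @param zero_rule `"error"` (default) or `"haldane"`.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_ci(allele_table(861, 95, 6026, 1570))  # OR 2.36 [1.90, 2.94]
#' @export
odds_ratio_ci <- function(t, conf = 0.95, zero_rule = c("error", "haldane")) {
  zero_rule <- match.arg(zero_rule)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (zero_rule == "error") {
      stop("zero cell: odds ratio undefined (enable zero_rule = 'haldane')")
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se))
}

#' Pearson chi-squared test on an allele table
#'
#' Uncorrected Pearson statistic
#' `N (a d - b c)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom;
#' the Yates continuity correction subtracts `N/2` from `|a d - b c|`
#' (floored at 0) when enabled.
#'
#' @param t An [allele_table()].
#' @param yates Apply the continuity correction (default `FALSE`).
#' @return List with `statistic` and `p.value`.
#' @export
chi2_allelic <- function(t, yates = FALSE) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("chi-squared test undefined with a zero margin")
  num <- abs(a * d - b * c_)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on an allele table
#'
#' Exact enumeration over the hypergeometric support of tables with the
#' observed margins: the two-sided p-value sums the probabilities of all
#' tables no more probable than the observed one (minimum-likelihood
#' convention, with relative tolerance 1e-7 for the comparison). Any table
#' with a zero margin has p = 1.
#'
#' @param t An [allele_table()].
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(allele_table(2, 954, 12, 7584))  # ~0.66
#' @export
fisher_exact <- function(t) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  m <- a + c_          # risk-allele margin
  n <- b + d           # non-risk margin
  k <- a + b           # case margin
  if (m == 0 || n == 0 || k == 0 || c_ + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Full association summary of a locus
#'
#' Convenience wrapper combining [build_allele_table()], [odds_ratio_ci()],
#' [chi2_allelic()] and [fisher_exact()] into one row of results.
#'
#' @param locus A [cnv_locus()].
#' @param samples Sample sheet data.frame.
#' @param yates Continuity-correct the chi-squared test.
#' @param zero_rule Zero-cell rule for the odds ratio (see
#'   [odds_ratio_ci()]).
#' @return One-row data.frame with counts, per-group risk-allele
#'   frequencies, odds ratio, confidence bounds and both p-values.
#' @export
associate_locus <- function(locus, samples, yates = FALSE,
                            zero_rule = "error") {
  t <- build_allele_table(locus, samples)
  or <- odds_ratio_ci(t, zero_rule = zero_rule)
  chi <- chi2_allelic(t, yates = yates)
  data.frame(locus_id = locus$locus_id, cnv_type = locus$cnv_type,
             a = t$a, b = t$b, c = t$c, d = t$d,
             case_freq = t$a / (t$a + t$b),
             control_freq = t$c / (t$c + t$d),
             or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
             chi2_p = chi$p.value, fisher_p = fisher_exact(t),
             stringsAsFactors = FALSE)
}
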