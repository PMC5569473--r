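# Shared builders for in-code fixtures.

make_calls <- function(individual_id, start, end, cn_state, marker_count,
                       chrom = "chr1") {
  n <- length(individual_id)
  start <- rep_len(start, n); end <- rep_len(end, n)
  cn_state <- rep_len(cn_state, n); marker_count <- rep_len(marker_count, n)
  chrom <- rep_len(chrom, n)
  df <- data.frame(individual_id = individual_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   cn_state = as.integer(cn_state),
                   marker_count = as.integer(marker_count),
                   stringsAsFactors = FALSE)
  df$span <- df$end - df$start
  df
}

make_samples <- function(n_case, n_control, batches = "b1") {
  data.frame(
    id = c(sprintf("P%03d", seq_len(n_case)),
           sprintf("C%03d", seq_len(n_control))),
    status = factor(rep(c("case", "control"), c(n_case, n_control)),
                    levels = c("case", "control")),
    batch = rep_len(batches, n_case + n_control),
    stringsAsFactors = FALSE)
}

# Truth locus with every cohort member's CN given explicitly.
make_truth_locus <- function(cn, cnv_type = "deletion", locus_id = "L1",
                             chrom = "chr1", start = 0L, end = 10000L) {
  if (is.null(names(cn))) names(cn) <- sprintf("I%05d", seq_along(cn))
  cnv_locus(locus_id, chrom, start, end, cnv_type, genotypes = cn)
}

write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     ...)
  path
}

# Independent grid-search oracle for the unphased r2: allele frequencies of
# any EM stationary point equal the sample frequencies, so the likelihood is
# maximised over the single free haplotype frequency p11 on a 1e-4 grid.
r2_grid_oracle <- function(gA, gB, step = 1e-4) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  cnt <- tabulate(gA * 3 + gB + 1, nbins = 9)  # (gA, gB) class counts
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  loglik <- function(p11) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    if (min(p00, p01, p10, p11) < -1e-12) return(-Inf)
    # genotype-class probabilities under random union of haplotypes,
    # ordered as (gA, gB) = (0,0) (0,1) (0,2) (1,0) (1,1) (1,2) (2,0) (2,1) (2,2)
    pr <- c(p00^2, 2 * p00 * p01, p01^2,
            2 * p00 * p10, 2 * p00 * p11 + 2 * p01 * p10, 2 * p01 * p11,
            p10^2, 2 * p10 * p11, p11^2)
    sum(cnt * log(pmax(pr, 1e-300)))
  }
  # coarse grid at `step`, then local refinement around the best point
  grid <- seq(lo, hi, by = step)
  best <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  fine <- seq(max(lo, best - step), min(hi, best + step), by = step / 100)
  p11 <- fine[which.max(vapply(fine, loglik, numeric(1)))]
  d <- p11 - pA * pB
  d^2 / (pA * (1 - pA) * pB * (1 - pB))
}
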