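# LD-region construction around lead SNPs and CNV overlap screening.

#' Squared correlation (r2) between two unphased SNPs
#'
#' Estimates haplotype frequencies from unphased diploid dosages by
#' expectation-maximization over the double-heterozygote phase ambiguity
#' (all other genotype pairs resolve unambiguously), then returns
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))` where `D` is the haplotype
#' disequilibrium coefficient. Individuals missing either genotype are
#' dropped pairwise. Convergence: maximum haplotype-frequency change below
#' `tol` or `max_iter` iterations.
#'
#' @param gA,gB Numeric dosage vectors in \{0, 1, 2\} (NA = missing).
#' @param tol EM convergence tolerance (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return `r2` in \[0, 1\], or `NA` when either SNP is monomorphic among
#'   the complete pairs.
#' @export
r2_unphased <- function(gA, gB, tol = 1e-10, max_iter = 1000L) {
  if (length(gA) != length(gB)) stop("dosage vectors must have equal length")
  ok <- !is.na(gA) & !is.na(gB)
  gA <- as.integer(gA[ok]); gB <- as.integer(gB[ok])
  n <- length(gA)
  if (n < 2) stop("at least 2 individuals with both genotypes are required")
  if (any(gA < 0 | gA > 2) || any(gB < 0 | gB > 2)) {
    stop("dosages must lie in {0, 1, 2}")
  }
  pA <- mean(gA) / 2
  pB <- mean(gB) / 2
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  # genotype-pair counts; only (1,1) is phase-ambiguous
  idx <- gA * 3L + gB + 1L            # 1..9 for (gA, gB) in {0,1,2}^2
  cnt <- tabulate(idx, nbins = 9L)
  n11_amb <- cnt[5]                   # double heterozygotes
  # unambiguous haplotype counts: h = (alleleA, alleleB) in {00, 01, 10, 11}
  base <- c(
    `00` = 2 * cnt[1] + cnt[2] + cnt[4],
    `01` = 2 * cnt[3] + cnt[2] + cnt[6],
    `10` = 2 * cnt[7] + cnt[4] + cnt[8],
    `11` = 2 * cnt[9] + cnt[6] + cnt[8])
  p <- rep(0.25, 4)
  for (iter in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5  # P(phase 00/11 | het-het)
    h <- base + n11_amb * c(w, 1 - w, 1 - w, w)
    p_new <- h / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  d <- p[4] - (p[3] + p[4]) * (p[2] + p[4])
  unname(d^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' LD region around a lead SNP
#'
#' Collects every panel SNP whose r2 with the lead exceeds `threshold`
#' (strict inequality; the lead itself is always a member) and returns the
#' bounding half-open interval of the member positions.
#'
#' @param lead_id Identifier of the lead SNP (must be in the panel).
#' @param panel SNP panel from [read_snp_matrix()] (`snp_id`, `position`,
#'   `dosages`).
#' @param chrom Chromosome label attached to the region (default "chr1").
#' @param threshold r2 threshold (default 0.1, strict).
#' @return List of class `ld_region`: `lead_snp_id`, `chrom`, `start`,
#'   `end` (0-based half-open bounding interval) and `members` (data.frame
#'   `snp_id`, `position`, `r2`).
#' @export
ld_region <- function(lead_id, panel, chrom = "chr1", threshold = 0.1) {
  i <- match(lead_id, panel$snp_id)
  if (is.na(i)) stop(sprintf("lead SNP %s not in panel", lead_id))
  lead <- panel$dosages[i, ]
  r2 <- vapply(seq_along(panel$snp_id), function(j) {
    if (j == i) return(1)
    v <- tryCatch(r2_unphased(lead, panel$dosages[j, ]),
                  error = function(e) NA_real_)
    v
  }, numeric(1))
  if (is.na(r2[i]) || stats::sd(lead, na.rm = TRUE) == 0) {
    stop(sprintf("lead SNP %s is monomorphic", lead_id))
  }
  member <- which(!is.na(r2) & r2 > threshold)
  member <- union(i, member)
  members <- data.frame(snp_id = panel$snp_id[member],
                        position = panel$position[member],
                        r2 = r2[member], stringsAsFactors = FALSE)
  members <- members[order(members$position), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(lead_snp_id = lead_id, chrom = chrom,
                 start = min(members$position),
                 end = max(members$position) + 1L,
                 members = members),
            class = "ld_region")
}

#' @export
print.ld_region <- function(x, ...) {
  cat(sprintf("<ld_region lead=%s %s:%d-%d, %d member SNP(s)>\n",
              x$lead_snp_id, x$chrom, x$start, x$end, nrow(x$members)))
  invisible(x)
}

#' Screen CNV loci for overlap with LD regions
#'
#' Lists every (locus, region) pair whose half-open intervals share at least
#' one base, with per-group CNV allele frequencies attached and rare CNVs
#' (overall allele frequency below `rare_maf`) flagged.
#'
#' @param loci List of [cnv_locus()] objects.
#' @param regions List of [ld_region()] objects.
#' @param samples Sample sheet data.frame for the frequencies.
#' @param rare_maf Rarity threshold on the pooled CNV allele frequency
#'   (default 0.05).
#' @return Data.frame with one row per overlapping pair (possibly empty):
#'   locus, region lead, interval coordinates, per-group allele counts and
#'   frequencies, `rare` flag.
#' @export
overlap_screen <- function(loci, regions, samples, rare_maf = 0.05) {
  if (inherits(loci, "cnv_locus")) loci <- list(loci)
  if (inherits(regions, "ld_region")) regions <- list(regions)
  rows <- list()
  for (lc in loci) {
    t <- build_allele_table(lc, samples)
    freq_all <- (t$a + t$c) / (t$a + t$b + t$c + t$d)
    for (rg in regions) {
      if (lc$chrom != rg$chrom) next
      if (interval_overlap(lc$start, lc$end, rg$start, rg$end) < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = lc$locus_id, cnv_type = lc$cnv_type,
        lead_snp_id = rg$lead_snp_id, chrom = lc$chrom,
        locus_start = lc$start, locus_end = lc$end,
        region_start = rg$start, region_end = rg$end,
        case_alleles = t$a, case_freq = t$a / (t$a + t$b),
        control_alleles = t$c, control_freq = t$c / (t$c + t$d),
        rare = freq_all < rare_maf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(0), cnv_type = character(0),
                      lead_snp_id = character(0), chrom = character(0),
                      locus_start = integer(0), locus_end = integer(0),
                      region_start = integer(0), region_end = integer(0),
                      case_alleles = integer(0), case_freq = numeric(0),
                      control_alleles = integer(0), control_freq = numeric(0),
                      rare = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
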