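# Array-vs-MLPA match-score concordance framework.

#' CNV type of a copy-number state
#'
#' @param cn Integer copy number(s).
#' @return `"deletion"` (CN < 2), `"reference"` (CN = 2) or `"duplication"`
#'   (CN > 2).
#' @export
cn_type <- function(cn) {
  ifelse(cn < 2, "deletion", ifelse(cn == 2, "reference", "duplication"))
}

#' Match score between an array and an MLPA genotype
#'
#' Per-individual agreement statistic between the two platforms: 2 when both
#' genotypes agree in type and copy number (i.e. are identical, including
#' reference-vs-reference); 1 when both are non-reference of the same type
#' (deletion or duplication) but differ in copy number; 0 otherwise,
#' including every reference-vs-CNV disagreement.
#'
#' @param array_cn,mlpa_cn Integer copy numbers, >= 0 (vectorised).
#' @return Integer score(s) in \{0, 1, 2\}.
#' @examples
#' match_score(1, 1)  # 2
#' match_score(0, 1)  # 1
#' match_score(1, 3)  # 0
#' @export
match_score <- function(array_cn, mlpa_cn) {
  if (any(array_cn < 0) || any(mlpa_cn < 0)) stop("copy numbers must be >= 0")
  ta <- cn_type(array_cn)
  tm <- cn_type(mlpa_cn)
  ifelse(array_cn == mlpa_cn, 2L,
         ifelse(ta == tm & ta != "reference", 1L, 0L))
}

#' Pair array and MLPA genotypes into match records
#'
#' Restricts to individuals assayed by MLPA at the locus, attaches the
#' array-derived copy number (CN 2 for individuals without a non-reference
#' array genotype) and computes the per-individual match score.
#'
#' @param locus A [cnv_locus()] holding the array-derived genotypes.
#' @param mlpa MLPA data.frame (`individual_id`, `locus_id`, `cn`).
#' @return Data.frame with columns `individual_id`, `locus_id`, `array_cn`,
#'   `mlpa_cn`, `score`.
#' @export
match_records <- function(locus, mlpa) {
  rec <- mlpa[mlpa$locus_id == locus$locus_id, , drop = FALSE]
  if (nrow(rec) == 0) stop(sprintf("no MLPA records for locus %s",
                                   locus$locus_id))
  array_cn <- rep(2L, nrow(rec))
  known <- rec$individual_id %in% names(locus$genotypes)
  array_cn[known] <- locus$genotypes[rec$individual_id[known]]
  data.frame(individual_id = rec$individual_id, locus_id = locus$locus_id,
             array_cn = array_cn, mlpa_cn = rec$cn,
             score = match_score(array_cn, rec$cn),
             stringsAsFactors = FALSE)
}

#' Per-locus concordance summary
#'
#' Mean match score, discordance rate (fraction of individuals with score
#' below 2, i.e. any disagreement in copy number), and the locus-level
#' validation call: a locus is validated when MLPA independently confirms at
#' least `min_confirmed` non-reference genotype(s) of the locus's CNV type.
#'
#' @param records Match-record data.frame from [match_records()] (one
#'   locus).
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param min_confirmed Minimum number of MLPA-confirmed non-reference
#'   genotypes for validation (default 1).
#' @return One-row data.frame: `locus_id`, `cnv_type`, `n_assayed`,
#'   `mean_score`, `discordance_rate`, `validated`.
#' @export
locus_concordance <- function(records, cnv_type, min_confirmed = 1L) {
  if (nrow(records) == 0) stop("empty match-record set")
  cnv_type <- match.arg(cnv_type, c("deletion", "duplication"))
  confirmed <- sum(records$mlpa_cn != 2L & cn_type(records$mlpa_cn) == cnv_type)
  data.frame(locus_id = records$locus_id[1], cnv_type = cnv_type,
             n_assayed = nrow(records),
             mean_score = mean(records$score),
             discordance_rate = mean(records$score < 2L),
             validated = confirmed >= min_confirmed,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided test of a location difference between two samples. With both
#' groups of size <= 12 the exact permutation distribution of the
#' Mann-Whitney U statistic is enumerated over all assignments of the
#' observed values (which handles ties exactly); otherwise the tie-corrected
#' normal approximation is used (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses it when both groups have <= 12 observations.
#' @return List with `U` (count of (x, y) pairs with x > y, plus half-ties)
#'   and `p.value`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  u_stat <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- n1 <= 12 && n2 <= 12
  if (exact) {
    pooled <- c(x, y)
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    pooled <- c(x, y)
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p.value = 1))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p.value = min(1, p))
}

#' Deletion-vs-duplication validation summary
#'
#' Aggregates per-locus concordance rows into a per-type table (number of
#' loci, number and percentage validated, mean of the per-locus mean match
#' scores) and compares the per-locus mean-match-score distributions of
#' deletions and duplications with a two-sided Mann-Whitney rank-sum test.
#' With pooled mode, per-individual scores are pooled across loci of each
#' type instead.
#'
#' @param loci Data.frame of [locus_concordance()] rows.
#' @param scores Optional match-record data.frame for `pooled = TRUE` mode.
#' @param pooled Compare pooled per-individual scores rather than per-locus
#'   means (default `FALSE`).
#' @return List with `by_type` (summary data.frame) and `p` (Mann-Whitney
#'   p-value; `NA` when a type is absent).
#' @export
type_validation_summary <- function(loci, scores = NULL, pooled = FALSE) {
  types <- c("deletion", "duplication")
  by_type <- do.call(rbind, lapply(types, function(ty) {
    sub <- loci[loci$cnv_type == ty, , drop = FALSE]
    data.frame(cnv_type = ty, n_loci = nrow(sub),
               n_validated = sum(sub$validated),
               pct_validated = if (nrow(sub) > 0) {
                 100 * sum(sub$validated) / nrow(sub)
               } else NA_real_,
               mean_of_mean_scores = if (nrow(sub) > 0) {
                 mean(sub$mean_score)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(by_type$n_loci == 0)) {
    return(list(by_type = by_type, p = NA_real_))
  }
  if (pooled) {
    if (is.null(scores)) stop("pooled mode requires the match records")
    ty_of <- stats::setNames(loci$cnv_type, loci$locus_id)
    g <- ty_of[scores$locus_id]
    p <- mann_whitney(scores$score[g == "deletion"],
                      scores$score[g == "duplication"])$p.value
  } else {
    p <- mann_whitney(loci$mean_score[loci$cnv_type == "deletion"],
                      loci$mean_score[loci$cnv_type == "duplication"])$p.value
  }
  list(by_type = by_type, p = p)
}
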