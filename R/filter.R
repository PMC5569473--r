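# Call-level inclusion filters and the batch-frequency heterogeneity screen.

#' Define a CNV call inclusion policy
#'
#' The default policy keeps calls supported by at least 5 array markers and
#' spanning at least 5000 bp — the standard stringency for array-based CNV
#' screens. Both thresholds are inclusive. Disabling the policy re-admits
#' sub-threshold calls, which is how the "unfiltered" re-analysis of an
#' association is performed.
#'
#' @param min_markers Minimum marker count, >= 1 (default 5).
#' @param min_span_bp Minimum segment span in bp, >= 1 (default 5000).
#' @param enabled If `FALSE` the filter passes everything through.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_markers = 5L, min_span_bp = 5000L,
                          enabled = TRUE) {
  if (min_markers < 1 || min_span_bp < 1) {
    stop("thresholds must be >= 1")
  }
  structure(list(min_markers = as.integer(min_markers),
                 min_span_bp = as.integer(min_span_bp),
                 enabled = isTRUE(enabled)),
            class = "filter_policy")
}

#' Partition CNV calls by the inclusion policy
#'
#' @param calls Validated call data.frame (see [read_cnv_calls()]).
#' @param policy A [filter_policy()].
#' @return List with `kept` and `dropped` data.frames; an exact partition of
#'   the input.
#' @export
filter_calls <- function(calls, policy = filter_policy()) {
  if (!"span" %in% names(calls)) calls$span <- calls$end - calls$start
  if (!policy$enabled) {
    return(list(kept = calls, dropped = calls[0, , drop = FALSE]))
  }
  keep <- calls$marker_count >= policy$min_markers &
    calls$span >= policy$min_span_bp
  list(kept = calls[keep, , drop = FALSE],
       dropped = calls[!keep, , drop = FALSE])
}

#' Genotype a CNV locus from segment calls
#'
#' Assigns each cohort member a copy number at a canonical locus: the
#' `cn_state` of their kept call(s) matching the locus by reciprocal overlap
#' (shared bases must cover at least `reciprocal` of *both* the locus and
#' the call), defaulting to the reference state CN 2 for individuals with no
#' matching call. Two matching calls with conflicting states for the same
#' individual are an ambiguity error.
#'
#' @param calls Call data.frame.
#' @param locus_id,chrom,start,end,cnv_type Canonical locus definition
#'   (0-based half-open interval).
#' @param samples Sample sheet data.frame; the cohort denominator.
#' @param policy A [filter_policy()]; pass `filter_policy(enabled = FALSE)`
#'   to re-admit sub-threshold calls (the "unfiltered" mode).
#' @param reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return A [cnv_locus()] carrying the non-reference genotypes.
#' @export
genotype_locus <- function(calls, locus_id, chrom, start, end, cnv_type,
                           samples, policy = filter_policy(),
                           reciprocal = 0.5) {
  kept <- filter_calls(calls, policy)$kept
  kept <- kept[kept$chrom == chrom & kept$individual_id %in% samples$id, ,
               drop = FALSE]
  ov <- interval_overlap(kept$start, kept$end, start, end)
  locus_span <- end - start
  hit <- ov >= reciprocal * locus_span & ov >= reciprocal * kept$span
  kept <- kept[hit, , drop = FALSE]
  geno <- integer(0)
  if (nrow(kept) > 0) {
    by_ind <- split(kept$cn_state, kept$individual_id)
    states <- vapply(by_ind, function(s) {
      u <- unique(s)
      if (length(u) > 1) NA_integer_ else u[1]
    }, integer(1))
    if (anyNA(states)) {
      stop(sprintf(
        "locus %s: conflicting copy-number states for individual(s): %s",
        locus_id, paste(names(states)[is.na(states)], collapse = ", ")))
    }
    geno <- states
  }
  cnv_locus(locus_id, chrom, start, end, cnv_type, genotypes = geno)
}

#' Screen a locus for batch heterogeneity of carrier frequency
#'
#' Systematic frequency differences between groups of conjointly processed
#' arrays (batch effects) are a major confounder of array-based CNV
#' association. This screen tabulates carriers (CN != 2) versus
#' non-carriers by batch and applies an uncorrected Pearson chi-squared
#' test; loci with p below `flag_threshold` are flagged for inspection. It
#' is a transparent heterogeneity screen, not a mixed-model batch
#' correction.
#'
#' @param locus A [cnv_locus()].
#' @param samples Sample sheet with `id` and `batch` columns.
#' @param flag_threshold Flagging threshold on the p-value (default 0.05).
#' @return List with `p` (NA when only one batch is present), `applicable`,
#'   `flagged`, and `batch_freq` (per-batch carrier frequencies).
#' @export
batch_heterogeneity <- function(locus, samples, flag_threshold = 0.05) {
  cn <- locus_genotypes(locus, samples)
  carrier <- cn != 2L
  batch <- samples$batch
  if (length(unique(batch)) < 2) {
    return(list(p = NA_real_, applicable = FALSE, flagged = FALSE,
                batch_freq = tapply(carrier, batch, mean)))
  }
  tab <- table(batch, factor(carrier, levels = c(FALSE, TRUE)))
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  list(p = p, applicable = TRUE,
       flagged = is.finite(p) && p < flag_threshold,
       batch_freq = tapply(carrier, batch, mean))
}
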