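# Call reliability as a function of median segment size and marker count:
# the cumulative mean-of-mean-match-scores curve and its rank correlation.

#' Median segment size and marker count of a locus's calls
#'
#' @param calls Call data.frame of a single locus (>= 1 row).
#' @return List with `median_size_bp` and `median_marker_count`; medians use
#'   the average-of-middle-two convention for even counts.
#' @export
locus_call_medians <- function(calls) {
  if (nrow(calls) == 0) stop("no calls: medians undefined")
  if (!"span" %in% names(calls)) calls$span <- calls$end - calls$start
  list(median_size_bp = stats::median(calls$span),
       median_marker_count = stats::median(calls$marker_count))
}

#' Cumulative mean-of-means reliability curve
#'
#' For each locus i with ordering key `key_i` (median segment size or median
#' marker count) and per-locus mean match score `m_i`, the curve value is
#' the mean of the `m_j` over all loci whose key is greater than or equal to
#' `key_i` — the locus itself and every larger/better-supported locus,
#' key ties included. The value at the smallest key is therefore the grand
#' mean of all per-locus scores, and tied keys share one curve value.
#'
#' @param key Numeric vector of ordering keys.
#' @param m Numeric vector of per-locus mean match scores (same length).
#' @return Numeric vector of curve values, aligned with the input.
#' @examples
#' cumulative_mean_curve(c(10, 20, 30), c(0, 1, 2))  # 1.0 1.5 2.0
#' @export
cumulative_mean_curve <- function(key, m) {
  if (length(key) != length(m)) stop("key and m must have equal length")
  if (length(key) == 0) stop("at least one point is required")
  vapply(key, function(k) mean(m[key >= k]), numeric(1))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (standard midrank tie handling);
#' undefined (NA) when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Reliability table for a set of validated loci
#'
#' Joins per-locus mean match scores with the median size / marker count of
#' their calls, computes the cumulative mean-of-means curve under the chosen
#' key, and the Spearman correlation between key and curve.
#'
#' @param concordance Data.frame of [locus_concordance()] rows (`locus_id`,
#'   `mean_score`).
#' @param calls Call data.frame covering the loci (matched by a `locus_id`
#'   column; add one before calling if absent).
#' @param key `"size"` or `"markers"`.
#' @return List with `table` (one row per locus, sorted by key: locus, key
#'   value, mean score, cumulative mean) and `rho`.
#' @export
reliability_table <- function(concordance, calls, key = c("size", "markers")) {
  key <- match.arg(key)
  if (!"locus_id" %in% names(calls)) {
    stop("calls must carry a locus_id column for the reliability analysis")
  }
  med <- do.call(rbind, lapply(split(calls, calls$locus_id), function(cc) {
    m <- locus_call_medians(cc)
    data.frame(locus_id = cc$locus_id[1],
               median_size_bp = m$median_size_bp,
               median_marker_count = m$median_marker_count,
               stringsAsFactors = FALSE)
  }))
  tab <- merge(concordance[, c("locus_id", "mean_score")], med,
               by = "locus_id")
  if (nrow(tab) == 0) stop("no loci shared between scores and calls")
  tab$key <- if (key == "size") tab$median_size_bp else tab$median_marker_count
  tab$cumulative_mean <- cumulative_mean_curve(tab$key, tab$mean_score)
  tab <- tab[order(tab$key, tab$locus_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, rho = spearman_rho(tab$key, tab$cumulative_mean))
}
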