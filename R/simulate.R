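# Synthetic case-control cohorts with known truth: Hardy-Weinberg CN
# genotypes, array calls corrupted by a type- and marker-count-dependent
# miscall process with batch shifts, and near-truth MLPA observations.

#' Case allele frequency implied by an allelic odds ratio
#'
#' Inverts the allelic odds ratio: given the control frequency `q` of the
#' CNV allele and the case-vs-control odds ratio `theta`, returns the case
#' frequency `theta * w / (1 + theta * w)` with `w = q / (1 - q)`, so that
#' the odds ratio recomputed from the two frequencies equals `theta`.
#'
#' @param q Control allele frequency, strictly inside (0, 1).
#' @param theta Allelic odds ratio, > 0.
#' @return Case allele frequency in (0, 1).
#' @examples
#' case_allele_freq(0.793, 2.36)  # ~0.900
#' @export
case_allele_freq <- function(q, theta) {
  if (any(q <= 0) || any(q >= 1)) stop("q must lie strictly inside (0, 1)")
  if (any(theta <= 0)) stop("theta must be > 0")
  w <- q / (1 - q)
  theta * w / (1 + theta * w)
}

#' Specify a CNV locus for simulation
#'
#' @param locus_id Locus identifier.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param q_control Control frequency of the CNV allele, in (0, 1).
#' @param odds_ratio Allelic case-vs-control odds ratio, > 0.
#' @param chrom,start,end Canonical interval (0-based half-open).
#' @param marker_mean Mean marker count per called segment (>= 1).
#' @param marker_dispersion Negative-binomial size parameter of the
#'   marker-count distribution; larger values give tighter counts.
#' @param marker_spacing_bp Mean spacing between adjacent markers; a call
#'   covering m markers spans `m * marker_spacing_bp` bases.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(locus_id, cnv_type, q_control, odds_ratio,
                       chrom = "chr1", start = 1000000L, end = 1010000L,
                       marker_mean = 20, marker_dispersion = 10,
                       marker_spacing_bp = 500) {
  cnv_type <- match.arg(cnv_type, c("deletion", "duplication"))
  if (q_control <= 0 || q_control >= 1) stop("q_control must be in (0, 1)")
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  if (marker_mean < 1) stop("marker_mean must be >= 1")
  structure(list(locus_id = locus_id, cnv_type = cnv_type,
                 q_control = q_control, odds_ratio = odds_ratio,
                 chrom = chrom, start = as.integer(start),
                 end = as.integer(end), marker_mean = marker_mean,
                 marker_dispersion = marker_dispersion,
                 marker_spacing_bp = marker_spacing_bp),
            class = "locus_spec")
}

#' Specify the array miscall and MLPA error model
#'
#' The probability that the array miscalls an individual's true copy number
#' is `plogis(alpha_type - beta * log(markers) + batch_shift)`: a per-type
#' intercept on the log-odds scale, a reliability gain per unit log marker
#' count, and an additive per-batch shift. A miscalled individual receives a
#' uniformly chosen different admissible state (deletion loci: \{0, 1, 2\};
#' duplication loci: \{2, 3, 4\}). MLPA reproduces truth with probability
#' `1 - mlpa_error`.
#'
#' @param alpha_del,alpha_dup Miscall log-odds intercepts for deletions and
#'   duplications.
#' @param beta Reliability gain per unit `log(marker_count)`, >= 0.
#' @param mlpa_error MLPA per-genotype error rate in \[0, 1).
#' @param batch_effects Named numeric vector of additive log-odds shifts per
#'   batch label; batches not listed shift by 0.
#' @return An object of class `error_model`.
#' @export
error_model <- function(alpha_del = -1, alpha_dup = 1, beta = 1,
                        mlpa_error = 0, batch_effects = numeric(0)) {
  if (beta < 0) stop("beta must be >= 0")
  if (mlpa_error < 0 || mlpa_error >= 1) stop("mlpa_error must be in [0, 1)")
  structure(list(alpha_del = alpha_del, alpha_dup = alpha_dup, beta = beta,
                 mlpa_error = mlpa_error, batch_effects = batch_effects),
            class = "error_model")
}

admissible_states <- function(cnv_type) {
  if (cnv_type == "deletion") c(0L, 1L, 2L) else c(2L, 3L, 4L)
}

#' Array miscall probability under an error model
#'
#' @param model An [error_model()].
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param markers Marker count(s) supporting the call.
#' @param batch Batch label(s); unlisted batches shift the log-odds by 0.
#' @return Miscall probabilities in (0, 1).
#' @export
miscall_prob <- function(model, cnv_type, markers, batch = NULL) {
  alpha <- if (cnv_type == "deletion") model$alpha_del else model$alpha_dup
  shift <- 0
  if (!is.null(batch) && length(model$batch_effects) > 0) {
    shift <- ifelse(batch %in% names(model$batch_effects),
                    unname(model$batch_effects[batch]), 0)
    shift[is.na(shift)] <- 0
  }
  stats::plogis(alpha - model$beta * log(markers) + shift)
}

# Deterministic named substream: each simulation stage draws from its own
# seed derived from (master seed, stream name), so adding loci or stages
# never perturbs the draws of earlier ones.
substream_seed <- function(master, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(master) * 48271 + h) %% 2147483629) + 1L
}

with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, name))
  force(expr)
}

#' Draw Hardy-Weinberg copy-number genotypes
#'
#' Each individual carries `rbinom(1, 2, q)` CNV alleles; deletions give
#' CN `2 - alleles`, duplications `2 + alleles`, i.e. genotype proportions
#' `q^2`, `2q(1-q)`, `(1-q)^2` for the homozygous-CNV, heterozygous and
#' reference states.
#'
#' @param q CNV allele frequency in \[0, 1\].
#' @param n Number of individuals, >= 1.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @return Integer vector of `n` copy numbers.
#' @export
draw_genotypes <- function(q, n, cnv_type = "deletion") {
  cnv_type <- match.arg(cnv_type, c("deletion", "duplication"))
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  alleles <- stats::rbinom(n, 2L, q)
  if (cnv_type == "deletion") 2L - alleles else 2L + alleles
}

# Replace true states by a uniformly chosen different admissible state with
# per-individual probability p.
perturb_states <- function(cn, p, states) {
  hit <- stats::runif(length(cn)) < p
  if (any(hit)) {
    cn[hit] <- vapply(cn[hit], function(s) {
      others <- states[states != s]
      others[sample.int(length(others), 1L)]
    }, integer(1))
  }
  cn
}

#' Corrupt true genotypes into array-style segment calls
#'
#' Applies the error model's marker-count dependent miscall process to a
#' truth locus and emits one [read_cnv_calls()]-style row per individual
#' whose *observed* state is non-reference. Marker counts are drawn per
#' individual as `1 + rnbinom(mu = marker_mean - 1, size = dispersion)` and
#' the segment span is `markers * marker_spacing_bp`, anchored at the locus
#' start.
#'
#' @param locus A [cnv_locus()] truth object whose genotype map covers every
#'   cohort member (use [locus_genotypes()] to expand first if needed).
#' @param spec The [locus_spec()] providing marker/span distributions.
#' @param model An [error_model()].
#' @param batch Optional named character vector, individual id -> batch
#'   label, for batch shifts.
#' @param seed Integer seed for this stage's random stream.
#' @return A list with `calls` (data.frame of emitted segments), `observed`
#'   (named integer vector of post-error CN for every individual) and
#'   `truth` (the input genotypes).
#' @export
corrupt_to_array_calls <- function(locus, spec, model, batch = NULL,
                                   seed = 1L) {
  truth <- locus$genotypes
  if (length(truth) == 0) stop("truth locus has no genotypes")
  states <- admissible_states(locus$cnv_type)
  with_substream(seed, paste0("array/", locus$locus_id), {
    n <- length(truth)
    markers <- 1L + stats::rnbinom(n, mu = max(spec$marker_mean - 1, 0),
                                   size = spec$marker_dispersion)
    b <- if (is.null(batch)) NULL else unname(batch[names(truth)])
    p <- miscall_prob(model, locus$cnv_type, markers, b)
    observed <- perturb_states(truth, p, states)
    carrier <- observed != 2L
    span <- pmax(1L, as.integer(round(markers * spec$marker_spacing_bp)))
    calls <- data.frame(
      individual_id = names(truth)[carrier],
      chrom = spec$chrom,
      start = spec$start,
      end = spec$start + span[carrier],
      cn_state = observed[carrier],
      marker_count = markers[carrier],
      stringsAsFactors = FALSE)
    calls <- validate_cnv_calls(calls, sprintf("simulated:%s", locus$locus_id))
    list(calls = calls, observed = observed, truth = truth)
  })
}

#' Simulate MLPA observations of a truth locus
#'
#' Each assayed individual's MLPA copy number equals truth with probability
#' `1 - epsilon`; otherwise a uniformly chosen different admissible state.
#'
#' @param locus A [cnv_locus()] truth object.
#' @param epsilon MLPA error rate in \[0, 1).
#' @param seed Integer seed for this stage's random stream.
#' @return Data.frame with columns `individual_id`, `locus_id`, `cn`.
#' @export
emit_mlpa <- function(locus, epsilon = 0, seed = 1L) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  truth <- locus$genotypes
  states <- admissible_states(locus$cnv_type)
  with_substream(seed, paste0("mlpa/", locus$locus_id), {
    cn <- perturb_states(truth, epsilon, states)
    data.frame(individual_id = names(truth), locus_id = locus$locus_id,
               cn = unname(cn), stringsAsFactors = FALSE)
  })
}

#' Simulate a full case-control cohort
#'
#' Draws true Hardy-Weinberg genotypes at each configured locus (cases at
#' the frequency implied by the locus's odds ratio via
#' [case_allele_freq()]), corrupts them into array calls under the error
#' model, and emits MLPA observations. All randomness derives from `seed`
#' through named substreams, so output is reproducible and insensitive to
#' locus ordering.
#'
#' @param loci List of [locus_spec()] objects.
#' @param n_case,n_control Cohort sizes.
#' @param model An [error_model()].
#' @param batches Character vector of batch labels, assigned round-robin
#'   across the cohort.
#' @param seed Master integer seed.
#' @return A list with `samples` (sample sheet), `truth` (long data.frame
#'   individual/locus/cn), `truth_loci` (list of [cnv_locus()] objects),
#'   `calls` (array segment calls across loci) and `mlpa` (MLPA table).
#' @export
simulate_cohort <- function(loci, n_case, n_control, model = error_model(),
                            batches = "b1", seed = 1L) {
  if (n_case < 1 || n_control < 1) stop("both cohort groups must be non-empty")
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  ids <- c(sprintf("case_%04d", seq_len(n_case)),
           sprintf("ctrl_%04d", seq_len(n_control)))
  samples <- data.frame(
    id = ids,
    status = factor(rep(c("case", "control"), c(n_case, n_control)),
                    levels = c("case", "control")),
    batch = rep_len(batches, n_case + n_control),
    stringsAsFactors = FALSE)
  batch_map <- stats::setNames(samples$batch, samples$id)
  is_case <- samples$status == "case"

  truth_loci <- list()
  truth_rows <- list()
  call_rows <- list()
  mlpa_rows <- list()
  for (sp in loci) {
    q_case <- case_allele_freq(sp$q_control, sp$odds_ratio)
    cn <- with_substream(seed, paste0("truth/", sp$locus_id), {
      g <- integer(nrow(samples))
      g[is_case] <- draw_genotypes(q_case, sum(is_case), sp$cnv_type)
      g[!is_case] <- draw_genotypes(sp$q_control, sum(!is_case), sp$cnv_type)
      stats::setNames(g, samples$id)
    })
    locus <- cnv_locus(sp$locus_id, sp$chrom, sp$start, sp$end, sp$cnv_type,
                       genotypes = cn)
    truth_loci[[sp$locus_id]] <- locus
    truth_rows[[sp$locus_id]] <- data.frame(
      individual_id = samples$id, locus_id = sp$locus_id, cn = unname(cn),
      stringsAsFactors = FALSE)
    arr <- corrupt_to_array_calls(locus, sp, model, batch = batch_map,
                                  seed = seed)
    call_rows[[sp$locus_id]] <- arr$calls
    mlpa_rows[[sp$locus_id]] <- emit_mlpa(locus, model$mlpa_error, seed = seed)
  }
  list(samples = samples,
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
       truth_loci = truth_loci,
       calls = do.call(rbind, c(call_rows, list(make.row.names = FALSE))),
       mlpa = do.call(rbind, c(mlpa_rows, list(make.row.names = FALSE))))
}

#' Write a simulated cohort to a directory
#'
#' Emits `samples.tsv`, `calls.tsv`, `mlpa.tsv` and `truth.tsv` in the
#' package's interchange formats.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  write_cnv_calls(cohort$calls, file.path(dir, "calls.tsv"))
  write_mlpa_table(cohort$mlpa, file.path(dir, "mlpa.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
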