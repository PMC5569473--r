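# Orchestration and report rendering. The pipeline runs the stages in
# order (simulate -> filter -> genotype -> associate -> concord ->
# reliability), writing one TSV per stage plus an append-only text log.

#' Format an odds ratio with its interval for reporting
#' @param or,ci_low,ci_high Estimate and 95% bounds.
#' @return String such as `"2.36 [1.90-2.94]"` (2 decimal places throughout).
#' @export
format_or_ci <- function(or, ci_low, ci_high) {
  sprintf("%.2f [%.2f-%.2f]", or, ci_low, ci_high)
}

#' Format a p-value to 2 significant figures
#' @param p P-value.
#' @return String such as `"2.8e-15"` or `"0.34"`.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "n/a", formatC(signif(p, 2), format = "g", digits = 2))
}

#' Format an exact-test p-value to one decimal place
#'
#' The reporting convention for the low-frequency locus table: one decimal,
#' so e.g. 0.665 prints as `"0.7"`.
#' @param p P-value.
#' @return String.
#' @export
format_p1 <- function(p) {
  ifelse(is.na(p), "n/a", sprintf("%.1f", p))
}

#' Format a percentage to one decimal place
#' @param x Percentage (0-100 scale).
#' @return String such as `"90.1"`.
#' @export
format_freq <- function(x) sprintf("%.1f", x)

pipeline_log <- function(path, ...) {
  cat(sprintf(...), "\n", sep = "", file = path, append = TRUE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates a cohort under the given locus specifications and error model,
#' then runs every analysis stage: call filtering, per-locus genotyping
#' (filtered mode), allelic association, array-vs-MLPA concordance, the
#' deletion-vs-duplication validation summary, and the reliability curves
#' for both ordering keys. Output is fully determined by `seed`.
#'
#' @param loci List of [locus_spec()] objects.
#' @param n_case,n_control Cohort sizes.
#' @param model An [error_model()].
#' @param batches Batch labels, assigned round-robin.
#' @param policy A [filter_policy()].
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, every stage writes its TSV
#'   there plus `pipeline.log`.
#' @return List with `cohort`, `kept`, `dropped`, `genotyped` (list of
#'   [cnv_locus()]), `association` (data.frame), `concordance` (data.frame),
#'   `type_summary`, `reliability_size`, `reliability_markers`.
#' @export
run_pipeline <- function(loci, n_case = 200, n_control = 400,
                         model = error_model(), batches = "b1",
                         policy = filter_policy(), seed = 1L,
                         out_dir = NULL) {
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  if (length(loci) == 0) stop("at least one locus specification is required")
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_file <- file.path(out_dir, "pipeline.log")
    pipeline_log(log_file, "run_pipeline seed=%d n_case=%d n_control=%d loci=%d",
                 seed, n_case, n_control, length(loci))
    pipeline_log(log_file, "filter: min_markers=%d min_span_bp=%d enabled=%s",
                 policy$min_markers, policy$min_span_bp, policy$enabled)
  }
  cohort <- simulate_cohort(loci, n_case, n_control, model = model,
                            batches = batches, seed = seed)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)

  parts <- filter_calls(cohort$calls, policy)
  conc_rows <- list()
  assoc_rows <- list()
  genotyped <- list()
  all_records <- list()
  for (sp in loci) {
    lc <- genotype_locus(cohort$calls, sp$locus_id, sp$chrom, sp$start,
                         sp$end, sp$cnv_type, cohort$samples, policy = policy)
    genotyped[[sp$locus_id]] <- lc
    assoc_rows[[sp$locus_id]] <- associate_locus(lc, cohort$samples,
                                                 zero_rule = "haldane")
    rec <- match_records(lc, cohort$mlpa)
    all_records[[sp$locus_id]] <- rec
    conc_rows[[sp$locus_id]] <- locus_concordance(rec, sp$cnv_type)
  }
  association <- do.call(rbind, c(assoc_rows, list(make.row.names = FALSE)))
  concordance <- do.call(rbind, c(conc_rows, list(make.row.names = FALSE)))
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  type_summary <- type_validation_summary(concordance)

  calls_by_locus <- cohort$calls
  calls_by_locus$locus_id <- vapply(seq_len(nrow(calls_by_locus)), function(i) {
    hits <- vapply(loci, function(sp) {
      sp$chrom == calls_by_locus$chrom[i] &&
        interval_overlap(calls_by_locus$start[i], calls_by_locus$end[i],
                         sp$start, sp$end) > 0
    }, logical(1))
    if (any(hits)) loci[[which(hits)[1]]]$locus_id else NA_character_
  }, character(1))
  calls_by_locus <- calls_by_locus[!is.na(calls_by_locus$locus_id), ,
                                   drop = FALSE]
  rel_size <- rel_markers <- NULL
  if (length(unique(calls_by_locus$locus_id)) >= 3) {
    rel_size <- reliability_table(concordance, calls_by_locus, key = "size")
    rel_markers <- reliability_table(concordance, calls_by_locus,
                                     key = "markers")
  }

  if (!is.null(out_dir)) {
    utils::write.table(association, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(records, file.path(out_dir, "match_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(concordance, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rel_size)) {
      utils::write.table(rel_size$table,
                         file.path(out_dir, "reliability_size.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rel_markers$table,
                         file.path(out_dir, "reliability_markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pipeline_log(log_file, "stages complete: %d kept / %d dropped calls, %d loci",
                 nrow(parts$kept), nrow(parts$dropped), length(loci))
  }
  list(cohort = cohort, kept = parts$kept, dropped = parts$dropped,
       genotyped = genotyped, association = association,
       match_records = records, concordance = concordance,
       type_summary = type_summary,
       reliability_size = rel_size, reliability_markers = rel_markers)
}

#' Reproduce the published tables from the packaged count fixture
#'
#' Recomputes every statistic of the published analysis that is derivable
#' from the printed count tables: the association rows of the two frequent
#' CNVs (odds ratio, Woolf interval, chi-squared p in both variants), the
#' exact tests at the validated low-frequency loci, the per-type validation
#' rates and the discordance percentages; and renders them with the
#' publication's printing conventions.
#'
#' @param out_dir Optional directory for the rendered TSV reports.
#' @return List with `association`, `susceptibility`, `validation`, and
#'   `rendered` (character vector of display lines).
#' @export
run_paper_fixture <- function(out_dir = NULL) {
  fx <- paper_fixture()
  assoc <- fixture_association_results(fx)
  susc <- fixture_susceptibility_results(fx)
  val <- fixture_validation_summary(fx)

  rendered <- c(
    "== Frequent CNV association ==",
    sprintf("%-5s %-20s freq %s%%/%s%%  OR %s  p %s",
            assoc$locus, assoc$analysis,
            format_freq(assoc$case_freq_pct),
            format_freq(assoc$control_freq_pct),
            format_or_ci(assoc$or, assoc$ci_low, assoc$ci_high),
            format_p(assoc$chi2_p)),
    "== Validated low-frequency CNVs (exact test) ==",
    sprintf("%-6s %-11s %d vs %d alleles  p %s",
            susc$gene[susc$validated], susc$cnv_type[susc$validated],
            susc$case_alleles[susc$validated],
            susc$control_alleles[susc$validated],
            format_p1(susc$fisher_p[susc$validated])),
    "== Validation by CNV type ==",
    sprintf("%-11s %d of %d validated (%.0f%%)",
            val$by_type$cnv_type, val$by_type$n_validated,
            val$by_type$n_loci, val$by_type$pct_validated),
    "== Array-vs-MLPA discordance ==",
    sprintf("%-5s %-12s %d of %d (%.1f%%)",
            val$discordance$locus, val$discordance$analysis,
            val$discordance$n_discordant, val$discordance$n_assayed,
            val$discordance$pct_discordant))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(assoc, file.path(out_dir, "fixture_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(susc, file.path(out_dir, "fixture_susceptibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(val$by_type, file.path(out_dir, "fixture_validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(rendered, file.path(out_dir, "report.txt"))
  }
  list(association = assoc, susceptibility = susc, validation = val,
       rendered = rendered)
}
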