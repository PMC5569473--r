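# Readers and writers for the package's tab-separated interchange formats.
# All genomic coordinates on disk and in memory are 0-based half-open; every
# writer emits a header line and every reader requires one.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

as_int_column <- function(x, col, path) {
  suppressWarnings(v <- as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("file %s: column '%s' is not integer at data row(s) %s",
                 path, col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  v
}

#' Read CNV segment calls
#'
#' Reads a tab-separated call file with header columns `individual_id`,
#' `chrom`, `start`, `end`, `cn_state`, `marker_count`; one row per called
#' segment per individual. Coordinates are 0-based half-open. Only
#' non-reference segments are ever called by segmentation algorithms, so a
#' copy-number state of 2 is rejected.
#'
#' @param path Path to a tab-separated call file.
#' @return A data.frame of validated calls with typed columns.
#' @export
read_cnv_calls <- function(path) {
  df <- read_tsv_checked(path, c("individual_id", "chrom", "start", "end",
                                 "cn_state", "marker_count"), "CNV call")
  df$start <- as_int_column(df$start, "start", path)
  df$end <- as_int_column(df$end, "end", path)
  df$cn_state <- as_int_column(df$cn_state, "cn_state", path)
  df$marker_count <- as_int_column(df$marker_count, "marker_count", path)
  validate_cnv_calls(df, path)
}

validate_cnv_calls <- function(df, origin = "<calls>") {
  bad <- which(df$end <= df$start)
  if (length(bad) > 0) {
    stop(sprintf("%s: end <= start at data row(s) %s", origin,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(df$cn_state == 2L)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: cn_state 2 (reference) is never emitted as a call; data row(s) %s",
      origin, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(df$cn_state < 0L)) stop(sprintf("%s: negative cn_state", origin))
  if (any(df$marker_count < 1L)) {
    stop(sprintf("%s: marker_count must be >= 1", origin))
  }
  df$span <- df$end - df$start
  rownames(df) <- NULL
  df
}

#' Write CNV segment calls
#'
#' @param calls Data.frame as returned by [read_cnv_calls()] (a `span`
#'   column, if present, is dropped on output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  cols <- c("individual_id", "chrom", "start", "end", "cn_state",
            "marker_count")
  utils::write.table(calls[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `id`, `status`, `batch`. Status tokens
#' are normalised case-insensitively to `"case"` / `"control"`; any other
#' token is a format error. Duplicate ids are rejected: the sample sheet is
#' the authoritative cohort denominator (call files list only carriers).
#'
#' @param path Path to the sample sheet.
#' @return A data.frame with columns `id`, `status` (factor case/control),
#'   `batch`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("id", "status", "batch"), "sample sheet")
  status <- tolower(trimws(df$status))
  bad <- which(!status %in% c("case", "control"))
  if (length(bad) > 0) {
    stop(sprintf("sample sheet %s: unknown status token '%s' at data row %d",
                 path, df$status[bad[1]], bad[1]))
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    stop(sprintf("sample sheet %s: duplicate id(s): %s", path,
                 paste(unique(utils::head(dup, 5)), collapse = ", ")))
  }
  data.frame(id = df$id,
             status = factor(status, levels = c("case", "control")),
             batch = df$batch, stringsAsFactors = FALSE)
}

#' Write a sample sheet
#' @param samples Data.frame with columns `id`, `status`, `batch`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  out <- data.frame(id = samples$id, status = as.character(samples$status),
                    batch = samples$batch)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MLPA genotype table
#'
#' Tab-separated with header columns `individual_id`, `locus_id`, `cn`; one
#' record per (individual, locus) pair, integer copy number >= 0.
#'
#' @param path Path to the MLPA table.
#' @return A data.frame with columns `individual_id`, `locus_id`, `cn`.
#' @export
read_mlpa_table <- function(path) {
  df <- read_tsv_checked(path, c("individual_id", "locus_id", "cn"),
                         "MLPA table")
  df$cn <- as_int_column(df$cn, "cn", path)
  if (any(df$cn < 0L)) {
    stop(sprintf("MLPA table %s: negative copy number", path))
  }
  key <- paste(df$individual_id, df$locus_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf(
      "MLPA table %s: duplicate (individual, locus) pair at data row %d (%s, %s)",
      path, dup[1], df$individual_id[dup[1]], df$locus_id[dup[1]]))
  }
  rownames(df) <- NULL
  df[, c("individual_id", "locus_id", "cn")]
}

#' Write an MLPA genotype table
#' @param mlpa Data.frame with columns `individual_id`, `locus_id`, `cn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mlpa_table <- function(mlpa, path) {
  utils::write.table(mlpa[, c("individual_id", "locus_id", "cn")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP genotype matrix
#'
#' Tab-separated matrix with SNPs as rows and individuals as columns: header
#' `snp_id`, `position`, then one column per individual holding minor-allele
#' dosages in \{0, 1, 2\} with `"."` for missing. Positions must be strictly
#' increasing (a sorted single-chromosome panel).
#'
#' @param path Path to the genotype matrix.
#' @return A list with `snp_id` (character), `position` (integer) and
#'   `dosages` (numeric matrix, SNPs x individuals, `NA` for missing).
#' @export
read_snp_matrix <- function(path) {
  df <- read_tsv_checked(path, c("snp_id", "position"), "SNP matrix")
  if (ncol(df) < 3) stop(sprintf("SNP matrix %s has no individual columns", path))
  position <- as_int_column(df$position, "position", path)
  if (any(diff(position) <= 0)) {
    stop(sprintf("SNP matrix %s: positions must be strictly increasing", path))
  }
  ind_cols <- setdiff(names(df), c("snp_id", "position"))
  dos <- vapply(df[ind_cols], function(col) {
    col[col == "."] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(df)))
  dos <- matrix(dos, nrow = nrow(df),
                dimnames = list(df$snp_id, ind_cols))
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) {
    stop(sprintf("SNP matrix %s: dosages must lie in [0, 2]", path))
  }
  list(snp_id = df$snp_id, position = position, dosages = dos)
}

#' Construct a CNV locus object
#'
#' A locus is a canonical interval of one CNV type together with the cohort's
#' integer copy-number genotypes. Individuals absent from the genotype map
#' are reference (CN = 2) by convention; deletion loci carry genotypes <= 2
#' and duplication loci >= 2 (at most 4, two duplication alleles).
#'
#' @param locus_id Locus identifier.
#' @param chrom Chromosome name.
#' @param start,end Canonical interval, 0-based half-open.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param genotypes Named integer vector, individual id -> copy number.
#'   Omitted individuals are CN 2.
#' @return An object of class `cnv_locus`.
#' @export
cnv_locus <- function(locus_id, chrom, start, end, cnv_type,
                      genotypes = integer(0)) {
  cnv_type <- match.arg(cnv_type, c("deletion", "duplication"))
  if (end <= start) stop("locus interval must satisfy end > start")
  nm <- names(genotypes)
  genotypes <- stats::setNames(as.integer(genotypes), nm)
  if (is.null(names(genotypes)) && length(genotypes) > 0) {
    stop("genotypes must be a named vector (individual id -> CN)")
  }
  if (cnv_type == "deletion" && any(genotypes > 2L)) {
    stop(sprintf("deletion locus %s has genotypes > 2", locus_id))
  }
  if (cnv_type == "duplication" &&
      (any(genotypes < 2L) || any(genotypes > 4L))) {
    stop(sprintf("duplication locus %s has genotypes outside [2, 4]", locus_id))
  }
  structure(list(locus_id = locus_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 cnv_type = cnv_type, genotypes = genotypes),
            class = "cnv_locus")
}

#' @export
print.cnv_locus <- function(x, ...) {
  cat(sprintf("<cnv_locus %s: %s:%d-%d (%s), %d non-reference genotype(s)>\n",
              x$locus_id, x$chrom, x$start, x$end, x$cnv_type,
              sum(x$genotypes != 2L)))
  invisible(x)
}

#' Copy-number genotypes for a full cohort
#'
#' Expands a locus's sparse genotype map to one CN per cohort member,
#' defaulting absent individuals to the reference state (CN 2).
#'
#' @param locus A [cnv_locus()] object.
#' @param samples Sample sheet data.frame (column `id`).
#' @return Named integer vector of copy numbers, one per cohort member.
#' @export
locus_genotypes <- function(locus, samples) {
  cn <- rep(2L, nrow(samples))
  names(cn) <- samples$id
  known <- intersect(names(locus$genotypes), samples$id)
  cn[known] <- locus$genotypes[known]
  cn
}
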