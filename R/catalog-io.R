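#' Construct an SnpCatalog from a records data.frame
#'
#' Low-level constructor used by [readSnpCatalog()] and the synthetic-data
#' generator. Missing optional metadata columns are added (empty strings for
#' character annotation, NA for numbers) so every catalog exposes the same
#' schema, and columns are put in canonical order. The object is validated:
#' duplicate rsIDs, frequencies outside [0, 1], non-positive sample sizes or
#' odds ratios, and records lacking an observation for an analysed
#' population are all rejected.
#'
#' @param records data.frame with mandatory columns `rsid`, `chromosome`,
#'   `risk_allele`, `ref_allele`, `or_value`, plus `<pop>_freq_<db>` /
#'   `<pop>_n_<db>` pairs. Sample sizes are individuals.
#' @param cancerLabel dataset name.
#' @param populations population labels to analyse; defaults to all
#'   populations found in the frequency columns.
#' @return an [SnpCatalog-class].
#' @examples
#' rec <- data.frame(rsid = c("rs1", "rs2"), chromosome = c("8", "12"),
#'                   risk_allele = c("A", "C"), ref_allele = c("G", "T"),
#'                   or_value = c(1.3, 1.1),
#'                   afr_freq_1kg = c(0.41, 0.22), afr_n_1kg = c(661, 661),
#'                   eur_freq_1kg = c(0.35, 0.27), eur_n_1kg = c(503, 503))
#' snpCatalog(rec, "example")
#' @export
snpCatalog <- function(records, cancerLabel = "catalog", populations = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (cc in .OPTIONAL_CHR_COLS)
    if (is.null(records[[cc]])) records[[cc]] <- rep("", nrow(records))
  for (nc in .OPTIONAL_NUM_COLS)
    if (is.null(records[[nc]])) records[[nc]] <- rep(NA_real_, nrow(records))
  for (cc in c("rsid", "chromosome", "risk_allele", "ref_allele", .OPTIONAL_CHR_COLS)) {
    records[[cc]] <- as.character(records[[cc]])
    records[[cc]][is.na(records[[cc]])] <- ""
  }
  for (nc in setdiff(names(records),
                     c("rsid", "chromosome", "risk_allele", "ref_allele",
                       .OPTIONAL_CHR_COLS)))
    records[[nc]] <- as.numeric(records[[nc]])
  if (is.null(populations)) populations <- .populationsInHeader(names(records))
  records <- .orderCatalogColumns(records)
  rownames(records) <- NULL
  new("SnpCatalog", cancerLabel = cancerLabel,
      populations = populations, records = records)
}

#' Read a SNP catalog from a tab-separated file
#'
#' Reads the documented catalog dialect: UTF-8, tab-separated, one header
#' row. Mandatory columns are `rsid`, `chromosome`, `risk_allele`,
#' `ref_allele`, `or_value`; optional metadata columns are `position`,
#' `cytoband`, `gene`, `functional_region`, `ci_low`, `ci_high`, `p_value`.
#' Allele-frequency observations follow the pattern `<pop>_freq_<db>` with a
#' companion `<pop>_n_<db>` sample-size column (individuals); a blank cell
#' is a missing observation. Rows violating a typed invariant (frequency
#' outside [0, 1], non-positive sample size or odds ratio, duplicate rsID)
#' are reported with their row number and rsID; nothing is silently dropped.
#'
#' @param path path to the TSV file.
#' @param populations population labels to analyse (default: all found).
#' @param cancerLabel dataset name (default: file name without extension).
#' @return an [SnpCatalog-class].
#' @seealso [writeSnpCatalog()] for the inverse; the two round-trip.
#' @export
readSnpCatalog <- function(path, populations = NULL, cancerLabel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(cancerLabel))
    cancerLabel <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "")
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0L)
    stop("catalog format error in '", basename(path), "': missing mandatory ",
         "column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  fc <- .freqColumnInfo(names(raw))
  if (nrow(fc) == 0L)
    stop("catalog format error in '", basename(path),
         "': no <pop>_freq_<db> columns found", call. = FALSE)

  num_cols <- c("or_value", intersect(.OPTIONAL_NUM_COLS, names(raw)),
                fc$freq_col, fc$n_col)
  problems <- character()
  for (col in num_cols) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0L)
      problems <- c(problems, sprintf(
        "row %d (rsid %s): non-numeric value '%s' in column %s",
        bad + 1L, raw$rsid[bad], v[bad], col))
    raw[[col]] <- parsed
  }
  # row-level invariant checks with file row numbers (header = row 1)
  .rowProblem <- function(idx, col, what)
    sprintf("row %d (rsid %s): %s in column %s", idx + 1L, raw$rsid[idx], what, col)
  for (col in fc$freq_col) {
    bad <- which(!is.na(raw[[col]]) & (raw[[col]] < 0 | raw[[col]] > 1))
    if (length(bad) > 0L)
      problems <- c(problems, .rowProblem(bad, col, "frequency outside [0,1]"))
  }
  for (col in fc$n_col) {
    bad <- which(!is.na(raw[[col]]) & raw[[col]] <= 0)
    if (length(bad) > 0L)
      problems <- c(problems, .rowProblem(bad, col, "non-positive sample size"))
  }
  bad <- which(is.na(raw$or_value) | raw$or_value <= 0)
  if (length(bad) > 0L)
    problems <- c(problems, .rowProblem(bad, "or_value",
                                        "missing or non-positive odds ratio"))
  bad <- which(duplicated(raw$rsid))
  if (length(bad) > 0L)
    problems <- c(problems, .rowProblem(bad, "rsid", "duplicate rsID"))
  if (length(problems) > 0L)
    stop("catalog validation error in '", basename(path), "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  snpCatalog(raw, cancerLabel = cancerLabel, populations = populations)
}

#' Write a SNP catalog to a tab-separated file
#'
#' Inverse of [readSnpCatalog()]: `readSnpCatalog(writeSnpCatalog(x, path))`
#' reproduces `x` field for field. Missing values are written as blank
#' cells; numeric fields are printed with 17 significant digits so that
#' doubles survive the round trip exactly.
#'
#' @param catalog an [SnpCatalog-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSnpCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "SnpCatalog"))
  validObject(catalog)
  rec <- records(catalog)
  out <- rec
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- ""
      out[[col]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write catalog to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Harmonize a catalog so every odds ratio is at least 1
#'
#' Association studies report the odds ratio of an arbitrary allele; a risk
#' allele is defined by OR >= 1. For every record with OR < 1 this swaps the
#' risk and reference alleles, replaces OR by 1/OR, inverts and swaps the
#' confidence-interval bounds, and replaces every allele frequency f by
#' 1 - f. Records with OR >= 1 pass through unchanged, so the operation is
#' idempotent. Each flip is reported via [message()].
#'
#' @param catalog an [SnpCatalog-class]; all odds ratios must be positive.
#' @return the harmonized [SnpCatalog-class].
#' @export
harmonizeRiskAlleles <- function(catalog) {
  stopifnot(is(catalog, "SnpCatalog"))
  rec <- records(catalog)
  if (nrow(rec) == 0L) return(catalog)
  if (any(!is.finite(rec$or_value) | rec$or_value <= 0))
    stop("harmonization requires positive odds ratios for all records",
         call. = FALSE)
  flip <- which(rec$or_value < 1)
  if (length(flip) > 0L) {
    ra <- rec$risk_allele[flip]
    rec$risk_allele[flip] <- rec$ref_allele[flip]
    rec$ref_allele[flip] <- ra
    old_low <- rec$ci_low[flip]
    rec$ci_low[flip] <- 1 / rec$ci_high[flip]
    rec$ci_high[flip] <- 1 / old_low
    rec$or_value[flip] <- 1 / rec$or_value[flip]
    fc <- .freqColumnInfo(names(rec))
    for (col in fc$freq_col)
      rec[[col]][flip] <- 1 - rec[[col]][flip]
    message("harmonized ", length(flip), " record(s) with OR < 1: ",
            paste(rec$rsid[flip], collapse = ", "))
  }
  snpCatalog(rec, cancerLabel = cancerLabel(catalog),
             populations = populations(catalog))
}

#' Read a linkage-disequilibrium pair table
#'
#' Reads a TSV with columns `rsid_a`, `rsid_b`, `r2` listing pairwise LD
#' (r-squared) between catalog SNPs, as exported from a pairwise LD lookup
#' tool. Pairs referencing rsIDs absent from the companion catalog are kept
#' but flagged `known = FALSE` (with a warning) so downstream grouping can
#' ignore them without losing the audit trail.
#'
#' @param path path to the TSV file.
#' @param catalog optional [SnpCatalog-class] used to flag unknown rsIDs.
#' @return data.frame with columns `rsid_a`, `rsid_b`, `r2`, `known`.
#' @export
readLdPairs <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "")
  need <- c("rsid_a", "rsid_b", "r2")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("LD-pairs format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(rsid_a = raw$rsid_a, rsid_b = raw$rsid_b,
                    r2 = suppressWarnings(as.numeric(raw$r2)),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$r2) | out$r2 < 0 | out$r2 > 1)
  if (length(bad) > 0L)
    stop("LD-pairs validation error: r2 outside [0,1] at row(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  bad <- which(out$rsid_a == out$rsid_b)
  if (length(bad) > 0L)
    stop("LD-pairs validation error: self-pair at row(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  if (!is.null(catalog)) {
    known_ids <- records(catalog)$rsid
    out$known <- out$rsid_a %in% known_ids & out$rsid_b %in% known_ids
    if (any(!out$known))
      warning(sum(!out$known), " LD pair(s) reference rsIDs absent from the ",
              "catalog and are flagged known = FALSE", call. = FALSE)
  } else {
    out$known <- rep(NA, nrow(out))
  }
  out
}
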