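#' @import methods
NULL

.MANDATORY_COLS <- c("rsid", "chromosome", "risk_allele", "ref_allele", "or_value")
.OPTIONAL_CHR_COLS <- c("cytoband", "gene", "functional_region")
.OPTIONAL_NUM_COLS <- c("position", "ci_low", "ci_high", "p_value")
.CANONICAL_COLS <- c("rsid", "chromosome", "position", "cytoband", "gene",
                     "functional_region", "risk_allele", "ref_allele",
                     "or_value", "ci_low", "ci_high", "p_value")

#' SnpCatalog: a curated catalog of disease risk variants
#'
#' An `SnpCatalog` holds one row per risk SNP: identity (rsID), location
#' (chromosome, optional position and cytoband), annotation (gene symbol,
#' functional region), the risk and reference alleles, the association odds
#' ratio with optional confidence interval and p-value, and per-population
#' allele-frequency observations from one or more reference databases.
#'
#' Frequency observations live in paired columns named
#' `<pop>_freq_<db>` / `<pop>_n_<db>` (for example `afr_freq_1kg`,
#' `afr_n_1kg`), where `<db>` labels the source database and `<pop>` a
#' population. Sample sizes are numbers of individuals; internal pooling
#' weights use allele counts (2n) for diploid autosomal loci. A blank (NA)
#' frequency cell is a missing observation; a frequency and its sample size
#' must be present or absent together.
#'
#' @slot cancerLabel single string naming the dataset (e.g. the cancer type).
#' @slot populations character vector of population labels analysed; every
#'   record must carry at least one observation for each.
#' @slot records data.frame with the columns described above, one row per SNP.
#'
#' @seealso [readSnpCatalog()], [harmonizeRiskAlleles()], [aggregateCatalog()]
#' @export
setClass("SnpCatalog",
         representation(cancerLabel = "character",
                        populations = "character",
                        records = "data.frame"))

setValidity("SnpCatalog", function(object) {
  msgs <- character()
  if (length(object@cancerLabel) != 1L)
    msgs <- c(msgs, "cancerLabel must be a single string")
  if (length(object@populations) == 0L)
    msgs <- c(msgs, "populations must be non-empty")
  rec <- object@records
  missing_cols <- setdiff(.MANDATORY_COLS, names(rec))
  if (length(missing_cols) > 0L)
    return(paste("missing mandatory column(s):",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(rec) > 0L) {
    if (anyDuplicated(rec$rsid))
      msgs <- c(msgs, paste("duplicate rsID(s):",
                            paste(unique(rec$rsid[duplicated(rec$rsid)]),
                                  collapse = ", ")))
    bad_or <- which(!is.finite(rec$or_value) | rec$or_value <= 0)
    if (length(bad_or) > 0L)
      msgs <- c(msgs, paste0("non-positive or missing odds ratio for rsID(s): ",
                             paste(rec$rsid[bad_or], collapse = ", ")))
    fc <- .freqColumnInfo(names(rec))
    for (pop in object@populations) {
      pc <- fc[fc$pop == pop, , drop = FALSE]
      if (nrow(pc) == 0L) {
        msgs <- c(msgs, paste0("no frequency columns for population '", pop, "'"))
        next
      }
      fm <- as.matrix(rec[, pc$freq_col, drop = FALSE])
      nm <- as.matrix(rec[, pc$n_col, drop = FALSE])
      bad_range <- which(!is.na(fm) & (fm < 0 | fm > 1), arr.ind = TRUE)
      if (nrow(bad_range) > 0L)
        msgs <- c(msgs, paste0("frequency outside [0,1] for rsID ",
                               rec$rsid[bad_range[1L, 1L]], ", column ",
                               pc$freq_col[bad_range[1L, 2L]]))
      bad_n <- which(!is.na(nm) & nm <= 0, arr.ind = TRUE)
      if (nrow(bad_n) > 0L)
        msgs <- c(msgs, paste0("non-positive sample size for rsID ",
                               rec$rsid[bad_n[1L, 1L]], ", column ",
                               pc$n_col[bad_n[1L, 2L]]))
      mismatch <- which(is.na(fm) != is.na(nm), arr.ind = TRUE)
      if (nrow(mismatch) > 0L)
        msgs <- c(msgs, paste0("frequency/sample-size presence mismatch for rsID ",
                               rec$rsid[mismatch[1L, 1L]], " (",
                               pc$freq_col[mismatch[1L, 2L]], ")"))
      if (any(rowSums(!is.na(fm)) == 0L))
        msgs <- c(msgs, paste0("record(s) with no observation for population '",
                               pop, "': ",
                               paste(rec$rsid[rowSums(!is.na(fm)) == 0L],
                                     collapse = ", ")))
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' AggregatedCatalog: pooled and OR-weighted frequencies per variant unit
#'
#' Result of [aggregateCatalog()]. Each row of `units` is one analysis unit
#' (a SNP, or a collapsed LD group) with, per population, the pooled
#' risk-allele frequency F (allele-count-weighted mean across databases) and
#' the weighted frequency Fw = F * OR / ORmax, where ORmax is the largest
#' odds ratio in the catalog the summary was computed over.
#'
#' @slot cancerLabel dataset label inherited from the source catalog.
#' @slot populations population labels.
#' @slot orMax largest odds ratio used as the Fw denominator.
#' @slot units data.frame with columns `unit_id`, `or_value`, and per
#'   population `<pop>_F`, `<pop>_Fw`, `<pop>_ndb` (databases used).
#' @export
setClass("AggregatedCatalog",
         representation(cancerLabel = "character",
                        populations = "character",
                        orMax = "numeric",
                        units = "data.frame"))

setValidity("AggregatedCatalog", function(object) {
  msgs <- character()
  if (length(object@orMax) != 1L || !is.finite(object@orMax) || object@orMax <= 0)
    msgs <- c(msgs, "orMax must be a single positive number")
  u <- object@units
  if (nrow(u) > 0L) {
    if (any(u$or_value > object@orMax + 1e-12))
      msgs <- c(msgs, "orMax smaller than a unit odds ratio")
    for (pop in object@populations) {
      fcol <- paste0(pop, "_F"); wcol <- paste0(pop, "_Fw")
      if (!all(c(fcol, wcol) %in% names(u))) {
        msgs <- c(msgs, paste0("missing aggregated columns for population '", pop, "'"))
        next
      }
      if (any(u[[wcol]] > u[[fcol]] + 1e-12))
        msgs <- c(msgs, paste0("Fw exceeds F for population '", pop, "'"))
    }
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' DemingFit: errors-in-variables straight-line fit
#'
#' A Deming regression fit of y on x, minimising residuals weighted by the
#' assumed ratio `lambda` of x-axis to y-axis error variance (`lambda = 1`
#' gives orthogonal regression). The fitted line always passes through the
#' data centroid. Slope uncertainty, when computed, is the delete-one
#' jackknife standard error, and slope tests use a t reference distribution
#' with n - 2 degrees of freedom.
#'
#' @slot slope fitted slope.
#' @slot intercept fitted intercept (ybar - slope * xbar).
#' @slot n number of points.
#' @slot lambda assumed x-error / y-error variance ratio.
#' @slot slopeSE jackknife standard error of the slope (NA until computed).
#' @slot pSlopeVsOne two-sided p-value for slope != 1 (NA until computed).
#' @slot pSlopeVsZero two-sided p-value for slope != 0 (NA until computed).
#' @seealso [demingFit()], [demingRegression()], [testSlope()]
#' @export
setClass("DemingFit",
         representation(slope = "numeric",
                        intercept = "numeric",
                        n = "integer",
                        lambda = "numeric",
                        slopeSE = "numeric",
                        pSlopeVsOne = "numeric",
                        pSlopeVsZero = "numeric"),
         prototype(slopeSE = NA_real_,
                   pSlopeVsOne = NA_real_,
                   pSlopeVsZero = NA_real_))

setValidity("DemingFit", function(object) {
  msgs <- character()
  if (object@n < 3L) msgs <- c(msgs, "n must be >= 3")
  if (!is.finite(object@lambda) || object@lambda <= 0)
    msgs <- c(msgs, "lambda must be positive")
  if (!is.na(object@slopeSE) && object@slopeSE < 0)
    msgs <- c(msgs, "slopeSE must be non-negative")
  if (length(msgs) == 0L) TRUE else msgs
})
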