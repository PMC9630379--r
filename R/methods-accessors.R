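#' Accessors for SnpCatalog objects
#'
#' `records()` returns the per-SNP data.frame, `populations()` the analysed
#' population labels, `cancerLabel()` the dataset name, and `nUnits()` the
#' number of variant units (rows).
#'
#' @param x an [SnpCatalog-class] (or, where stated, [AggregatedCatalog-class]).
#' @name SnpCatalog-accessors
#' @aliases records populations cancerLabel nUnits
NULL

#' @rdname SnpCatalog-accessors
#' @export
setMethod("records", "SnpCatalog", function(x) x@records)

#' @rdname SnpCatalog-accessors
#' @export
setMethod("populations", "SnpCatalog", function(x) x@populations)

#' @rdname SnpCatalog-accessors
#' @export
setMethod("cancerLabel", "SnpCatalog", function(x) x@cancerLabel)

#' @rdname SnpCatalog-accessors
#' @export
setMethod("nUnits", "SnpCatalog", function(x) nrow(x@records))

#' Accessors for AggregatedCatalog objects
#'
#' `aggregatedUnits()` returns the per-unit data.frame of pooled (F) and
#' OR-weighted (Fw) frequencies; `orMax()` the catalog-wide maximum odds
#' ratio used as the Fw denominator.
#'
#' @param x an [AggregatedCatalog-class].
#' @name AggregatedCatalog-accessors
#' @aliases orMax aggregatedUnits
NULL

#' @rdname AggregatedCatalog-accessors
#' @export
setMethod("aggregatedUnits", "AggregatedCatalog", function(x) x@units)

#' @rdname AggregatedCatalog-accessors
#' @export
setMethod("orMax", "AggregatedCatalog", function(x) x@orMax)

#' @rdname AggregatedCatalog-accessors
#' @export
setMethod("populations", "AggregatedCatalog", function(x) x@populations)

#' @rdname AggregatedCatalog-accessors
#' @export
setMethod("cancerLabel", "AggregatedCatalog", function(x) x@cancerLabel)

#' @rdname AggregatedCatalog-accessors
#' @export
setMethod("nUnits", "AggregatedCatalog", function(x) nrow(x@units))

setMethod("show", "SnpCatalog", function(object) {
  cat("SnpCatalog '", object@cancerLabel, "': ", nrow(object@records),
      " SNP record(s)\n", sep = "")
  cat("  populations: ", paste(object@populations, collapse = ", "), "\n", sep = "")
  fc <- .freqColumnInfo(names(object@records))
  cat("  databases:   ", paste(unique(fc$db), collapse = ", "), "\n", sep = "")
  if (nrow(object@records) > 0L)
    cat("  odds ratios: ", sprintf("%.3g-%.3g", min(object@records$or_value),
                                   max(object@records$or_value)), "\n", sep = "")
})

setMethod("show", "AggregatedCatalog", function(object) {
  cat("AggregatedCatalog '", object@cancerLabel, "': ", nrow(object@units),
      " unit(s), ORmax = ", format(object@orMax, digits = 4), "\n", sep = "")
  for (pop in object@populations)
    cat(sprintf("  %s: mean F = %.4f, mean Fw = %.4f\n", pop,
                mean(object@units[[paste0(pop, "_F")]]),
                mean(object@units[[paste0(pop, "_Fw")]])))
})

setMethod("show", "DemingFit", function(object) {
  cat(sprintf("DemingFit (lambda = %g, n = %d)\n", object@lambda, object@n))
  cat(sprintf("  y = %.4f * x + %.4f\n", object@slope, object@intercept))
  if (!is.na(object@slopeSE))
    cat(sprintf("  slope SE (jackknife) = %.4g; p(slope != 1) = %.4g, p(slope != 0) = %.4g\n",
                object@slopeSE, object@pSlopeVsOne, object@pSlopeVsZero))
})
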