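#' @rdname SnpCatalog-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SnpCatalog-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname SnpCatalog-accessors
#' @export
setGeneric("cancerLabel", function(x) standardGeneric("cancerLabel"))

#' @rdname SnpCatalog-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname AggregatedCatalog-accessors
#' @export
setGeneric("orMax", function(x) standardGeneric("orMax"))

#' @rdname AggregatedCatalog-accessors
#' @export
setGeneric("aggregatedUnits", function(x) standardGeneric("aggregatedUnits"))

#' Test a Deming slope against a reference value
#'
#' Two-sided t-test of the fitted slope against a reference slope, using the
#' jackknife slope standard error and n - 2 degrees of freedom. The usual
#' reference is 1, the identity line on which both populations would carry
#' every risk allele at the same frequency.
#'
#' @param fit a [DemingFit-class] with `slopeSE` filled in (see
#'   [demingRegression()] or [demingSlopeSE()]).
#' @param reference reference slope (default 1).
#' @return two-sided p-value. If `slopeSE` is zero the p-value degenerates to
#'   1 when the slope equals the reference and 0 (with a warning) otherwise.
#' @export
setGeneric("testSlope", function(fit, reference = 1) standardGeneric("testSlope"))
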