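#' Pool allele frequencies across reference databases
#'
#' Combines the per-database risk-allele frequency estimates of one SNP in
#' one population into a single pooled frequency F. The default is the
#' sample-size-weighted arithmetic mean with weights equal to allele counts
#' (2 x individuals for diploid autosomal loci), which is the
#' maximum-likelihood pooled estimate under binomial sampling; an unweighted
#' mean is available for comparison. The result always lies between the
#' smallest and largest input frequency, and rescaling all sample sizes by a
#' common factor leaves it unchanged.
#'
#' @param frequencies numeric vector of per-database frequencies in [0, 1].
#' @param sampleSizes numeric vector of per-database individual counts (> 0).
#' @param pooling `"weighted"` (allele-count weights, default) or
#'   `"unweighted"` (plain mean).
#' @return pooled frequency, a proportion.
#' @examples
#' pooledFrequency(c(0.2, 0.5), c(100, 300))  # 0.425
#' @export
pooledFrequency <- function(frequencies, sampleSizes,
                            pooling = c("weighted", "unweighted")) {
  pooling <- match.arg(pooling)
  keep <- !is.na(frequencies)
  frequencies <- frequencies[keep]
  sampleSizes <- sampleSizes[keep]
  if (length(frequencies) == 0L)
    stop("no frequency observations to pool", call. = FALSE)
  if (length(sampleSizes) != length(frequencies))
    stop("frequencies and sampleSizes must have equal length", call. = FALSE)
  if (any(frequencies < 0 | frequencies > 1))
    stop("frequencies must lie in [0,1]", call. = FALSE)
  if (any(is.na(sampleSizes) | sampleSizes <= 0))
    stop("sample sizes must be positive", call. = FALSE)
  if (pooling == "weighted") {
    w <- 2 * sampleSizes  # allele counts; the factor 2 cancels but keeps units honest
    sum(w * frequencies) / sum(w)
  } else {
    mean(frequencies)
  }
}

#' Odds-ratio-weighted allele frequency
#'
#' Scales a pooled risk-allele frequency by the allele's odds ratio relative
#' to the largest odds ratio in the catalog: Fw = F * OR / ORmax. The
#' weighting down-weights alleles with weaker association so that the
#' population comparison reflects attributable risk rather than raw allele
#' counts; Fw equals F exactly when OR = ORmax and never exceeds F.
#'
#' @param F pooled frequency in [0, 1].
#' @param oddsRatio the allele's odds ratio (0 < OR <= `orMax`).
#' @param orMax largest odds ratio among the catalog's risk alleles.
#' @return weighted frequency Fw, a proportion.
#' @examples
#' weightedFrequency(0.5, 1.2, 2.4)  # 0.25
#' @export
weightedFrequency <- function(F, oddsRatio, orMax) {
  .assertScalarNumber(orMax, "orMax", positive = TRUE)
  if (any(!is.finite(oddsRatio) | oddsRatio <= 0))
    stop("oddsRatio must be positive", call. = FALSE)
  if (any(F < 0 | F > 1))
    stop("F must lie in [0,1]", call. = FALSE)
  if (any(oddsRatio > orMax * (1 + 1e-12)))
    stop("oddsRatio exceeds orMax: the maximum was computed on a different ",
         "catalog", call. = FALSE)
  F * oddsRatio / orMax
}

#' Aggregate a catalog into pooled and weighted frequencies
#'
#' For every record of a harmonized catalog and every analysed population,
#' computes the pooled frequency F across the databases with data (see
#' [pooledFrequency()]) and the OR-weighted frequency Fw (see
#' [weightedFrequency()]). ORmax defaults to the catalog-wide maximum odds
#' ratio; pass an explicit `orMax` to keep Fw on a common scale when
#' aggregating a subset of a larger catalog (as the sensitivity re-analyses
#' do by default).
#'
#' @param catalog an [SnpCatalog-class], harmonized so all OR >= 1.
#' @param orMax optional externally fixed maximum odds ratio; must be at
#'   least the catalog's own maximum.
#' @param pooling passed to [pooledFrequency()].
#' @return an [AggregatedCatalog-class]; unit order follows the catalog.
#' @export
aggregateCatalog <- function(catalog, orMax = NULL,
                             pooling = c("weighted", "unweighted")) {
  stopifnot(is(catalog, "SnpCatalog"))
  pooling <- match.arg(pooling)
  rec <- records(catalog)
  if (nrow(rec) == 0L)
    stop("cannot aggregate an empty catalog", call. = FALSE)
  catalog_max <- max(rec$or_value)
  if (is.null(orMax)) {
    orMax <- catalog_max
  } else {
    .assertScalarNumber(orMax, "orMax", positive = TRUE)
    if (orMax < catalog_max - 1e-12)
      stop("supplied orMax (", orMax, ") is smaller than the catalog maximum (",
           catalog_max, ")", call. = FALSE)
  }
  fc <- .freqColumnInfo(names(rec))
  units <- data.frame(unit_id = rec$rsid, or_value = rec$or_value,
                      stringsAsFactors = FALSE)
  for (pop in populations(catalog)) {
    pc <- fc[fc$pop == pop, , drop = FALSE]
    fm <- as.matrix(rec[, pc$freq_col, drop = FALSE])
    nm <- as.matrix(rec[, pc$n_col, drop = FALSE])
    used <- rowSums(!is.na(fm))
    if (any(used == 0L))
      stop("no frequency observation for population '", pop, "' in unit(s): ",
           paste(rec$rsid[used == 0L], collapse = ", "), call. = FALSE)
    if (pooling == "weighted") {
      w <- 2 * nm
      w[is.na(fm)] <- NA
      Fp <- rowSums(w * fm, na.rm = TRUE) / rowSums(w, na.rm = TRUE)
    } else {
      Fp <- rowMeans(fm, na.rm = TRUE)
    }
    units[[paste0(pop, "_F")]] <- Fp
    units[[paste0(pop, "_Fw")]] <- weightedFrequency(Fp, rec$or_value, orMax)
    units[[paste0(pop, "_ndb")]] <- used
  }
  rownames(units) <- NULL
  new("AggregatedCatalog", cancerLabel = cancerLabel(catalog),
      populations = populations(catalog), orMax = orMax, units = units)
}
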