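#' Remove catalog records falling in a chromosomal region
#'
#' Drops records belonging to a locus, identified either by a cytoband
#' prefix (e.g. `"8q24"` matches cytobands `"8q24"`, `"8q24.21"`, ...) or
#' by a chromosome plus 1-based position interval. Removing a locus and
#' re-running the analysis shows how much of a population difference that
#' locus carries. The operation is idempotent; a region matching nothing
#' returns the catalog unchanged with a warning.
#'
#' @param catalog an [SnpCatalog-class].
#' @param region a list with either `cytoband` (prefix string) or
#'   `chromosome` plus `start` and `end` (inclusive interval).
#' @return the reduced [SnpCatalog-class]; the number of records removed is
#'   reported via [message()] and attached as `attr(, "removed")`.
#' @examples
#' \dontrun{removeByRegion(catalog, list(cytoband = "8q24"))}
#' @export
removeByRegion <- function(catalog, region) {
  stopifnot(is(catalog, "SnpCatalog"), is.list(region))
  rec <- records(catalog)
  if (!is.null(region$cytoband)) {
    hit <- startsWith(rec$cytoband, region$cytoband)
    if (!is.null(region$chromosome))
      hit <- hit & rec$chromosome == region$chromosome
  } else if (!is.null(region$chromosome) && !is.null(region$start) &&
             !is.null(region$end)) {
    hit <- rec$chromosome == region$chromosome &
      !is.na(rec$position) &
      rec$position >= region$start & rec$position <= region$end
  } else {
    stop("region must supply 'cytoband' or 'chromosome' + 'start' + 'end'",
         call. = FALSE)
  }
  if (!any(hit)) {
    warning("region matched no records; catalog returned unchanged",
            call. = FALSE)
    out <- catalog
  } else {
    message("removed ", sum(hit), " record(s) in region")
    out <- snpCatalog(rec[!hit, , drop = FALSE],
                      cancerLabel = cancerLabel(catalog),
                      populations = populations(catalog))
  }
  attr(out, "removed") <- sum(hit)
  out
}

#' Remove catalog records by rsID
#'
#' Drops the listed variants (e.g. hand-identified outliers that dominate a
#' regression fit). Unknown rsIDs are reported with a warning and ignored;
#' an empty list is the identity.
#'
#' @param catalog an [SnpCatalog-class].
#' @param rsids character vector of variant identifiers to remove.
#' @return the reduced [SnpCatalog-class], with `attr(, "removed")`.
#' @export
removeByRsids <- function(catalog, rsids) {
  stopifnot(is(catalog, "SnpCatalog"), is.character(rsids) || length(rsids) == 0L)
  rec <- records(catalog)
  unknown <- setdiff(rsids, rec$rsid)
  if (length(unknown) > 0L)
    warning("rsID(s) not in catalog: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  hit <- rec$rsid %in% rsids
  out <- if (!any(hit)) catalog else
    snpCatalog(rec[!hit, , drop = FALSE], cancerLabel = cancerLabel(catalog),
               populations = populations(catalog))
  attr(out, "removed") <- sum(hit)
  out
}

#' Describe one sensitivity re-analysis
#'
#' A sensitivity specification names what to remove (nothing, a region, or
#' an rsID list) and how to treat linkage disequilibrium: `"off"` (no
#' collapsing), `"full_rules"` (collapse with all three exclusion rules),
#' or `"ignore_locations"` (collapse with the gene and functional-region
#' rules disabled, keeping only the direction rule).
#'
#' @param name label for the results table.
#' @param removal `"none"`, `"by_region"`, or `"by_rsid_list"`.
#' @param region region list (see [removeByRegion()]); required for
#'   `"by_region"`.
#' @param rsids rsID vector; required (non-empty) for `"by_rsid_list"`.
#' @param ldMode `"off"`, `"full_rules"`, or `"ignore_locations"`.
#' @return a `"SensitivitySpec"` list.
#' @export
sensitivitySpec <- function(name,
                            removal = c("none", "by_region", "by_rsid_list"),
                            region = NULL, rsids = character(),
                            ldMode = c("off", "full_rules", "ignore_locations")) {
  removal <- match.arg(removal)
  ldMode <- match.arg(ldMode)
  if (removal == "by_region" && is.null(region))
    stop("removal = 'by_region' requires a region", call. = FALSE)
  if (removal == "by_rsid_list" && length(rsids) == 0L)
    stop("removal = 'by_rsid_list' requires a non-empty rsids vector",
         call. = FALSE)
  structure(list(name = name, removal = removal, region = region,
                 rsids = rsids, ldMode = ldMode),
            class = "SensitivitySpec")
}

#' Run a suite of sensitivity re-analyses
#'
#' Applies each [sensitivitySpec()] to the catalog (removal, then optional
#' LD collapsing), re-aggregates, and re-runs the population comparison and
#' (optionally) the Deming regression of population A frequency on
#' population B frequency. The catalog is never mutated, and the
#' all-defaults spec (`removal = "none"`, `ldMode = "off"`) reproduces the
#' primary analysis exactly. By default the ORmax used for weighted
#' frequencies is the one from the full input catalog, so Fw stays on a
#' common scale across subsets; set `recomputeOrMax = TRUE` to rescale
#' within each subset.
#'
#' @param catalog a harmonized [SnpCatalog-class].
#' @param ldPairs LD pairs data.frame (see [readLdPairs()]); may be `NULL`
#'   when no spec uses LD collapsing.
#' @param specs list of [sensitivitySpec()] objects.
#' @param popA,popB populations compared (t-test direction: popA vs popB;
#'   regression: y = popA, x = popB).
#' @param direction,variant,useWeighted t-test configuration, see
#'   [comparePopulations()].
#' @param r2Threshold LD threshold for [buildLdGroups()].
#' @param lambda Deming error-variance ratio; regression runs on unweighted
#'   F (set `withDeming = FALSE` to skip it).
#' @param withDeming also fit the Deming regression per spec.
#' @param recomputeOrMax recompute ORmax inside each subset.
#' @param pooling database pooling rule, see [pooledFrequency()].
#' @return data.frame, one row per spec: `name`, `n_units`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, and with `withDeming` also `slope`,
#'   `intercept`, `slope_se`, `p_slope_vs_one`.
#' @export
runSensitivitySuite <- function(catalog, ldPairs = NULL, specs,
                                popA, popB,
                                direction = c("greater", "less"),
                                variant = c("student", "welch", "paired"),
                                useWeighted = TRUE, r2Threshold = 0.8,
                                lambda = 1, withDeming = TRUE,
                                recomputeOrMax = FALSE,
                                pooling = c("weighted", "unweighted")) {
  stopifnot(is(catalog, "SnpCatalog"))
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  if (inherits(specs, "SensitivitySpec")) specs <- list(specs)
  fixed_ormax <- if (recomputeOrMax) NULL else max(records(catalog)$or_value)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "SensitivitySpec"))
    cat2 <- switch(sp$removal,
                   none = catalog,
                   by_region = removeByRegion(catalog, sp$region),
                   by_rsid_list = removeByRsids(catalog, sp$rsids))
    if (sp$ldMode != "off") {
      if (is.null(ldPairs))
        stop("spec '", sp$name, "' uses LD collapsing but no ldPairs were ",
             "supplied", call. = FALSE)
      groups <- buildLdGroups(cat2, ldPairs, r2Threshold = r2Threshold)
      groups <- applyCollapseRules(groups, cat2, popA = popA, popB = popB,
                                   ignoreLocations = sp$ldMode == "ignore_locations",
                                   pooling = pooling)
      cat2 <- collapseCatalog(cat2, groups, pooling = pooling)
    }
    agg <- aggregateCatalog(cat2, orMax = fixed_ormax, pooling = pooling)
    cmp <- comparePopulations(agg, popA, popB, useWeighted = useWeighted,
                              direction = direction, variant = variant)
    row <- data.frame(name = sp$name, n_units = cmp$n_units,
                      mean_a = cmp$mean_a, mean_b = cmp$mean_b,
                      t = cmp$ttest$statistic, df = cmp$ttest$df,
                      p = cmp$ttest$p_one_tailed, stringsAsFactors = FALSE)
    if (withDeming) {
      u <- aggregatedUnits(agg)
      fit <- demingRegression(u[[paste0(popB, "_F")]],
                              u[[paste0(popA, "_F")]], lambda = lambda)
      row$slope <- fit@slope
      row$intercept <- fit@intercept
      row$slope_se <- fit@slopeSE
      row$p_slope_vs_one <- fit@pSlopeVsOne
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
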