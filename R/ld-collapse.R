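#' Build linkage-disequilibrium groups from pairwise r-squared
#'
#' Partitions a catalog's SNPs into LD groups: the connected components of
#' the graph whose vertices are catalog rsIDs and whose edges are
#' same-chromosome pairs with r-squared strictly greater than the
#' threshold. Connected components (transitive closure) are used rather
#' than cliques because pairwise LD reports do not guarantee clique
#' structure. Singletons are not returned; pairs flagged unknown (rsIDs
#' outside the catalog) are ignored.
#'
#' @param catalog an [SnpCatalog-class].
#' @param ldPairs data.frame from [readLdPairs()] (columns `rsid_a`,
#'   `rsid_b`, `r2`, optionally `known`).
#' @param r2Threshold LD threshold in (0, 1); the conventional cut-off for
#'   calling two variants linked is r-squared > 0.8.
#' @return data.frame with one row per group: `group_id`, `chromosome`,
#'   `members` (list column of rsIDs in catalog order), `decision`,
#'   `reason` (both `NA` until [applyCollapseRules()] fills them).
#' @export
buildLdGroups <- function(catalog, ldPairs, r2Threshold = 0.8) {
  stopifnot(is(catalog, "SnpCatalog"), is.data.frame(ldPairs))
  if (r2Threshold <= 0 || r2Threshold >= 1)
    stop("r2Threshold must lie in (0,1)", call. = FALSE)
  rec <- records(catalog)
  empty <- data.frame(group_id = character(), chromosome = character(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  empty$decision <- character()
  empty$reason <- character()
  if (nrow(ldPairs) == 0L) return(empty)
  if (!is.null(ldPairs$known))
    ldPairs <- ldPairs[is.na(ldPairs$known) | ldPairs$known, , drop = FALSE]
  known <- ldPairs$rsid_a %in% rec$rsid & ldPairs$rsid_b %in% rec$rsid
  ldPairs <- ldPairs[known, , drop = FALSE]
  if (nrow(ldPairs) == 0L) return(empty)
  chr <- stats::setNames(rec$chromosome, rec$rsid)
  cross <- chr[ldPairs$rsid_a] != chr[ldPairs$rsid_b]
  if (any(cross))
    stop("LD pair(s) span two chromosomes: ",
         paste(sprintf("%s-%s", ldPairs$rsid_a[cross], ldPairs$rsid_b[cross]),
               collapse = ", "), call. = FALSE)
  edges <- ldPairs[ldPairs$r2 > r2Threshold, , drop = FALSE]
  if (nrow(edges) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(edges[, c("rsid_a", "rsid_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  # order members by catalog position; order groups by first member
  groups <- lapply(groups, function(m) m[order(match(m, rec$rsid))])
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(empty)
  groups <- groups[order(vapply(groups, function(m) match(m[1L], rec$rsid), 0L))]
  out <- data.frame(group_id = sprintf("LD%d", seq_along(groups)),
                    chromosome = vapply(groups, function(m) unname(chr[m[1L]]), ""),
                    stringsAsFactors = FALSE)
  out$members <- unname(groups)
  out$decision <- NA_character_
  out$reason <- NA_character_
  out
}

#' Decide whether each LD group may be collapsed
#'
#' Applies, in fixed order, the three exclusion rules under which linked
#' SNPs are kept as separate analysis units rather than averaged:
#' \enumerate{
#'   \item \emph{different_coding_genes}: members carry two or more distinct
#'     non-empty gene symbols;
#'   \item \emph{functional_region}: any member has a non-empty functional
#'     region annotation (e.g. "3'-UTR");
#'   \item \emph{opposite_direction}: the sign of the pooled-frequency
#'     difference between the two compared populations differs between
#'     members (the risk allele is commoner in one population for some
#'     members and in the other population for the rest; a zero difference
#'     is compatible with either sign).
#' }
#' The rule order only determines which `reason` is recorded when several
#' would trigger; any triggered rule prevents collapsing. With
#' `ignoreLocations = TRUE` the two location-based rules (1) and (2) are
#' disabled and only the direction rule applies.
#'
#' @param groups data.frame from [buildLdGroups()].
#' @param catalog the companion [SnpCatalog-class].
#' @param popA,popB population labels whose pooled-frequency difference
#'   defines the direction in rule 3 (defaults: first two catalog
#'   populations).
#' @param ignoreLocations disable rules 1 and 2.
#' @param pooling passed to [aggregateCatalog()] for the rule-3 frequencies.
#' @return `groups` with `decision` (`"collapsed"` / `"kept_separate"`) and
#'   `reason` (`"none"`, `"different_coding_genes"`, `"functional_region"`,
#'   `"opposite_direction"`) filled in.
#' @export
applyCollapseRules <- function(groups, catalog,
                               popA = populations(catalog)[1L],
                               popB = populations(catalog)[2L],
                               ignoreLocations = FALSE,
                               pooling = c("weighted", "unweighted")) {
  stopifnot(is(catalog, "SnpCatalog"), is.data.frame(groups))
  pooling <- match.arg(pooling)
  if (nrow(groups) == 0L) return(groups)
  rec <- records(catalog)
  agg <- aggregatedUnits(aggregateCatalog(catalog, pooling = pooling))
  dF <- stats::setNames(agg[[paste0(popA, "_F")]] - agg[[paste0(popB, "_F")]],
                        agg$unit_id)
  gene <- stats::setNames(rec$gene, rec$rsid)
  funreg <- stats::setNames(rec$functional_region, rec$rsid)
  for (i in seq_len(nrow(groups))) {
    m <- groups$members[[i]]
    if (!all(m %in% rec$rsid))
      stop("group ", groups$group_id[i], " has member(s) absent from the ",
           "catalog: ", paste(setdiff(m, rec$rsid), collapse = ", "),
           call. = FALSE)
    reason <- "none"
    if (!ignoreLocations) {
      gsym <- unique(gene[m][nzchar(gene[m])])
      if (length(gsym) >= 2L) reason <- "different_coding_genes"
      else if (any(nzchar(funreg[m]))) reason <- "functional_region"
    }
    if (reason == "none") {
      s <- sign(dF[m])
      s <- s[s != 0]  # a zero difference matches either direction
      if (length(unique(s)) > 1L) reason <- "opposite_direction"
    }
    groups$decision[i] <- if (reason == "none") "collapsed" else "kept_separate"
    groups$reason[i] <- reason
  }
  groups
}

#' Collapse decided LD groups into averaged units
#'
#' Replaces each group with `decision == "collapsed"` by a single synthetic
#' unit: its per-population frequency is the unweighted mean of the member
#' pooled frequencies F (stored as one pseudo-observation under database
#' label `"pooled"`, with the summed member individual counts as sample
#' size), and its odds ratio follows `orRule` (`"max"`, the default, or
#' `"mean"` over members). Kept-separate groups and ungrouped SNPs pass
#' through unchanged. The collapsed unit takes the first member's alleles
#' and position slot in the record order; its gene symbol is kept only when
#' all members agree. Groups whose members are no longer present in the
#' catalog are skipped, which makes the operation idempotent. The unit
#' count satisfies `nUnits(out) == nUnits(in) - sum(|group| - 1)` over the
#' groups actually collapsed.
#'
#' @param catalog an [SnpCatalog-class].
#' @param groups decided groups from [applyCollapseRules()].
#' @param orRule odds ratio assigned to a collapsed unit: `"max"` or
#'   `"mean"` of the members.
#' @param pooling passed to [aggregateCatalog()] for the member F values.
#' @return a new [SnpCatalog-class] of analysis units.
#' @export
collapseCatalog <- function(catalog, groups, orRule = c("max", "mean"),
                            pooling = c("weighted", "unweighted")) {
  stopifnot(is(catalog, "SnpCatalog"), is.data.frame(groups))
  orRule <- match.arg(orRule)
  pooling <- match.arg(pooling)
  rec <- records(catalog)
  if (nrow(groups) > 0L && any(is.na(groups$decision)))
    stop("undecided group(s): run applyCollapseRules() first", call. = FALSE)
  todo <- groups[!is.na(groups$decision) & groups$decision == "collapsed", ,
                 drop = FALSE]
  if (nrow(todo) > 0L) {
    present <- vapply(todo$members, function(m) all(m %in% rec$rsid), TRUE)
    todo <- todo[present, , drop = FALSE]
  }
  if (nrow(todo) == 0L) return(catalog)
  agg <- aggregatedUnits(aggregateCatalog(catalog, pooling = pooling))
  fc <- .freqColumnInfo(names(rec))
  pops <- populations(catalog)
  keep <- rec
  for (i in seq_len(nrow(todo))) {
    m <- todo$members[[i]]
    mrec <- rec[match(m, rec$rsid), , drop = FALSE]
    magg <- agg[match(m, agg$unit_id), , drop = FALSE]
    unit <- mrec[1L, , drop = FALSE]
    unit$rsid <- todo$group_id[i]
    gsym <- unique(mrec$gene[nzchar(mrec$gene)])
    unit$gene <- if (length(gsym) == 1L) gsym else ""
    unit$functional_region <- ""
    unit$or_value <- if (orRule == "max") max(mrec$or_value) else mean(mrec$or_value)
    unit$ci_low <- NA_real_; unit$ci_high <- NA_real_; unit$p_value <- NA_real_
    # wipe member observations, store one pooled pseudo-observation per pop
    for (col in c(fc$freq_col, fc$n_col)) unit[[col]] <- NA_real_
    for (pop in pops) {
      Fm <- magg[[paste0(pop, "_F")]]
      if (any(is.na(Fm)))
        stop("member of group ", todo$group_id[i], " lacks a pooled ",
             "frequency for population '", pop, "'", call. = FALSE)
      pc <- fc[fc$pop == pop, , drop = FALSE]
      n_tot <- sum(as.matrix(mrec[, pc$n_col, drop = FALSE]), na.rm = TRUE)
      unit[[paste0(pop, "_freq_pooled")]] <- mean(Fm)
      unit[[paste0(pop, "_n_pooled")]] <- n_tot
    }
    first_at <- match(m[1L], keep$rsid)
    for (col in setdiff(names(unit), names(keep))) keep[[col]] <- NA_real_
    keep[first_at, names(unit)] <- unit
    keep <- keep[!(keep$rsid %in% m[-1L]), , drop = FALSE]
  }
  # drop all-NA pooled columns if nothing used them (keeps schema tidy)
  snpCatalog(keep, cancerLabel = cancerLabel(catalog), populations = pops)
}
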