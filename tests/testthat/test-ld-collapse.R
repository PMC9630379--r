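ldPairsDf <- function(a, b, r2) {
  data.frame(rsid_a = a, rsid_b = b, r2 = r2, stringsAsFactors = FALSE)
}

test_that("LD groups are the connected components above the r2 threshold", {
  cat <- singleDbCatalog(or_value = rep(1.5, 5), afr = seq(0.2, 0.6, 0.1),
                         eur = seq(0.2, 0.6, 0.1),
                         chromosome = c("12", "12", "12", "5", "5"),
                         rsid = c("rsA", "rsB", "rsC", "rsD", "rsE"))
  # nothing above the threshold: no groups
  g <- buildLdGroups(cat, ldPairsDf("rsA", "rsB", 0.5))
  expect_equal(nrow(g), 0L)
  # the threshold is strict: r2 = 0.8 is not linked
  g <- buildLdGroups(cat, ldPairsDf("rsA", "rsB", 0.8))
  expect_equal(nrow(g), 0L)
  # transitive chain A-B, B-C forms one group of three
  g <- buildLdGroups(cat, ldPairsDf(c("rsA", "rsB"), c("rsB", "rsC"),
                                    c(0.9, 0.85)))
  expect_equal(nrow(g), 1L)
  expect_setequal(g$members[[1]], c("rsA", "rsB", "rsC"))
  # disconnected components on different chromosomes stay separate
  g <- buildLdGroups(cat, ldPairsDf(c("rsA", "rsD"), c("rsB", "rsE"),
                                    c(0.9, 0.95)))
  expect_equal(nrow(g), 2L)
  expect_equal(g$chromosome, c("12", "5"))
  # a pair spanning two chromosomes is inconsistent input
  expect_error(buildLdGroups(cat, ldPairsDf("rsA", "rsD", 0.9)),
               "span two chromosomes")
  # pairs flagged as unknown are ignored
  pairs <- ldPairsDf(c("rsA", "rsX"), c("rsB", "rsC"), c(0.9, 0.9))
  pairs$known <- c(TRUE, FALSE)
  g <- buildLdGroups(cat, pairs)
  expect_equal(nrow(g), 1L)
})

test_that("raising the r2 threshold only refines the grouping", {
  set.seed(21)
  n <- 30
  cat <- singleDbCatalog(or_value = rep(1.5, n), afr = runif(n), eur = runif(n),
                         chromosome = rep("7", n))
  ids <- records(cat)$rsid
  pairs <- ldPairsDf(sample(ids, 40, TRUE), sample(ids, 40, TRUE),
                     runif(40, 0.5, 1))
  pairs <- pairs[pairs$rsid_a != pairs$rsid_b, ]
  prev <- NULL
  for (thr in c(0.55, 0.7, 0.85, 0.95)) {
    g <- buildLdGroups(cat, pairs, r2Threshold = thr)
    grouped <- unlist(g$members)
    expect_equal(anyDuplicated(grouped), 0L)  # groups partition the linked SNPs
    if (!is.null(prev)) {
      # fewer SNPs grouped, no group grows, and each new group refines an old one
      expect_lte(length(grouped), length(unlist(prev$members)))
      if (nrow(g) > 0 && nrow(prev) > 0) {
        expect_lte(max(lengths(g$members)), max(lengths(prev$members)))
        for (m in g$members) {
          parent <- vapply(prev$members, function(pm) all(m %in% pm), TRUE)
          expect_equal(sum(parent), 1L)
        }
      }
    }
    prev <- g
  }
})

test_that("the three keep-separate rules fire in their documented order", {
  collapseDecision <- function(gene, funreg, afr, eur, ignoreLocations = FALSE) {
    n <- length(afr)
    cat <- singleDbCatalog(or_value = rep(1.5, n), afr = afr, eur = eur,
                           gene = gene, functional_region = funreg)
    g <- buildLdGroups(cat, ldPairsDf(rep("rs1", n - 1),
                                      sprintf("rs%d", 2:n), rep(0.9, n - 1)))
    g <- applyCollapseRules(g, cat, ignoreLocations = ignoreLocations)
    g[, c("decision", "reason")]
  }
  # same gene, no functional region, same direction: collapse
  d <- collapseDecision(c("KITLG", "KITLG"), c("", ""),
                        afr = c(0.3, 0.35), eur = c(0.2, 0.3))
  expect_equal(d$decision, "collapsed")
  expect_equal(d$reason, "none")
  # rule 1: two distinct coding genes
  d <- collapseDecision(c("GENE1", "GENE2"), c("", ""),
                        afr = c(0.3, 0.35), eur = c(0.2, 0.3))
  expect_equal(d$decision, "kept_separate")
  expect_equal(d$reason, "different_coding_genes")
  # rule 2: any member in a functional region
  d <- collapseDecision(c("", ""), c("3'-UTR", ""),
                        afr = c(0.3, 0.35), eur = c(0.2, 0.3))
  expect_equal(d$reason, "functional_region")
  # rule 3: opposite frequency directions between the populations
  d <- collapseDecision(c("", ""), c("", ""),
                        afr = c(0.3, 0.25), eur = c(0.2, 0.3))
  expect_equal(d$reason, "opposite_direction")
  # a zero difference is compatible with either direction
  d <- collapseDecision(c("", ""), c("", ""),
                        afr = c(0.3, 0.25), eur = c(0.3, 0.2))
  expect_equal(d$reason, "none")
  # rule order: gene beats functional region in the recorded reason
  d <- collapseDecision(c("GENE1", "GENE2"), c("3'-UTR", ""),
                        afr = c(0.3, 0.35), eur = c(0.2, 0.3))
  expect_equal(d$reason, "different_coding_genes")
  # location-blind mode disables rules 1 and 2 but not 3
  d <- collapseDecision(c("GENE1", "GENE2"), c("3'-UTR", ""),
                        afr = c(0.3, 0.35), eur = c(0.2, 0.3),
                        ignoreLocations = TRUE)
  expect_equal(d$decision, "collapsed")
  d <- collapseDecision(c("GENE1", "GENE2"), c("", ""),
                        afr = c(0.3, 0.25), eur = c(0.2, 0.3),
                        ignoreLocations = TRUE)
  expect_equal(d$reason, "opposite_direction")
})

test_that("collapsing averages member frequencies and keeps exact unit counts", {
  cat <- singleDbCatalog(or_value = c(1.2, 1.8, 1.5, 2.0),
                         afr = c(0.2, 0.4, 0.7, 0.1),
                         eur = c(0.15, 0.3, 0.6, 0.2))
  g <- buildLdGroups(cat, ldPairsDf("rs1", "rs2", 0.9))
  g <- applyCollapseRules(g, cat)
  expect_equal(g$decision, "collapsed")
  out <- collapseCatalog(cat, g)
  # bookkeeping: 4 units - (2 - 1) = 3
  expect_equal(nUnits(out), 3L)
  u <- aggregatedUnits(aggregateCatalog(out, orMax = 2.0))
  unit <- u[u$unit_id == "LD1", ]
  expect_equal(unit$afr_F, 0.3)   # mean of 0.2 and 0.4
  expect_equal(unit$eur_F, 0.225)
  expect_equal(unit$or_value, 1.8)  # max of member ORs by default
  or_mean <- collapseCatalog(cat, g, orRule = "mean")
  expect_equal(records(or_mean)$or_value[records(or_mean)$rsid == "LD1"], 1.5)
  # collapsing again with the same groups changes nothing
  expect_identical(records(collapseCatalog(out, g)), records(out))
  # kept-separate groups pass through unchanged
  g2 <- g; g2$decision <- "kept_separate"; g2$reason <- "functional_region"
  expect_identical(records(collapseCatalog(cat, g2)), records(cat))
  # undecided groups are refused
  g3 <- g; g3$decision <- NA_character_
  expect_error(collapseCatalog(cat, g3), "undecided")
})

test_that("with no LD pairs the collapsed analysis equals the primary analysis", {
  sim <- simulateCatalog(syntheticConfig(nSnps = 40, delta = 0.02, seed = 5))
  g <- buildLdGroups(sim$catalog, data.frame(rsid_a = character(),
                                             rsid_b = character(),
                                             r2 = numeric()))
  out <- collapseCatalog(sim$catalog, g)
  expect_identical(records(out), records(sim$catalog))
  expect_identical(aggregatedUnits(aggregateCatalog(out)),
                   aggregatedUnits(aggregateCatalog(sim$catalog)))
})
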