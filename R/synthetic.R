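#' Configuration for the synthetic catalog generator
#'
#' Bundles and validates the generative parameters of [simulateCatalog()].
#' The defaults describe a plausible curated GWAS catalog compared between
#' two ancestral populations: base risk-allele frequencies uniform on
#' (0.05, 0.95); population A shifted relative to population B by a
#' constant `delta` plus per-SNP heterogeneity (`snpNoiseSd`, so a paired
#' test has genuine per-unit variation); lognormal odds ratios floored at 1
#' (median 1.2); and three reference databases whose individual counts
#' follow the scale ordering of the public frequency sources (a
#' thousand-genomes-sized panel, a mid-sized sequencing aggregate, and a
#' very large array aggregate).
#'
#' @param nSnps number of SNPs (> 0).
#' @param delta mean true-frequency shift of population A relative to B.
#' @param freqDist base-frequency distribution for population B:
#'   `"uniform"` or `"beta"`.
#' @param freqParams length-2 parameters: uniform bounds, or beta shapes.
#' @param snpNoiseSd SD of the per-SNP shift heterogeneity.
#' @param orLogMean,orLogSd log-scale mean and SD of the odds ratios.
#' @param dbSampleSizes named vector of individuals per database.
#' @param nLdGroups,ldGroupSize number and size of LD groups; group members
#'   share identical true frequencies and pairwise r-squared drawn above
#'   0.8.
#' @param seed integer root seed; replicate helpers derive replicate seeds
#'   as `seed + replicate index`.
#' @return a validated `"SyntheticConfig"` list.
#' @export
syntheticConfig <- function(nSnps = 226, delta = 0,
                            freqDist = c("uniform", "beta"),
                            freqParams = c(0.05, 0.95),
                            snpNoiseSd = 0.02,
                            orLogMean = log(1.2), orLogSd = 0.2,
                            dbSampleSizes = c(`1kg` = 661, gnomad = 8000,
                                              alfa = 50000),
                            nLdGroups = 0, ldGroupSize = 3, seed = 1) {
  freqDist <- match.arg(freqDist)
  if (nSnps < 1) stop("nSnps must be positive", call. = FALSE)
  if (length(freqParams) != 2L || any(!is.finite(freqParams)))
    stop("freqParams must be two finite numbers", call. = FALSE)
  if (freqDist == "uniform" &&
      (freqParams[1L] < 0 || freqParams[2L] > 1 || diff(freqParams) <= 0))
    stop("uniform freqParams must satisfy 0 <= low < high <= 1", call. = FALSE)
  if (freqDist == "beta" && any(freqParams <= 0))
    stop("beta freqParams must be positive shapes", call. = FALSE)
  if (snpNoiseSd < 0) stop("snpNoiseSd must be non-negative", call. = FALSE)
  if (is.null(names(dbSampleSizes)) || any(!nzchar(names(dbSampleSizes))))
    stop("dbSampleSizes must be a named vector", call. = FALSE)
  if (any(dbSampleSizes <= 0)) stop("dbSampleSizes must be positive", call. = FALSE)
  if (nLdGroups < 0 || ldGroupSize < 2)
    stop("need nLdGroups >= 0 and ldGroupSize >= 2", call. = FALSE)
  if (nLdGroups * ldGroupSize > nSnps)
    stop("LD groups would need more SNPs than nSnps", call. = FALSE)
  structure(list(nSnps = as.integer(nSnps), delta = delta, freqDist = freqDist,
                 freqParams = freqParams, snpNoiseSd = snpNoiseSd,
                 orLogMean = orLogMean, orLogSd = orLogSd,
                 dbSampleSizes = dbSampleSizes,
                 nLdGroups = as.integer(nLdGroups),
                 ldGroupSize = as.integer(ldGroupSize),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Simulate a SNP catalog with known ground truth
#'
#' Draws a two-population catalog under the generative model the analysis
#' assumes. Per SNP: a true population-B frequency `p_B` from the base
#' distribution; a true population-A frequency
#' `p_A = clip(p_B + delta + noise, 0.01, 0.99)`; an odds ratio
#' `max(1, Lognormal(orLogMean, orLogSd))`; and, per database `d` with
#' `n_d` individuals, an observed frequency `Binomial(2 n_d, p) / (2 n_d)`
#' for each population. Members of an LD group share identical true
#' frequencies (including the per-SNP noise) and a chromosome, and the
#' returned pair table lists all within-group pairs with r-squared drawn
#' from Uniform(0.85, 0.99). A fixed seed makes the output bit-identical
#' across calls.
#'
#' @param config a [syntheticConfig()].
#' @return list with `catalog` (an [SnpCatalog-class], populations
#'   `c("afr", "eur")` with A = afr), `ldPairs` (data.frame `rsid_a`,
#'   `rsid_b`, `r2`), and `truth` (list of latent `p_a`, `p_b`, `or`,
#'   `delta`, and the config).
#' @export
simulateCatalog <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$nSnps
  p_b <- switch(config$freqDist,
                uniform = stats::runif(n, config$freqParams[1L],
                                       config$freqParams[2L]),
                beta = stats::rbeta(n, config$freqParams[1L],
                                    config$freqParams[2L]))
  noise <- stats::rnorm(n, 0, config$snpNoiseSd)
  chrom <- as.character(sample.int(22L, n, replace = TRUE))

  # LD groups occupy the first nLdGroups * ldGroupSize SNPs
  group_of <- rep(NA_integer_, n)
  if (config$nLdGroups > 0L) {
    idx <- seq_len(config$nLdGroups * config$ldGroupSize)
    group_of[idx] <- rep(seq_len(config$nLdGroups), each = config$ldGroupSize)
    for (g in seq_len(config$nLdGroups)) {
      gi <- which(group_of == g)
      p_b[gi] <- p_b[gi[1L]]
      noise[gi] <- noise[gi[1L]]
      chrom[gi] <- chrom[gi[1L]]
    }
  }
  clip <- function(p) pmin(pmax(p, 0.01), 0.99)
  p_b <- clip(p_b)
  p_a <- clip(p_b + config$delta + noise)
  if (all(p_a %in% c(0.01, 0.99)))
    stop("infeasible configuration: delta pushes all population-A ",
         "frequencies to the clip bounds", call. = FALSE)

  or_value <- pmax(1, stats::rlnorm(n, config$orLogMean, config$orLogSd))
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, n, replace = TRUE)
  ref <- vapply(risk, function(b) sample(setdiff(bases, b), 1L), "")
  rec <- data.frame(rsid = sprintf("rs%06d", seq_len(n)),
                    chromosome = chrom,
                    position = sample.int(2.4e8, n, replace = TRUE),
                    gene = "", functional_region = "",
                    risk_allele = risk, ref_allele = unname(ref),
                    or_value = or_value, stringsAsFactors = FALSE)
  for (db in names(config$dbSampleSizes)) {
    n_ind <- config$dbSampleSizes[[db]]
    m <- 2 * n_ind  # allele count per database
    rec[[paste0("afr_freq_", db)]] <- stats::rbinom(n, m, p_a) / m
    rec[[paste0("afr_n_", db)]] <- n_ind
    rec[[paste0("eur_freq_", db)]] <- stats::rbinom(n, m, p_b) / m
    rec[[paste0("eur_n_", db)]] <- n_ind
  }
  ld <- data.frame(rsid_a = character(), rsid_b = character(), r2 = numeric(),
                   stringsAsFactors = FALSE)
  if (config$nLdGroups > 0L) {
    for (g in seq_len(config$nLdGroups)) {
      gi <- which(group_of == g)
      pairs <- utils::combn(gi, 2L)
      ld <- rbind(ld, data.frame(rsid_a = rec$rsid[pairs[1L, ]],
                                 rsid_b = rec$rsid[pairs[2L, ]],
                                 r2 = stats::runif(ncol(pairs), 0.85, 0.99),
                                 stringsAsFactors = FALSE))
    }
  }
  list(catalog = snpCatalog(rec, cancerLabel = "synthetic",
                            populations = c("afr", "eur")),
       ldPairs = ld,
       truth = list(p_a = p_a, p_b = p_b, or = or_value,
                    ld_group = group_of, delta = config$delta,
                    config = config))
}

# run fn(simulation) over nReps replicates; replicate r reuses the config
# with seed = config$seed + r, keeping replicates independently reproducible
.replicate <- function(config, nReps, fn) {
  vapply(seq_len(nReps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    fn(simulateCatalog(cfg))
  }, 0)
}

# one-tailed p of the simulate -> aggregate -> compare pipeline
.pipelineP <- function(sim, variant, direction, useWeighted) {
  agg <- aggregateCatalog(sim$catalog)
  comparePopulations(agg, "afr", "eur", useWeighted = useWeighted,
                     direction = direction, variant = variant)$ttest$p_one_tailed
}

#' Empirical type-I error of the population comparison
#'
#' Simulates null catalogs (`delta` forced to 0), runs the full
#' simulate-aggregate-compare pipeline on each, and reports the fraction of
#' replicates with one-tailed p below `alpha`, with a 95% binomial
#' (Clopper-Pearson) interval. A calibrated test should cover `alpha`.
#'
#' @param config a [syntheticConfig()]; its `delta` is overridden to 0.
#' @param alpha nominal level.
#' @param nReps number of replicates (>= 200 recommended).
#' @param variant,direction,useWeighted comparison configuration, see
#'   [comparePopulations()].
#' @return list with `rate`, `ci` (length 2), `alpha`, `nReps`.
#' @export
calibrateTypeIError <- function(config, alpha = 0.05, nReps = 1000,
                                variant = c("paired", "student", "welch"),
                                direction = "greater", useWeighted = TRUE) {
  stopifnot(inherits(config, "SyntheticConfig"))
  variant <- match.arg(variant)
  config$delta <- 0
  p <- .replicate(config, nReps,
                  function(sim) .pipelineP(sim, variant, direction, useWeighted))
  hits <- sum(p < alpha)
  ci <- as.numeric(stats::binom.test(hits, nReps)$conf.int)
  list(rate = hits / nReps, ci = ci, alpha = alpha, nReps = nReps)
}

#' Empirical power of the population comparison
#'
#' As [calibrateTypeIError()], but under the configured frequency shift
#' `delta > 0`: the rejection fraction estimates the power to detect that
#' shift with the given catalog size. At `delta = 0` this reduces to the
#' type-I error by definition.
#'
#' @inheritParams calibrateTypeIError
#' @return list with `power`, `ci`, `alpha`, `nReps`, `delta`.
#' @export
estimatePower <- function(config, alpha = 0.05, nReps = 500,
                          variant = c("paired", "student", "welch"),
                          direction = "greater", useWeighted = TRUE) {
  stopifnot(inherits(config, "SyntheticConfig"))
  variant <- match.arg(variant)
  p <- .replicate(config, nReps,
                  function(sim) .pipelineP(sim, variant, direction, useWeighted))
  hits <- sum(p < alpha)
  ci <- as.numeric(stats::binom.test(hits, nReps)$conf.int)
  list(power = hits / nReps, ci = ci, alpha = alpha, nReps = nReps,
       delta = config$delta)
}

#' Recovery of the generative frequency shift
#'
#' Runs the simulate-aggregate pipeline over replicates and returns the
#' mean estimated shift, i.e. the average over replicates of
#' `mean(F_afr) - mean(F_eur)` on pooled frequencies. With an unbiased
#' pipeline this recovers the generative `delta` up to clipping effects at
#' the frequency bounds.
#'
#' @param config a [syntheticConfig()].
#' @param nReps number of replicates.
#' @return list with `mean_shift`, `se` (Monte-Carlo standard error),
#'   `delta`, `nReps`.
#' @export
estimateShiftRecovery <- function(config, nReps = 500) {
  stopifnot(inherits(config, "SyntheticConfig"))
  shifts <- .replicate(config, nReps, function(sim) {
    u <- aggregatedUnits(aggregateCatalog(sim$catalog))
    mean(u$afr_F) - mean(u$eur_F)
  })
  list(mean_shift = mean(shifts), se = stats::sd(shifts) / sqrt(nReps),
       delta = config$delta, nReps = nReps)
}
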