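# Small in-memory fixtures shared across tests.

# Three hand-written SNP records over two populations and two databases,
# with one missing observation (rs2 has no gnomAD entry) and some blank
# optional fields.
fixtureRecords <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    chromosome = c("8", "8", "12"),
    position = c(128000000, 127500000, 88900000),
    cytoband = c("8q24.21", "8q21.13", "12q21.32"),
    gene = c("MYC", "", "KITLG"),
    functional_region = c("", "", ""),
    risk_allele = c("A", "C", "G"),
    ref_allele = c("G", "T", "A"),
    or_value = c(1.5, 2.0, 1.2),
    ci_low = c(1.2, NA, 1.05),
    ci_high = c(1.9, NA, 1.4),
    p_value = c(1e-8, 1e-6, NA),
    afr_freq_1kg = c(0.40, 0.20, 0.55),
    afr_n_1kg = c(661, 661, 661),
    afr_freq_gnomad = c(0.42, NA, 0.50),
    afr_n_gnomad = c(8000, NA, 8000),
    eur_freq_1kg = c(0.30, 0.25, 0.60),
    eur_n_1kg = c(503, 503, 503),
    eur_freq_gnomad = c(0.33, NA, 0.62),
    eur_n_gnomad = c(7500, NA, 7500),
    stringsAsFactors = FALSE
  )
}

fixtureCatalog <- function() {
  snpCatalog(fixtureRecords(), cancerLabel = "fixture",
             populations = c("afr", "eur"))
}

# Write a raw TSV from a data.frame of character cells, preserving blanks.
writeRawTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}

fixtureTsvPath <- function(mutate = identity) {
  df <- fixtureRecords()
  for (col in names(df)) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  writeRawTsv(mutate(df))
}

# Catalog with a single database, handy when frequencies must equal exact
# target values after pooling.
singleDbCatalog <- function(or_value, afr, eur, gene = rep("", length(or_value)),
                            functional_region = rep("", length(or_value)),
                            chromosome = rep("1", length(or_value)),
                            rsid = sprintf("rs%d", seq_along(or_value))) {
  snpCatalog(data.frame(
    rsid = rsid, chromosome = chromosome, gene = gene,
    functional_region = functional_region,
    risk_allele = "A", ref_allele = "G", or_value = or_value,
    afr_freq_1kg = afr, afr_n_1kg = 1000,
    eur_freq_1kg = eur, eur_n_1kg = 1000,
    stringsAsFactors = FALSE
  ), cancerLabel = "singledb", populations = c("afr", "eur"))
}
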