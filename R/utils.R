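# Internal helpers shared across the package. Frequency observations are
# stored wide: one <pop>_freq_<db> / <pop>_n_<db> column pair per
# population x database combination.

.FREQ_COL_RE <- "^([A-Za-z0-9]+)_freq_([A-Za-z0-9]+)$"
.N_COL_RE <- "^([A-Za-z0-9]+)_n_([A-Za-z0-9]+)$"

# Parse frequency/sample-size column pairs from a header. Returns a
# data.frame(pop, db, freq_col, n_col); errors on unpaired columns.
.freqColumnInfo <- function(cols) {
  fm <- regmatches(cols, regexec(.FREQ_COL_RE, cols))
  nm <- regmatches(cols, regexec(.N_COL_RE, cols))
  fidx <- which(lengths(fm) == 3L)
  nidx <- which(lengths(nm) == 3L)
  out <- data.frame(pop = vapply(fm[fidx], `[`, "", 2L),
                    db = vapply(fm[fidx], `[`, "", 3L),
                    freq_col = cols[fidx],
                    stringsAsFactors = FALSE)
  out$n_col <- paste0(out$pop, "_n_", out$db)
  missing_n <- setdiff(out$n_col, cols[nidx])
  if (length(missing_n) > 0L)
    stop("frequency column(s) without matching sample-size column(s): ",
         paste(missing_n, collapse = ", "), call. = FALSE)
  orphan_n <- setdiff(cols[nidx], out$n_col)
  if (length(orphan_n) > 0L)
    stop("sample-size column(s) without matching frequency column(s): ",
         paste(orphan_n, collapse = ", "), call. = FALSE)
  out
}

# Populations present in a catalog-shaped data.frame header.
.populationsInHeader <- function(cols) unique(.freqColumnInfo(cols)$pop)

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be positive", call. = FALSE)
  invisible(x)
}

# Canonical column order: metadata first, then frequency pairs grouped by
# population then database, in first-appearance order.
.orderCatalogColumns <- function(rec) {
  fc <- .freqColumnInfo(names(rec))
  meta <- intersect(.CANONICAL_COLS, names(rec))
  freq_cols <- as.vector(t(as.matrix(fc[order(match(fc$pop, unique(fc$pop)),
                                              match(fc$db, unique(fc$db))),
                                        c("freq_col", "n_col")])))
  other <- setdiff(names(rec), c(meta, freq_cols))
  rec[, c(meta, freq_cols, other), drop = FALSE]
}
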