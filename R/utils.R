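# Internal helpers shared across modules.

# Canonical key for one BSJ: "chrom:start|end:strand".
circ_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d|%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

# CIRI2-style identifier (no strand).
circ_id <- function(chrom, start, end) {
  sprintf("%s:%d|%d", chrom, as.integer(start), as.integer(end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_circkit <- function(fmt, ..., class = "circkit_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_circkit(fmt, ...)
  invisible(TRUE)
}

# Deterministic TSV writer: fixed column order as given, no quoting, no
# row names.  Used by every table writer so outputs are byte-stable.
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                       stringsAsFactors = FALSE))
}

# Pearson R^2 with a missing-value flag for degenerate input.
pearson_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}
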