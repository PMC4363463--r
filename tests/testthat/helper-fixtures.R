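# Fixtures are built in code; nothing is read from checked-in data files.

# Universe directly from vectors (bypasses the TSV path when the test is not
# about ingestion).
make_universe <- function(log_expr, cds = NULL, tx = NULL, clip = NULL,
                          symbols = NULL) {
  n <- length(log_expr)
  if (is.null(symbols)) symbols <- sprintf("G%04d", seq_len(n))
  df <- data.frame(symbol = symbols,
                   log_expr = log_expr,
                   cds_len_log2 = if (is.null(cds)) rep(10, n) else cds,
                   tx_len_log2 = if (is.null(tx)) rep(11, n) else tx,
                   clip_count = if (is.null(clip)) rep(NA_real_, n) else clip,
                   stringsAsFactors = FALSE)
  covmatch:::new_gene_universe(df, provenance = "test fixture")
}

# Hand-specified weight vector aligned to a universe.
make_weights <- function(u, prob) {
  stopifnot(length(prob) == nrow(u))
  structure(data.frame(symbol = u$symbol, raw_ratio = prob,
                       probability = prob / sum(prob),
                       stringsAsFactors = FALSE),
            mode = "manual", bandwidths = list(),
            class = c("weight_vector", "data.frame"))
}

# Write a small gene-table TSV; `rows` is a data frame whose columns are
# written verbatim (character cells allowed, to plant parse failures).
write_fixture_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fixture_rows <- function(n = 5) {
  data.frame(symbol = sprintf("gene%d", seq_len(n)),
             logCPM = seq(2, by = 0.5, length.out = n),
             cds_length = rep(10.5, n),
             tx_length = rep(11.5, n),
             clip_count = seq_len(n),
             stringsAsFactors = FALSE)
}

write_set_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}
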