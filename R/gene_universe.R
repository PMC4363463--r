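# Gene universe: ingestion, validation and filtering of the per-gene
# covariate table that forms the sampling frame and the denominator of
# every overlap test.

#' Construct a gene set
#'
#' A gene set is a named, de-duplicated collection of gene symbols. Symbols
#' are uppercased and stripped of surrounding whitespace before any set
#' operation, so human candidate lists match mouse-derived tables regardless
#' of case convention.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Single string naming the set.
#' @return An object of class `gene_set`: a list with `name` and `symbols`
#'   (unique, normalized, in first-occurrence order).
#' @export
gene_set <- function(symbols, name = "gene_set") {
  stopifnot(is.character(symbols), length(name) == 1L)
  syms <- normalize_symbols(symbols)
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0L) {
    stop("gene set '", name, "' is empty after normalization", call. = FALSE)
  }
  structure(list(name = as.character(name), symbols = unique(syms)),
            class = "gene_set")
}

normalize_symbols <- function(x) toupper(trimws(as.character(x)))

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$symbols), " symbols\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene set from a plain-text file
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the file.
#' @param name Name for the resulting set (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("gene set file '", path, "' contains no symbols", call. = FALSE)
  }
  gene_set(lines, name = name)
}

#' Write a gene set to a plain-text file
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$symbols, path)
  invisible(path)
}

# Internal constructor; `df` must already carry the canonical columns.
new_gene_universe <- function(df, provenance = character()) {
  stopifnot(is.data.frame(df),
            all(c("symbol", "log_expr", "cds_len_log2", "tx_len_log2",
                  "clip_count") %in% names(df)))
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("gene_universe", "data.frame"))
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("<gene_universe> ", nrow(x), " genes\n", sep = "")
  for (p in attr(x, "provenance")) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' Provenance of a gene universe
#'
#' Every ingestion and filtering step appends a human-readable line with the
#' record counts involved, so the filter cascade that produced a universe can
#' always be reconstructed.
#'
#' @param u A `gene_universe`.
#' @return Character vector of provenance lines.
#' @export
provenance <- function(u) {
  stopifnot(inherits(u, "gene_universe"))
  attr(u, "provenance")
}

#' Read the per-gene covariate table
#'
#' Reads a tab-separated table with a header row holding, per gene: symbol,
#' log2 counts-per-million expression, coding-sequence length, transcript
#' length, and CLIP tag count. Column names are configurable through
#' `column_map`. Lengths may be supplied raw in nucleotides
#' (`log_transform = TRUE`, the default expectation for annotation exports)
#' or already on the log2 scale.
#'
#' Cells that fail numeric parsing become missing values rather than zeros;
#' a record missing a length simply cannot pass a filter that requires that
#' length. Records with an unusable symbol or expression value are dropped
#' (expression is required by every downstream operation), and duplicated
#' symbols keep their first occurrence. Both events are reported via
#' [message()]/[warning()] with counts.
#'
#' @param path Path to the TSV file.
#' @param column_map Named list mapping roles `symbol`, `log_expr`,
#'   `cds_length`, `tx_length`, `clip_count` to column names in the file.
#'   `clip_count` may be `NA` if the table has no CLIP column.
#' @param log_transform If `TRUE`, length columns are raw nucleotide counts
#'   and are log2-transformed on ingestion (values < 2 nt become missing).
#'   If `FALSE` they are taken as already log2.
#' @return A `gene_universe`: a data frame with columns `symbol`,
#'   `log_expr`, `cds_len_log2`, `tx_len_log2`, `clip_count` plus a
#'   provenance attribute.
#' @export
read_gene_table <- function(path,
                            column_map = list(symbol = "symbol",
                                              log_expr = "logCPM",
                                              cds_length = "cds_length",
                                              tx_length = "tx_length",
                                              clip_count = "clip_count"),
                            log_transform = FALSE) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  required <- c("symbol", "log_expr", "cds_length", "tx_length")
  for (role in required) {
    col <- column_map[[role]]
    if (is.null(col) || !(col %in% names(raw))) {
      stop("column_map role '", role, "' names column '", col,
           "' which is absent from ", path, call. = FALSE)
    }
  }
  clip_col <- column_map[["clip_count"]]
  has_clip <- !is.null(clip_col) && !is.na(clip_col)
  if (has_clip && !(clip_col %in% names(raw))) {
    stop("column_map role 'clip_count' names column '", clip_col,
         "' which is absent from ", path, call. = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(
    symbol = normalize_symbols(raw[[column_map$symbol]]),
    log_expr = num(raw[[column_map$log_expr]]),
    cds_len_log2 = num(raw[[column_map$cds_length]]),
    tx_len_log2 = num(raw[[column_map$tx_length]]),
    clip_count = if (has_clip) num(raw[[clip_col]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  if (log_transform) {
    df$cds_len_log2 <- ifelse(!is.na(df$cds_len_log2) & df$cds_len_log2 >= 2,
                              log2(df$cds_len_log2), NA_real_)
    df$tx_len_log2 <- ifelse(!is.na(df$tx_len_log2) & df$tx_len_log2 >= 2,
                             log2(df$tx_len_log2), NA_real_)
  }
  # lengths must be positive on the log2 scale (>= 2 nt)
  df$cds_len_log2[!is.na(df$cds_len_log2) & df$cds_len_log2 <= 0] <- NA_real_
  df$tx_len_log2[!is.na(df$tx_len_log2) & df$tx_len_log2 <= 0] <- NA_real_
  df$clip_count[!is.na(df$clip_count) & df$clip_count < 0] <- NA_real_

  usable <- nzchar(df$symbol) & !is.na(df$log_expr)
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    message("read_gene_table: dropped ", n_dropped,
            " record(s) with missing symbol or unparseable expression")
  }
  df <- df[usable, , drop = FALSE]

  dup <- duplicated(df$symbol)
  if (any(dup)) {
    warning("read_gene_table: ", sum(dup),
            " duplicated symbol(s); keeping first occurrence", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("gene table '", path, "' yielded no usable records",
                           call. = FALSE)
  new_gene_universe(df, provenance = sprintf(
    "read %d records from %s (%d dropped, %d duplicates removed)",
    nrow(df), path, n_dropped, sum(dup)))
}

#' Write a gene universe back to TSV
#'
#' Numeric fields are written with full precision (15 significant digits) so
#' that a write/read cycle round-trips exactly.
#'
#' @param u A `gene_universe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(u, path) {
  stopifnot(inherits(u, "gene_universe"))
  out <- data.frame(
    symbol = u$symbol,
    logCPM = format(u$log_expr, digits = 15, trim = TRUE, scientific = FALSE),
    cds_length = format(u$cds_len_log2, digits = 15, trim = TRUE,
                        scientific = FALSE),
    tx_length = format(u$tx_len_log2, digits = 15, trim = TRUE,
                       scientific = FALSE),
    clip_count = format(u$clip_count, digits = 15, trim = TRUE,
                        scientific = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a gene universe
#'
#' Applies the filter cascade that defines an analysis universe: a strict
#' lower bound on log2 expression (brain-expressed genes are `log_expr > 2`),
#' optional requirements that coding-sequence and transcript lengths be
#' annotated, and an optional minimum CLIP tag count (the regression universe
#' keeps genes with at least one tag). Record order is preserved and the
#' provenance attribute gains one line per call with before/after counts.
#'
#' @param u A `gene_universe`.
#' @param min_log_expr Strict lower bound on `log_expr`, or `NULL` to skip.
#' @param require_cds_len,require_tx_len If `TRUE`, drop records whose
#'   length is missing.
#' @param min_clip_count Keep records with `clip_count >= min_clip_count`
#'   (missing counts are dropped), or `NULL` to skip.
#' @return The filtered `gene_universe`.
#' @export
filter_universe <- function(u, min_log_expr = NULL,
                            require_cds_len = FALSE, require_tx_len = FALSE,
                            min_clip_count = NULL) {
  stopifnot(inherits(u, "gene_universe"), nrow(u) > 0L)
  keep <- rep(TRUE, nrow(u))
  desc <- character()
  if (!is.null(min_log_expr)) {
    keep <- keep & u$log_expr > min_log_expr
    desc <- c(desc, sprintf("log_expr > %g", min_log_expr))
  }
  if (isTRUE(require_cds_len)) {
    keep <- keep & !is.na(u$cds_len_log2)
    desc <- c(desc, "cds length annotated")
  }
  if (isTRUE(require_tx_len)) {
    keep <- keep & !is.na(u$tx_len_log2)
    desc <- c(desc, "tx length annotated")
  }
  if (!is.null(min_clip_count)) {
    keep <- keep & !is.na(u$clip_count) & u$clip_count >= min_clip_count
    desc <- c(desc, sprintf("clip_count >= %g", min_clip_count))
  }
  out <- u[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("filter_universe: no records pass [",
         paste(desc, collapse = "; "), "]", call. = FALSE)
  }
  new_gene_universe(as.data.frame(out), provenance = c(
    attr(u, "provenance"),
    sprintf("filter [%s]: %d -> %d records",
            if (length(desc)) paste(desc, collapse = "; ") else "none",
            nrow(u), nrow(out))))
}

#' Take the top-n genes by a covariate
#'
#' Selects the `n` records with the largest values of a covariate (or of an
#' externally supplied weight vector, for the "highest sampling probability"
#' selection). Ties at the cutoff are broken by universe order, first come
#' first kept.
#'
#' @param u A `gene_universe`.
#' @param covariate One of `"log_expr"`, `"cds_len_log2"`, `"tx_len_log2"`,
#'   or `"weight"`.
#' @param n Number of genes to select.
#' @param weights A [density_ratio_weights()] result, required when
#'   `covariate = "weight"`.
#' @return A [gene_set()] of exactly `n` symbols.
#' @export
select_top_by <- function(u, covariate = c("log_expr", "cds_len_log2",
                                           "tx_len_log2", "weight"),
                          n, weights = NULL) {
  stopifnot(inherits(u, "gene_universe"))
  covariate <- match.arg(covariate)
  if (n > nrow(u)) {
    stop("select_top_by: n = ", n, " exceeds universe size ", nrow(u),
         call. = FALSE)
  }
  if (covariate == "weight") {
    if (is.null(weights)) stop("covariate 'weight' requires a weights table",
                               call. = FALSE)
    vals <- weights$probability[match(u$symbol, weights$symbol)]
  } else {
    vals <- u[[covariate]]
  }
  if (anyNA(vals)) {
    stop("select_top_by: covariate '", covariate,
         "' is missing for some records; filter first", call. = FALSE)
  }
  ord <- order(vals, decreasing = TRUE, method = "radix")
  gene_set(u$symbol[sort(ord[seq_len(n)])],
           name = sprintf("top_%d_by_%s", n, covariate))
}
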