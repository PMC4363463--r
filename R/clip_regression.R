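# Ordinary least squares models of log2 CLIP tag depth on transcript
# abundance and length, reproducing the structure of the tag-depth bias
# table (five model formulas at two tag-count filters).

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, length >= 3, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_correlation: constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Ordinary least squares fit
#'
#' Fits `response ~ covariates` with an intercept by least squares and
#' returns the coefficient vector, the coefficient of determination
#' `r^2 = 1 - SSE/SST`, and the overall F-test p-value with
#' `(p, n - p - 1)` degrees of freedom.
#'
#' @param response Numeric response vector.
#' @param covariates Data frame or matrix of covariate columns (named).
#' @param response_name Label for the response in the returned object.
#' @return A `regression_fit` list: `response_name`, `covariate_names`,
#'   `coefficients` (intercept first), `r_squared`, `model_p`, `n`.
#' @export
ols_fit <- function(response, covariates, response_name = "response") {
  X <- as.data.frame(covariates)
  stopifnot(nrow(X) == length(response))
  p <- ncol(X)
  n <- length(response)
  if (n <= p + 1L) stop("ols_fit: need n > p + 1", call. = FALSE)
  fit <- stats::lm(response ~ ., data = X)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("ols_fit: design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  model_p <- stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                       lower.tail = FALSE)
  structure(list(response_name = response_name,
                 covariate_names = names(X),
                 coefficients = stats::coef(fit),
                 std_errors = sm$coefficients[, "Std. Error"],
                 r_squared = sm$r.squared,
                 model_p = model_p,
                 n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s ~ %s: n=%d, r2=%.3f, p=%.3g\n",
              x$response_name, paste(x$covariate_names, collapse = " + "),
              x$n, x$r_squared, x$model_p))
  invisible(x)
}

TABLE1_FORMULAS <- list(
  abundance = "log_expr",
  cds_length = "cds_len_log2",
  tx_length = "tx_len_log2",
  abundance_cds = c("log_expr", "cds_len_log2"),
  abundance_tx = c("log_expr", "tx_len_log2"),
  full = c("log_expr", "cds_len_log2", "tx_len_log2")
)

#' Tag-depth bias regression table
#'
#' For each minimum tag-count filter, restricts the universe to genes with
#' `clip_count >= filter` and fits six OLS models of `log2(clip_count)`:
#' abundance alone, each length alone, abundance plus each length (the
#' published table's "abundance + length (either)" row is ambiguous about
#' which length, so both are reported), and the full three-covariate model.
#' Counts are guaranteed >= 1 by the filter, so no pseudocount is needed for
#' the log transform.
#'
#' @param universe A `gene_universe` with expression, both lengths and CLIP
#'   counts present.
#' @param clip_filters Numeric vector of minimum tag counts; the default
#'   `c(1, 17)` reproduces the "at least one tag" and "more than 16 tags"
#'   universes.
#' @return A `table1_result`: a data frame with one row per (filter,
#'   formula): `filter`, `formula`, `n`, `r_squared`, `model_p`; the list of
#'   `regression_fit`s is attached as attribute `fits`.
#' @export
table1 <- function(universe, clip_filters = c(1, 17)) {
  stopifnot(inherits(universe, "gene_universe"))
  rows <- list()
  fits <- list()
  for (f in clip_filters) {
    uf <- filter_universe(universe, require_cds_len = TRUE,
                          require_tx_len = TRUE, min_clip_count = f)
    y <- log2(uf$clip_count)
    for (fname in names(TABLE1_FORMULAS)) {
      covs <- TABLE1_FORMULAS[[fname]]
      fit <- ols_fit(y, as.data.frame(uf)[, covs, drop = FALSE],
                     response_name = "log2_clip_count")
      key <- sprintf("min%g_%s", f, fname)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(filter = f, formula = fname, n = fit$n,
                                r_squared = fit$r_squared,
                                model_p = fit$model_p,
                                stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            fits = fits, class = c("table1_result", "data.frame"))
}
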