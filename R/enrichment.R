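# Exact right-tail overlap tests between gene sets, odds ratios with
# Woolf confidence intervals, and summaries of resampling null
# distributions.

#' Build a 2x2 overlap contingency table
#'
#' Cells: `k` genes in both sets, `a = |A| - k`, `b = |B| - k`, and
#' `d = N - |A| - |B| + k` in neither. When a universe is supplied, both sets
#' are first intersected with it and `N` is the universe size; otherwise `N`
#' is taken as given (the "genome size of 20,000" convention for candidate
#' lists of unknown provenance).
#'
#' @param setA,setB [gene_set()]s.
#' @param universe_size Universe size `N`, used when `universe` is `NULL`.
#' @param universe Optional `gene_universe`; overrides `universe_size`.
#' @return A `contingency_table` list with fields `k`, `a`, `b`, `d`, `N`.
#' @export
make_contingency <- function(setA, setB, universe_size = NULL,
                             universe = NULL) {
  stopifnot(inherits(setA, "gene_set"), inherits(setB, "gene_set"))
  a_sym <- setA$symbols
  b_sym <- setB$symbols
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "gene_universe"))
    a_sym <- intersect(a_sym, universe$symbol)
    b_sym <- intersect(b_sym, universe$symbol)
    N <- nrow(universe)
  } else {
    if (is.null(universe_size)) {
      stop("make_contingency: supply either a universe or universe_size",
           call. = FALSE)
    }
    N <- as.integer(universe_size)
  }
  k <- length(intersect(a_sym, b_sym))
  union_size <- length(a_sym) + length(b_sym) - k
  if (N < union_size) {
    stop("make_contingency: universe size ", N, " is smaller than |A union B| = ",
         union_size, call. = FALSE)
  }
  structure(list(k = k, a = length(a_sym) - k, b = length(b_sym) - k,
                 d = N - union_size, N = N),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> k=", x$k, " a=", x$a, " b=", x$b, " d=", x$d,
      " (N=", x$N, ")\n", sep = "")
  invisible(x)
}

#' Exact right-tail overlap probability
#'
#' The one-sided Fisher exact test: the probability under the hypergeometric
#' null (margins fixed) of an overlap at least as large as observed,
#' `P(X >= k)`. Terms are accumulated from log binomial coefficients for
#' numeric stability; no approximation is involved.
#'
#' @param t A `contingency_table`.
#' @return The right-tail probability, in `(0, 1]`.
#' @export
fisher_right_tail <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  sizeA <- t$k + t$a
  sizeB <- t$k + t$b
  N <- t$N
  j_max <- min(sizeA, sizeB)
  j_min <- max(0L, sizeA + sizeB - N)
  if (t$k <= j_min) return(1)
  j <- t$k:j_max
  logp <- lchoose(sizeA, j) + lchoose(N - sizeA, sizeB - j) -
    lchoose(N, sizeB)
  min(1, sum(exp(logp)))
}

#' Odds ratio with 95% confidence interval
#'
#' Sample (cross-product) odds ratio `(k*d)/(a*b)`. If any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells. The 95% CI is the
#' Woolf log interval `exp(log(OR) +/- 1.96 * sqrt(1/k + 1/a + 1/b + 1/d))`
#' on the (possibly corrected) cells. This is the transparent closed-form
#' estimate, not the conditional-MLE estimate some software reports; the two
#' differ modestly when all cells are large.
#'
#' @param t A `contingency_table`.
#' @return List with `odds_ratio` and `ci95` (length-2 numeric, lower/upper).
#' @export
odds_ratio_ci <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$k, t$a, t$b, t$d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(odds_ratio = or, ci95 = ci)
}

#' Overlap enrichment of one set against another
#'
#' Convenience wrapper building the contingency table and computing the
#' exact right-tail p-value, odds ratio and 95% CI in one call.
#'
#' @inheritParams make_contingency
#' @return An `enrichment_result` list: `table`, `p_right`, `odds_ratio`,
#'   `ci95`, plus the set names.
#' @export
enrich_test <- function(setA, setB, universe_size = NULL, universe = NULL) {
  tab <- make_contingency(setA, setB, universe_size = universe_size,
                          universe = universe)
  orci <- odds_ratio_ci(tab)
  structure(list(set_a = setA$name, set_b = setB$name, table = tab,
                 p_right = fisher_right_tail(tab),
                 odds_ratio = orci$odds_ratio, ci95 = orci$ci95),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s vs %s: k=%d, p_right=%.3g, OR=%.3g [%.3g, %.3g]\n",
              x$set_a, x$set_b, x$table$k, x$p_right, x$odds_ratio,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Summarize a resampling null distribution
#'
#' Runs one right-tail overlap test per replicate set against the candidate
#' list within the universe and summarizes the resulting p-value
#' distribution: the fraction nominally significant (`p < 0.05`) and the
#' fraction at least as significant as the target set's own p-value.
#'
#' @param replicate_sets List of [gene_set()]s (matched null draws).
#' @param candidate The candidate [gene_set()] being tested.
#' @param universe The `gene_universe` defining `N`.
#' @param target_result The target set's [enrich_test()] result against the
#'   same candidate and universe.
#' @return A `null_summary` list: `p_values`, `frac_nominal`,
#'   `frac_beats_target`, `target_p`.
#' @export
null_summary <- function(replicate_sets, candidate, universe, target_result) {
  stopifnot(length(replicate_sets) >= 1L,
            inherits(target_result, "enrichment_result"))
  p <- vapply(replicate_sets, function(s) {
    fisher_right_tail(make_contingency(s, candidate, universe = universe))
  }, numeric(1))
  structure(list(p_values = p,
                 frac_nominal = mean(p < 0.05),
                 frac_beats_target = mean(p <= target_result$p_right),
                 target_p = target_result$p_right),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "<null_summary> %d replicates: frac p<0.05 = %.3f, frac <= target p (%.3g) = %.3f\n",
    length(x$p_values), x$frac_nominal, x$target_p, x$frac_beats_target))
  invisible(x)
}

#' Tabulate enrichment results as a data frame
#'
#' One row per result, with the four cells, `p_right`, odds ratio and CI
#' bounds; ready for TSV export.
#'
#' @param results List of `enrichment_result`s (or a single one).
#' @return A data frame.
#' @export
enrichment_table <- function(results) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(set_a = r$set_a, set_b = r$set_b, k = r$table$k, a = r$table$a,
               b = r$table$b, d = r$table$d, N = r$table$N,
               p_right = r$p_right, odds_ratio = r$odds_ratio,
               ci95_lower = r$ci95[1], ci95_upper = r$ci95[2],
               stringsAsFactors = FALSE)
  }))
}
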