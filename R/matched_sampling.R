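# Matched sampling: density-ratio weights over the universe and weighted
# sampling without replacement of replicate gene sets whose covariate
# distribution matches a target set's.

RATIO_FLOOR <- 1e-12

#' Derive a per-stage or per-replicate seed
#'
#' Splittable-seed construction: a fixed linear-congruential hash of
#' `(seed, stream)` modulo the Mersenne prime 2^31 - 1. Replicate r of a
#' sampling plan uses `derive_seed(plan_seed, r)`, so replicates can be
#' generated in any order with identical results and all derived seeds stay
#' within R's 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param stream Non-negative integer stream index.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  # all intermediates < 2^53, exact in doubles
  x <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  x <- (x + (as.numeric(stream) %% 2147483647) * 16807 + 1) %% 2147483647
  as.integer(x %% 2147483646 + 1)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Density-ratio sampling weights
#'
#' For every gene in the universe, computes the ratio of a kernel density
#' estimate fit on the target set's covariates to one fit on the whole
#' universe's covariates, evaluated at that gene's covariate point, and
#' normalizes the ratios into sampling probabilities. Genes whose covariates
#' look like the target's receive high probability; sampling with these
#' weights yields sets matched to the target's covariate distribution.
#'
#' Modes: `"expression"` (1D on `log_expr`), `"cds_length"` (1D on
#' `cds_len_log2`), `"both_2d"` (product kernel on both). Raw ratios below
#' `1e-12` are floored there before normalization so that every gene keeps a
#' nonzero probability and large without-replacement draws cannot stall.
#'
#' @param universe A `gene_universe` with the required covariates present
#'   for every record.
#' @param target A [gene_set()]; at least 2 members must be in the universe.
#' @param mode Matching mode, see above.
#' @param bandwidths Optional bandwidth override: a single value for 1D
#'   modes, a pair for `both_2d`. Applied to both the target and universe
#'   estimates.
#' @return A data frame of class `weight_vector` with columns `symbol`,
#'   `raw_ratio`, `probability` (non-negative, summing to 1), aligned to the
#'   universe; attributes `mode` and `bandwidths` (target and universe
#'   estimates' bandwidths).
#' @export
density_ratio_weights <- function(universe, target,
                                  mode = c("expression", "cds_length",
                                           "both_2d"),
                                  bandwidths = NULL) {
  stopifnot(inherits(universe, "gene_universe"), inherits(target, "gene_set"))
  mode <- match.arg(mode)
  in_target <- universe$symbol %in% target$symbols
  if (sum(in_target) < 2L) {
    stop("density_ratio_weights: target has ", sum(in_target),
         " member(s) in the universe; need >= 2", call. = FALSE)
  }
  cov_cols <- switch(mode,
    expression = "log_expr",
    cds_length = "cds_len_log2",
    both_2d = c("log_expr", "cds_len_log2"))
  for (cc in cov_cols) {
    if (anyNA(universe[[cc]])) {
      stop("density_ratio_weights: covariate '", cc,
           "' missing for some records; filter the universe first",
           call. = FALSE)
    }
  }
  if (mode == "both_2d") {
    f_t <- kde_2d(universe$log_expr[in_target],
                  universe$cds_len_log2[in_target], bandwidths = bandwidths)
    f_u <- kde_2d(universe$log_expr, universe$cds_len_log2,
                  bandwidths = bandwidths)
    dt <- kde_eval(f_t, universe$log_expr, universe$cds_len_log2)
    du <- kde_eval(f_u, universe$log_expr, universe$cds_len_log2)
  } else {
    v <- universe[[cov_cols]]
    f_t <- kde_1d(v[in_target], bandwidth = bandwidths)
    f_u <- kde_1d(v, bandwidth = bandwidths)
    dt <- kde_eval(f_t, v)
    du <- kde_eval(f_u, v)
  }
  ratio <- dt / du
  ratio[!is.finite(ratio) | ratio < RATIO_FLOOR] <- RATIO_FLOOR
  if (any(!is.finite(ratio))) {
    stop("density_ratio_weights: non-finite ratios after flooring",
         call. = FALSE)
  }
  prob <- ratio / sum(ratio)
  structure(
    data.frame(symbol = universe$symbol, raw_ratio = ratio,
               probability = prob, stringsAsFactors = FALSE),
    mode = mode,
    bandwidths = list(target = f_t$bw, universe = f_u$bw),
    class = c("weight_vector", "data.frame"))
}

#' Export a weight vector as TSV
#'
#' Columns `symbol`, `raw_ratio`, `probability`; one row per universe gene.
#'
#' @param weights A `weight_vector`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_vector"))
  utils::write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Weighted sampling without replacement of one matched set
#'
#' Draws exactly `n` distinct genes with probabilities proportional to the
#' weight vector, using the exponential-keys scheme: each pool gene gets key
#' `-log(U_i) / w_i` (an Exponential(w_i) variate) and the `n` smallest keys
#' win. This is distributionally identical to sequential weighted draws
#' without replacement. Genes in `exclude` are removed from the pool but the
#' remaining genes keep their original weights (renormalization is implicit),
#' matching the "same probabilities, smaller pool" exclusion convention.
#'
#' @param universe A `gene_universe`.
#' @param weights A [density_ratio_weights()] result aligned to `universe`.
#' @param n Number of genes to draw.
#' @param exclude Optional [gene_set()] removed from the pool.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A [gene_set()] of exactly `n` symbols, none in `exclude`.
#' @export
sample_matched_set <- function(universe, weights, n, exclude = NULL,
                               seed = 1L) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(weights, "weight_vector"))
  if (!identical(universe$symbol, weights$symbol)) {
    stop("sample_matched_set: weights are not aligned to this universe",
         call. = FALSE)
  }
  pool <- rep(TRUE, nrow(universe))
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "gene_set"))
    pool <- pool & !(universe$symbol %in% exclude$symbols)
  }
  pool <- pool & weights$probability > 0
  n_pool <- sum(pool)
  if (n > n_pool) {
    stop("sample_matched_set: need ", n, " genes but pool has only ", n_pool,
         " (short by ", n - n_pool, ")", call. = FALSE)
  }
  syms <- universe$symbol[pool]
  w <- weights$probability[pool]
  keys <- with_seed(seed, stats::rexp(n_pool) / w)
  picked <- sort(order(keys, method = "radix")[seq_len(n)])
  gene_set(syms[picked], name = sprintf("matched_n%d_seed%d", n, seed))
}

#' Sampling plan for replicate draws
#'
#' @param mode Matching mode as in [density_ratio_weights()].
#' @param n_per_set Genes per replicate set.
#' @param n_replicates Number of replicate sets.
#' @param exclude Optional [gene_set()] excluded from the pool (the
#'   "non-target genes only" convention).
#' @param seed Base seed; replicate `r` uses [derive_seed()]`(seed, r)`.
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(mode = c("expression", "cds_length", "both_2d"),
                          n_per_set, n_replicates, exclude = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_per_set >= 1L, n_replicates >= 1L)
  structure(list(mode = mode, n_per_set = as.integer(n_per_set),
                 n_replicates = as.integer(n_replicates), exclude = exclude,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Draw replicate matched gene sets
#'
#' Repeats [sample_matched_set()] `plan$n_replicates` times with per-replicate
#' seeds derived from `plan$seed`. Weights are computed once and shared by
#' all replicates.
#'
#' @param universe A `gene_universe`.
#' @param weights Weights aligned to `universe`.
#' @param plan A [sampling_plan()].
#' @return List of [gene_set()]s of length `plan$n_replicates`.
#' @export
sample_replicates <- function(universe, weights, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  lapply(seq_len(plan$n_replicates), function(r) {
    s <- sample_matched_set(universe, weights, plan$n_per_set,
                            exclude = plan$exclude,
                            seed = derive_seed(plan$seed, r))
    s$name <- sprintf("replicate_%04d", r)
    s
  })
}

#' Export replicate sets as a long-format TSV
#'
#' Columns `replicate_id`, `symbol`.
#'
#' @param replicates List of [gene_set()]s from [sample_replicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(replicates, path) {
  df <- do.call(rbind, lapply(seq_along(replicates), function(r) {
    data.frame(replicate_id = r, symbol = replicates[[r]]$symbols,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
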