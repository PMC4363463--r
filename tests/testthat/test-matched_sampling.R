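test_that("density_ratio_weights is uniform when target equals universe", {
  set.seed(21)
  u <- make_universe(rnorm(300, 5, 1.5), cds = rnorm(300, 10, 1))
  target <- gene_set(u$symbol, "everything")
  for (mode in c("expression", "cds_length", "both_2d")) {
    w <- density_ratio_weights(u, target, mode = mode)
    expect_equal(w$probability, rep(1 / 300, 300), tolerance = 1e-6)
    expect_equal(sum(w$probability), 1, tolerance = 1e-9)
    expect_true(all(w$probability >= 0))
  }
})

test_that("weights upweight the mode the target was drawn from", {
  set.seed(22)
  lower <- rnorm(250, 0, 0.5)
  upper <- rnorm(250, 4, 0.5)
  u <- make_universe(c(lower, upper))
  target <- gene_set(u$symbol[251:350], "upper_mode")
  w <- density_ratio_weights(u, target, mode = "expression")
  expect_gt(mean(w$probability[251:500]), mean(w$probability[1:250]))
})

test_that("weighted mean under the weights matches a shifted target's mean", {
  # importance-weighting oracle: universe N(5, 1.5), 50-gene target drawn
  # from the +2-shifted distribution via rejection-free importance draw
  set.seed(23)
  expr <- rnorm(500, 5, 1.5)
  u <- make_universe(expr)
  shift_w <- dnorm(expr, 7, 1.5) / dnorm(expr, 5, 1.5)
  idx <- sample(500, 50, prob = shift_w)
  target <- gene_set(u$symbol[idx], "shifted")
  w <- density_ratio_weights(u, target, mode = "expression")
  target_mean <- mean(expr[idx])
  expect_lt(abs(sum(w$probability * expr) - target_mean), 0.2)
})

test_that("weights require covariates and >= 2 in-universe target members", {
  u <- make_universe(c(1, 2, 3), cds = c(10, NA, 11))
  expect_error(density_ratio_weights(u, gene_set("G0001"), "expression"),
               ">= 2")
  expect_error(density_ratio_weights(u, gene_set(u$symbol), "cds_length"),
               "missing")
})

test_that("sample_matched_set honors degenerate weights, pool size, exclusions", {
  u <- make_universe(c(1, 2, 3))
  w <- make_weights(u, c(1, 0, 0))
  for (s in c(1, 7, 99)) {
    expect_equal(sample_matched_set(u, w, 1, seed = s)$symbols, u$symbol[1])
  }

  # n = pool size returns the whole pool regardless of weights
  w <- make_weights(u, c(0.9, 0.05, 0.05))
  expect_setequal(sample_matched_set(u, w, 3, seed = 1)$symbols, u$symbol)

  # exclusion shrinks the pool; shortfall is reported
  excl <- gene_set(u$symbol[1], "excl")
  expect_setequal(sample_matched_set(u, w, 2, exclude = excl, seed = 1)$symbols,
                  u$symbol[2:3])
  expect_error(sample_matched_set(u, w, 3, exclude = excl, seed = 1),
               "short by 1")

  # misaligned weights are refused
  u2 <- make_universe(c(1, 2))
  expect_error(sample_matched_set(u2, w, 1, seed = 1), "not aligned")
})

test_that("exponential-keys sampling matches sequential-draw enumeration", {
  # Oracle: enumerate all ordered 2-draws from weights (.5, .3, .2) and sum
  # the sequential without-replacement probabilities for 'gene 1 included'.
  w <- c(0.5, 0.3, 0.2)
  inc1 <- 0
  for (first in 1:3) {
    rest <- setdiff(1:3, first)
    for (second in rest) {
      pr <- w[first] * w[second] / (1 - w[first])
      if (1 %in% c(first, second)) inc1 <- inc1 + pr
    }
  }
  u <- make_universe(c(1, 2, 3))
  wv <- make_weights(u, w)
  n_seeds <- 20000
  hits <- 0L
  for (s in seq_len(n_seeds)) {
    if ("G0001" %in% sample_matched_set(u, wv, 2, seed = s)$symbols) {
      hits <- hits + 1L
    }
  }
  mc_se <- sqrt(inc1 * (1 - inc1) / n_seeds)
  expect_lt(abs(hits / n_seeds - inc1), 3 * mc_se)
})

test_that("replicate draws are deterministic, sized, and exclusion-sound", {
  set.seed(31)
  u <- make_universe(rnorm(400, 5, 1.5))
  target <- gene_set(u$symbol[sample(400, 60)], "t")
  w <- density_ratio_weights(u, target, mode = "expression")
  plan <- sampling_plan("expression", n_per_set = 50, n_replicates = 20,
                        exclude = target, seed = 99L)
  reps1 <- sample_replicates(u, w, plan)
  reps2 <- sample_replicates(u, w, plan)
  expect_identical(lapply(reps1, `[[`, "symbols"),
                   lapply(reps2, `[[`, "symbols"))
  expect_true(all(vapply(reps1, length, integer(1)) == 50L))
  for (r in reps1) expect_length(intersect(r$symbols, target$symbols), 0L)
  # distinct replicates are distinct draws
  expect_false(identical(reps1[[1]]$symbols, reps1[[2]]$symbols))
})

test_that("derived seeds stay in 32-bit range and separate streams", {
  s <- vapply(0:5000, function(r) derive_seed(123456789, r), integer(1))
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_equal(length(unique(s)), length(s))
  expect_identical(derive_seed(42, 7), derive_seed(42, 7))
  expect_false(derive_seed(42, 7) == derive_seed(43, 7))
})

test_that("matched replicates track the target's covariate distribution", {
  # Matching property (1D): pooled replicate covariates are closer to the
  # target distribution (KS distance) than the universe is.
  set.seed(33)
  n <- 1500
  expr <- rnorm(n, 5, 1.5)
  u <- make_universe(expr)
  shift_w <- dnorm(expr, 6.5, 1.5) / dnorm(expr, 5, 1.5)
  idx <- sample(n, 150, prob = shift_w)
  target <- gene_set(u$symbol[idx], "t")
  w <- density_ratio_weights(u, target, mode = "expression")
  reps <- sample_replicates(u, w, sampling_plan("expression", 150, 100,
                                                seed = 5L))
  pooled <- unlist(lapply(reps, function(r) expr[u$symbol %in% r$symbols]))
  ks <- function(a, b) suppressWarnings(ks.test(a, b)$statistic)
  expect_lt(ks(pooled, expr[idx]), ks(expr, expr[idx]))
})
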