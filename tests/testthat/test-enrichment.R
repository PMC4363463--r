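# Exact-choose enumeration oracle for the hypergeometric right tail.
enum_right_tail <- function(k, sizeA, sizeB, N) {
  j <- max(0, sizeA + sizeB - N):min(sizeA, sizeB)
  pmf <- choose(sizeA, j) * choose(N - sizeA, sizeB - j) / choose(N, sizeB)
  sum(pmf[j >= k])
}

set_of <- function(ids, name = "s") gene_set(sprintf("G%03d", ids), name)

test_that("make_contingency builds the four cells and restricts to a universe", {
  A <- set_of(1:5); B <- set_of(3:6)
  t <- make_contingency(A, B, universe_size = 20)
  expect_equal(unclass(t)[c("k", "a", "b", "d", "N")],
               list(k = 3L, a = 2L, b = 1L, d = 14L, N = 20L))

  expect_equal(make_contingency(set_of(1:3), set_of(4:6),
                                universe_size = 10)$k, 0L)

  # symbols outside the universe are silently restricted to it:
  # universe G001..G010; A = {1..5, 90, 91}, B = {4..6, 92, 93}
  u <- make_universe(rnorm(10), symbols = sprintf("G%03d", 1:10))
  t <- make_contingency(set_of(c(1:5, 90, 91)), set_of(c(4:6, 92, 93)),
                        universe = u)
  expect_equal(unclass(t)[c("k", "a", "b", "d", "N")],
               list(k = 2L, a = 3L, b = 1L, d = 4L, N = 10L))

  expect_error(make_contingency(A, B, universe_size = 5), "smaller")
})

test_that("fisher_right_tail matches exact enumeration on hand cases", {
  # N=20, |A|=5, |B|=4, k=3 -> 155/4845 (two-term tail)
  t <- make_contingency(set_of(1:5), set_of(3:6), universe_size = 20)
  expect_equal(fisher_right_tail(t), 155 / 4845, tolerance = 1e-12)
  expect_equal(fisher_right_tail(t), enum_right_tail(3, 5, 4, 20),
               tolerance = 1e-12)

  # N=10, |A|=|B|=3, k=3 -> single term 1/C(10,3)
  t <- make_contingency(set_of(1:3), set_of(1:3), universe_size = 10)
  expect_equal(fisher_right_tail(t), 1 / 120, tolerance = 1e-14)

  # k = 0 -> whole tail, p = 1 exactly
  t <- make_contingency(set_of(1:3), set_of(4:6), universe_size = 10)
  expect_identical(fisher_right_tail(t), 1)

  # margins forcing a positive minimum overlap still give p = 1 at that k
  t <- make_contingency(set_of(1:8), set_of(5:10), universe_size = 12)
  expect_equal(fisher_right_tail(t),
               enum_right_tail(t$k, 8, 6, 12), tolerance = 1e-12)
})

test_that("fisher_right_tail is monotone in k and the pmf sums to 1", {
  N <- 50L; sizeA <- 18L; sizeB <- 11L
  mk <- function(k) structure(list(k = k, a = sizeA - k, b = sizeB - k,
                                   d = N - sizeA - sizeB + k, N = N),
                              class = "contingency_table")
  ks <- 0:sizeB
  p <- vapply(ks, function(k) fisher_right_tail(mk(k)), numeric(1))
  expect_true(all(diff(p) < 0))
  # implied pmf sums to 1
  pmf <- c(-diff(p), p[length(p)])
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
})

test_that("universe restriction equals pre-intersection with N = |U|", {
  set.seed(41)
  u <- make_universe(rnorm(50), symbols = sprintf("G%03d", 1:50))
  A <- set_of(sample(80, 20)); B <- set_of(sample(80, 25))
  via_universe <- fisher_right_tail(make_contingency(A, B, universe = u))
  A2 <- gene_set(intersect(A$symbols, u$symbol), "A2")
  B2 <- gene_set(intersect(B$symbols, u$symbol), "B2")
  direct <- fisher_right_tail(make_contingency(A2, B2, universe_size = 50))
  expect_equal(via_universe, direct, tolerance = 1e-14)
})

test_that("odds_ratio_ci computes the cross-product estimate and Woolf CI", {
  mk <- function(k, a, b, d) structure(list(k = k, a = a, b = b, d = d,
                                            N = k + a + b + d),
                                       class = "contingency_table")
  r <- odds_ratio_ci(mk(3, 2, 1, 13))
  expect_equal(r$odds_ratio, 19.5, tolerance = 1e-12)
  se <- sqrt(1 / 3 + 1 / 2 + 1 / 1 + 1 / 13)
  expect_equal(r$ci95, exp(log(19.5) + c(-1, 1) * 1.96 * se),
               tolerance = 1e-12)

  # balanced table: OR = 1, CI symmetric about 1 on the log scale
  r <- odds_ratio_ci(mk(2, 2, 2, 2))
  expect_equal(r$odds_ratio, 1, tolerance = 1e-12)
  expect_equal(log(r$ci95[1]), -log(r$ci95[2]), tolerance = 1e-12)

  # zero cell: Haldane-Anscombe correction on all cells
  r <- odds_ratio_ci(mk(0, 5, 4, 11))
  expect_equal(r$odds_ratio, (0.5 * 11.5) / (5.5 * 4.5), tolerance = 1e-12)
  expect_lt(r$odds_ratio, 1)

  # CI brackets the OR when no cell is zero
  r <- odds_ratio_ci(mk(6, 10, 8, 40))
  expect_true(r$ci95[1] <= r$odds_ratio && r$odds_ratio <= r$ci95[2])
})

test_that("enrich_test agrees with fisher.test's one-sided p", {
  set.seed(43)
  for (i in 1:10) {
    N <- sample(50:500, 1)
    u <- make_universe(rnorm(N), symbols = sprintf("X%04d", 1:N))
    A <- gene_set(u$symbol[sample(N, sample(5:40, 1))], "A")
    B <- gene_set(u$symbol[sample(N, sample(5:40, 1))], "B")
    res <- enrich_test(A, B, universe = u)
    t <- res$table
    m <- matrix(c(t$k, t$a, t$b, t$d), 2)
    expect_equal(res$p_right,
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("null_summary summarizes replicate p-value distributions", {
  set.seed(47)
  N <- 2000
  u <- make_universe(rnorm(N, 5, 1.5), symbols = sprintf("X%04d", 1:N))
  candidate <- gene_set(u$symbol[sample(N, 200)], "cand")
  target <- gene_set(u$symbol[sample(N, 200)], "target")
  tr <- enrich_test(target, candidate, universe = u)

  # all replicates identical to the target -> frac_beats_target = 1
  ns <- null_summary(rep(list(target), 5), candidate, u, tr)
  expect_equal(ns$frac_beats_target, 1)
  expect_length(ns$p_values, 5L)

  # calibration under the null: uniform random replicates vs a uniform
  # random candidate give frac_nominal near 0.05 (the exact test is
  # slightly conservative, so test the upper side plus a generous band)
  R <- 400
  reps <- lapply(seq_len(R), function(r) {
    gene_set(u$symbol[sample(N, 200)], sprintf("r%d", r))
  })
  ns <- null_summary(reps, candidate, u, tr)
  expect_lt(abs(ns$frac_nominal - 0.05), 3 * sqrt(0.05 * 0.95 / R) + 0.01)
})

test_that("enrichment_table flattens results for export", {
  u <- make_universe(rnorm(30), symbols = sprintf("Y%03d", 1:30))
  res <- enrich_test(gene_set(u$symbol[1:10], "A"),
                     gene_set(u$symbol[5:20], "B"), universe = u)
  df <- enrichment_table(list(res, res))
  expect_equal(nrow(df), 2L)
  expect_named(df, c("set_a", "set_b", "k", "a", "b", "d", "N", "p_right",
                     "odds_ratio", "ci95_lower", "ci95_upper"))
})
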