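# Group comparison: Kruskal-Wallis against exact and permutation oracles,
# extraction geometry, normality screening.

test_that("H matches the direct rank formula on the textbook instance", {
  gs <- grouped_samples(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  kw <- kruskal_wallis(gs)
  # 12/(9*10) * (3*(2-5)^2 + 3*(5-5)^2 + 3*(8-5)^2) = 7.2
  expect_equal(kw$h_statistic, 7.2, tolerance = 1e-12)
  expect_identical(kw$df, 2L)
  expect_false(kw$tie_corrected)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against the reference implementation
  ref <- stats::kruskal.test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$h_statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("degenerate all-tied input returns H = 0, p = 1", {
  gs <- grouped_samples(list(a = c(2, 2), b = c(2, 2), c = c(2, 2, 2)))
  kw <- kruskal_wallis(gs)
  expect_identical(kw$h_statistic, 0)
  expect_identical(kw$p_value, 1)
  expect_true(kw$tie_corrected)
})

test_that("tie correction matches the reference implementation on tied data", {
  set.seed(14)
  for (i in 1:10) {
    groups <- lapply(1:3, function(g) sample(1:4, 6, replace = TRUE) + g * 0.5)
    kw <- kruskal_wallis(grouped_samples(groups))
    ref <- stats::kruskal.test(groups)
    expect_equal(kw$h_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("chi-square p agrees with a 1e5-draw permutation oracle", {
  set.seed(7)
  x <- list(rnorm(4), rnorm(4, 0.8), rnorm(4, 1.6))
  kw <- kruskal_wallis(grouped_samples(x))
  pooled <- unlist(x)
  r <- rank(pooled)
  n <- length(r)
  h_of <- function(rr) {
    rbar <- c(mean(rr[1:4]), mean(rr[5:8]), mean(rr[9:12]))
    12 / (n * (n + 1)) * sum(4 * (rbar - (n + 1) / 2)^2)
  }
  set.seed(8)
  draws <- replicate(1e5, h_of(sample(r)))
  p_perm <- mean(draws >= kw$h_statistic - 1e-12)
  # chi-square is an approximation at N = 12; agreement to ~0.02 plus the
  # ~0.005 Monte-Carlo half-width is what the asymptotics support here
  expect_lt(abs(kw$p_value - p_perm), 0.025)
})

test_that("H is invariant to monotone transforms and group relabeling", {
  set.seed(9)
  groups <- lapply(1:4, function(g) rnorm(5, g * 0.5))
  kw <- kruskal_wallis(grouped_samples(groups))
  kw_exp <- kruskal_wallis(grouped_samples(lapply(groups, exp)))
  expect_equal(kw$h_statistic, kw_exp$h_statistic, tolerance = 1e-12)
  kw_rev <- kruskal_wallis(grouped_samples(rev(groups)))
  expect_equal(kw$h_statistic, kw_rev$h_statistic, tolerance = 1e-12)
})

test_that("p decreases as group separation grows (common random numbers)", {
  set.seed(15)
  base <- lapply(1:3, function(i) rnorm(5))
  p_at <- function(d) {
    shifted <- Map(function(x, i) x + (i - 1) * d, base, 1:3)
    kruskal_wallis(grouped_samples(shifted))$p_value
  }
  ps <- vapply(c(0.2, 1, 3), p_at, numeric(1L))
  expect_true(all(diff(ps) < 0))
})

test_that("extract_at_frequency picks the nearest grid point", {
  ds <- generate_vt_dataset(noise = noise_model(0.02, 0.02, 3, seed = 6))
  gs <- extract_at_frequency(ds, 433e6, "permittivity")
  expect_lte(abs(gs$frequency_hz - 433e6), 4.5e6)  # 9 MHz spacing
  expect_false(gs$off_grid)
  expect_length(gs$groups, 6L)
  expect_true(all(vapply(gs$groups, length, integer(1L)) == 3L))
  # exact on-grid request
  gs2 <- extract_at_frequency(ds, ds$grid$freqs_hz[50], "conductivity")
  expect_identical(gs2$frequency_hz, ds$grid$freqs_hz[50])
  # on a uniform grid every in-range request is within half a spacing of
  # some point; only an out-of-range request can be genuinely off-grid
  expect_warning(gs3 <- extract_at_frequency(ds, 1.02e9, "permittivity"),
                 "half the grid spacing")
  expect_true(gs3$off_grid)
})

test_that("normality screen is calibrated on normal and heavy-tailed draws", {
  set.seed(30)
  p_norm <- replicate(100, normality_check(rnorm(500))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  set.seed(31)
  p_t1 <- replicate(100, normality_check(rt(500, df = 1))$p_value)
  expect_gte(mean(p_t1 < 0.05), 0.90)
  res <- normality_check(rnorm(200))
  expect_named(res$summary, c("mean", "sd"))
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(c(1, 2)), "n >= 3")
})
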