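test_that("Lin's concordance matches the closed-form definition", {
  set.seed(10)
  x <- rnorm(12, 100, 20); y <- 0.8 * x + rnorm(12, 10, 5)
  # brute-force evaluation of the population-moment formula
  brute <- 2 * mean((x - mean(x)) * (y - mean(y))) /
    (mean((x - mean(x))^2) + mean((y - mean(y))^2) +
       (mean(x) - mean(y))^2)
  expect_equal(ccc(x, y), brute, tolerance = 1e-12)
  expect_equal(ccc(x, x), 1.0)
  expect_lt(ccc(x, x + 25), stats::cor(x, x + 25))  # shift penalised
  expect_equal(ccc(x, y), ccc(y, x), tolerance = 1e-15)
  # |CCC| <= |r| on many random tables
  for (s in 1:25) {
    set.seed(s)
    a <- rnorm(8); b <- rnorm(8, sd = 2) + a
    expect_lte(abs(ccc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
  expect_error(ccc(1:3, 1:4), "equal length")
  expect_error(ccc(1, 2), "at least 2")
  expect_error(ccc(c(1, 1), c(1, 1)), "degenerate")
})

test_that("RMS percentage error matches hand arithmetic", {
  expect_equal(rms_percent_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms_percent_error(110, 100), 10)
  set.seed(3)
  p <- runif(6, 80, 120); o <- runif(6, 80, 120)
  expect_equal(rms_percent_error(p, o),
               sqrt(mean(((p - o) / o)^2)) * 100, tolerance = 1e-12)
  expect_error(rms_percent_error(1, 0), "non-zero")
})

test_that("BV/TV-force correlation is the squared Pearson r", {
  x <- seq(0.4, 0.8, length.out = 8)
  expect_equal(bvtv_force_correlation(x, 3 + 5 * x), 1.0)
  set.seed(42)
  a <- rnorm(400); b <- rnorm(400)
  expect_lt(bvtv_force_correlation(a, b), 0.05)      # null behaviour
  x12 <- rnorm(12); y12 <- rnorm(12) + 0.4 * x12
  expect_equal(bvtv_force_correlation(x12, y12),
               stats::cor(x12, y12)^2, tolerance = 1e-12)
  expect_error(bvtv_force_correlation(rep(1, 5), rnorm(5)), "variance")
})
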