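test_that("threshold calibration is deterministic and monotone in alpha", {
  q1 <- calibrate_threshold(50, 0.01, 800, seed = 11)
  q5 <- calibrate_threshold(50, 0.1, 800, seed = 11)
  expect_lt(q5, q1)
  expect_identical(q1, calibrate_threshold(50, 0.01, 800, seed = 11))
  expect_true(is.finite(calibrate_threshold(2, 0.5, 800, seed = 3)))
  expect_warning(calibrate_threshold(10, 0.1, 100, seed = 1), "unstable")
})

test_that("degenerate inputs are handled without error", {
  f <- fit_smuce(rep(3, 20))
  expect_equal(f$n_blocks, 1)
  expect_equal(f$block_means, 3)
  expect_error(fit_smuce(c(1, NA, 2)), "finite")
  f1 <- fit_smuce(5)
  expect_equal(f1$n_blocks, 1)
  # noiseless step: blocks recovered exactly
  f2 <- fit_smuce(c(rep(0, 5), rep(10, 5)))
  expect_equal(f2$changepoints, 5L)
  expect_equal(f2$block_means, c(0, 10))
})

test_that("a clear step is found at the right place", {
  set.seed(1)
  hits <- 0
  for (r in 1:20) {
    y <- c(rep(0, 50), rep(10, 50)) + stats::rnorm(100)
    f <- fit_smuce(y, alpha = 0.05, sigma = 1, seed = 77)
    if (f$n_blocks == 2 && abs(f$changepoints - 50) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("fits are invariant to shifts and equivariant under scaling", {
  set.seed(5)
  y <- c(rep(0, 30), rep(4, 30)) + stats::rnorm(60)
  q <- calibrate_threshold(60, 0.05, 800, seed = 2)
  f0 <- fit_smuce(y, sigma = 1, threshold = q)
  fs <- fit_smuce(y + 100, sigma = 1, threshold = q)
  expect_equal(fs$changepoints, f0$changepoints)
  expect_equal(fs$block_means, f0$block_means + 100)
  fsc <- fit_smuce(3 * y, sigma = 3, threshold = q)
  expect_equal(fsc$changepoints, f0$changepoints)
  expect_equal(fsc$block_means, 3 * f0$block_means, tolerance = 1e-12)
})

test_that("block count is monotone in alpha (nested acceptance regions)", {
  set.seed(8)
  for (r in 1:10) {
    y <- cumsum(c(0, stats::rbinom(39, 1, 0.1) * 4)) + stats::rnorm(40)
    nb <- vapply(c(0.01, 0.05, 0.1), function(a)
      fit_smuce(y, alpha = a, sigma = 1, seed = 4, mc_reps = 800)$n_blocks,
      numeric(1))
    expect_true(!is.unsorted(nb))
  }
})

test_that("the dynamic program agrees with exhaustive enumeration", {
  set.seed(12)
  for (r in 1:40) {
    n <- sample(5:18, 1)
    y <- cumsum(c(0, stats::rbinom(n - 1, 1, 0.15) * 4)) + stats::rnorm(n)
    q <- calibrate_threshold(n, 0.1, 600, seed = 42)
    fa <- fit_smuce(y, sigma = 1, threshold = q)
    fb <- exhaustive_oracle(y, sigma = 1, threshold = q)
    expect_identical(fa$changepoints, fb$changepoints)
    expect_equal(fa$block_means, fb$block_means, tolerance = 1e-9)
  }
  expect_error(exhaustive_oracle(stats::rnorm(31)), "length > 30")
})

test_that("confidence band covers the fitted means", {
  set.seed(3)
  y <- c(rep(0, 25), rep(6, 25)) + stats::rnorm(50)
  f <- fit_smuce(y, sigma = 1, seed = 9, mc_reps = 800)
  expect_true(all(f$block_means >= f$band[, "lo"] - 1e-12))
  expect_true(all(f$block_means <= f$band[, "hi"] + 1e-12))
})
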