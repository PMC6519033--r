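test_that("Box-Cox transform and inverse are exact", {
  expect_equal(boxcox_transform(0.3, 1), -0.7)
  expect_equal(boxcox_transform(0.04, 0.5), (0.2 - 1) / 0.5)
  expect_equal(boxcox_transform(2, 0), log(2))
  rho <- seq(1e-4, 0.1, length.out = 50)
  for (lam in c(0, 0.3, 0.55, 1))
    expect_equal(inverse_boxcox(boxcox_transform(rho, lam), lam), rho,
                 tolerance = 1e-12)
  # inverse clamps out-of-domain arguments to 0
  expect_equal(inverse_boxcox(-10, 0.5), 0)
  expect_error(boxcox_transform(-1, 0.5), "rho > 0")
})

test_that("linear quantile regression matches the exact small-n oracle", {
  set.seed(21)
  for (r in 1:20) {
    x <- stats::runif(25)
    y <- 1 + 2 * x + stats::rt(25, df = 3) * 0.3
    tau <- sample(c(0.25, 0.35, 0.5, 0.75), 1)
    got <- rq_linear(x, y, tau)
    want <- oracle_rq(x, y, tau)
    # IRLS converges to the check-loss optimum up to small numerical slack
    loss <- function(b) sum((y - b[1] - b[2] * x) *
                              (tau - ((y - b[1] - b[2] * x) < 0)))
    expect_lte(loss(got), loss(want) * (1 + 1e-3) + 1e-8)
  }
})

test_that("median quantile regression of an unbiased estimator is near identity", {
  set.seed(33)
  x <- stats::runif(10000, -2, 2)
  y <- x + stats::rnorm(10000, sd = 0.3)
  co <- rq_linear(x, y, 0.5)
  expect_lt(abs(co[1]), 0.05)
  expect_lt(abs(co[2] - 1), 0.05)
})

make_toy_training <- function(n = 800, noise = 0, seed = 1) {
  # synthetic additive truth: rho depends smoothly on the predictors
  set.seed(seed)
  d <- data.frame(haps = stats::runif(n), vapw = stats::runif(n),
                  apwd = stats::runif(n), wath = stats::runif(n),
                  hahe = stats::runif(n), maxchi = stats::runif(n),
                  nss = stats::runif(n))
  eta <- -1.5 + 0.8 * sin(pi * d$haps) + 0.5 * d$apwd^2 + 0.4 * d$wath +
    0.3 * cos(pi * d$hahe) + 0.2 * d$maxchi + 0.1 * d$nss + 0.2 * d$vapw +
    stats::rnorm(n, sd = noise)
  d$rho <- inverse_boxcox(eta, 0.5)
  d$impute <- FALSE
  d
}

test_that("a noiseless additive signal is recovered by the spline fit", {
  d <- make_toy_training(noise = 0)
  m <- fit_rho_model(d, lambda = 0.5)
  pred <- predict_rho(m, d)
  expect_gt(stats::cor(pred$rho_hat_raw, d$rho), 0.999)
  expect_lt(max(abs(pred$t_hat - boxcox_transform(d$rho, 0.5))), 0.02)
  expect_gt(m$r_squared, 0.999)
})

test_that("rank-deficient designs raise an error naming the predictor", {
  d <- make_toy_training()
  d$nss <- 0.5
  expect_error(fit_rho_model(d, lambda = 0.5), "nss")
})

test_that("predictions are floored at zero and hull clamping warns", {
  d <- make_toy_training()
  m <- fit_rho_model(d, lambda = 0.5)
  expect_true(all(predict_rho(m, d)$rho_hat >= 0))
  far <- d[1, ]; far$haps <- 10
  expect_warning(predict_rho(m, far), "hull")
})

test_that("bias correction is monotone and preserves ranking", {
  d <- make_toy_training(noise = 0.3)
  m <- fit_rho_model(d, lambda = 0.5)
  cal <- make_toy_training(noise = 0.3, seed = 2)
  m <- fit_bias_correction(m, cal)
  expect_setequal(names(m$bias_correction),
                  c("q0.25", "q0.35", "q0.45", "q0.5"))
  # probe the calibrated range of the estimator
  raw <- unname(stats::quantile(cal$rho, seq(0.05, 0.95, length.out = 40)))
  corr <- apply_bias_correction(m, raw, q = 0.35)
  expect_true(all(diff(corr) >= 0))
  expect_true(all(corr >= 0))
  # the conservative default quantile shrinks relative to the median one
  corr50 <- apply_bias_correction(m, raw, q = 0.5)
  expect_true(all(corr <= corr50 + 1e-12))
  expect_error(apply_bias_correction(m, raw, q = 0.9), "available")
})

test_that("model serialization round-trips to identical predictions", {
  d <- make_toy_training(noise = 0.2)
  m <- fit_rho_model(d, lambda = 0.5, meta = list(demography_tag = "neutral"))
  m <- fit_bias_correction(m, make_toy_training(noise = 0.2, seed = 3))
  path <- tempfile(fileext = ".json")
  save_rho_model(m, path)
  m2 <- load_rho_model(path)
  nd <- make_toy_training(seed = 4)[1:50, ]
  expect_identical(predict_rho(m, nd), predict_rho(m2, nd))
  expect_identical(predict_rho(m, nd, bias_quantile = 0.35),
                   predict_rho(m2, nd, bias_quantile = 0.35))
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$meta$demography_tag, "neutral")
})
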