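#' @name segmentation
#' @title Multiscale change-point estimation
#'
#' @description
#' A simultaneous multiscale change-point estimator for a noisy sequence
#' `y` assumed piecewise constant plus approximately Gaussian noise. The
#' fit is the piecewise-constant function with the *minimal* number of
#' jumps such that, on every interval `[u, v]` contained in a constant
#' block with level `mu`, the local likelihood-ratio statistic
#' `|mean(y[u:v]) - mu| * sqrt(v - u + 1) / sigma` stays below
#' `q + sqrt(2 * log(e * n / (v - u + 1)))`, where `q` is a Monte-Carlo
#' calibrated critical value. Calibrating `q` as the `(1 - alpha)` quantile
#' of the corresponding maximum statistic under pure noise controls the
#' probability of overestimating the number of change points at level
#' `alpha`. Among the minimal-jump fits the maximum-likelihood one is
#' returned (block means clamped to the multiscale confidence intervals),
#' with ties broken towards leftmost change points.
NULL

# penalty per interval length, Frick-style scale balancing
scale_penalty <- function(n, len) sqrt(2 * log(exp(1) * n / len))

.threshold_cache <- new.env(parent = emptyenv())

#' Calibrate the multiscale critical value
#'
#' Monte-Carlo `(1 - alpha)` quantile of
#' `max_{[u,v]} { |mean(z[u:v])| * sqrt(len) - sqrt(2 log(e n / len)) }`
#' over all intervals of a standard normal sequence of length `n`.
#' Deterministic given `seed`; results are cached per
#' `(n, alpha, mc_reps, seed)`.
#'
#' @param n sequence length.
#' @param alpha type-I error level in `(0, 1)`.
#' @param mc_reps Monte-Carlo replicates (a warning is given below 500).
#' @param seed integer seed.
#' @return The calibrated critical value (a scalar).
#' @export
calibrate_threshold <- function(n, alpha, mc_reps = 1000, seed = 1) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  if (mc_reps < 500)
    warning("mc_reps < 500 gives an unstable threshold quantile")
  key <- paste(n, format(alpha), mc_reps, seed, sep = "_")
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  pen <- scale_penalty(n, seq_len(n))
  stats <- vapply(seq_len(mc_reps), function(r) {
    cum <- c(0, cumsum(stats::rnorm(n)))
    m <- -Inf
    for (len in seq_len(n)) {
      u <- seq_len(n - len + 1L)
      m <- max(m, abs(cum[u + len] - cum[u]) / sqrt(len) - pen[len])
    }
    m
  }, numeric(1))
  q <- unname(stats::quantile(stats, 1 - alpha))
  .threshold_cache[[key]] <- q
  q
}

# robust noise scale: MAD of first differences / sqrt(2); falls back to the
# classical SD of differences when the MAD degenerates (e.g. one big jump in
# otherwise noiseless data)
estimate_sigma <- function(y) {
  if (length(y) < 2) return(0)
  d <- diff(y)
  s <- stats::mad(d) / sqrt(2)
  if (s == 0) s <- stats::sd(d) / sqrt(2)
  if (!is.finite(s)) s <- 0
  s
}

#' Fit the multiscale change-point estimator
#'
#' @param y numeric sequence (finite values).
#' @param alpha type-I error level, default 0.05.
#' @param sigma noise standard deviation; estimated robustly from first
#'   differences when `NULL`.
#' @param seed seed used for the threshold calibration.
#' @param mc_reps Monte-Carlo replicates for the calibration.
#' @param threshold optionally a pre-calibrated critical value, bypassing
#'   calibration.
#' @return An object of class `segmentation_result`: `changepoints`
#'   (indices `i` meaning a jump between `y[i]` and `y[i + 1]`, i.e. each
#'   value is the index of the last element of a block), `block_means`,
#'   `n_blocks`, `alpha`, `threshold`, `sigma`, and `band` (per-block
#'   feasible-mean intervals, matrix with columns `lo`, `hi`).
#' @examples
#' y <- c(rep(0, 20), rep(5, 20)) + rnorm(40, sd = 0.5)
#' fit_smuce(y, alpha = 0.05, sigma = 0.5, seed = 7)
#' @export
fit_smuce <- function(y, alpha = 0.05, sigma = NULL, seed = 1,
                      mc_reps = 1000, threshold = NULL) {
  if (any(!is.finite(y))) stop("y must be finite (no NA/NaN/Inf)")
  n <- length(y)
  stopifnot(n >= 1)
  if (n == 1 || length(unique(y)) == 1L)
    return(new_segmentation(integer(0), mean(y), alpha, NA_real_, 0,
                            cbind(lo = mean(y), hi = mean(y))))
  if (is.null(sigma)) sigma <- estimate_sigma(y)
  if (sigma <= 0) {
    # noiseless input: blocks are the runs of equal values
    cp <- which(diff(y) != 0)
    means <- vapply(split(y, cumsum(c(0, diff(y) != 0))), mean, numeric(1))
    return(new_segmentation(cp, unname(means), alpha, NA_real_, 0,
                            cbind(lo = unname(means), hi = unname(means))))
  }
  if (is.null(threshold))
    threshold <- calibrate_threshold(n, alpha, mc_reps, seed)
  halfw <- sigma * (threshold + scale_penalty(n, seq_len(n))) /
    sqrt(seq_len(n))                       # by block length
  cum <- c(0, cumsum(y)); cum2 <- c(0, cumsum(y^2))
  # quick exit: single block feasible?
  if (block_feasible_direct(y, cum, halfw)) {
    lohi <- block_bounds_direct(cum, 1L, n, halfw)
    mu <- clamp(cum[n + 1] / n, lohi[1], lohi[2])
    return(new_segmentation(integer(0), mu, alpha, threshold, sigma,
                            cbind(lo = lohi[1], hi = lohi[2])))
  }
  # Lo[u]/Hi[u]: feasible-mean bounds of block [u, j] at the current j;
  # LoM/HiM keep them for every (u, j) for backtracking
  Lo <- rep(-Inf, n); Hi <- rep(Inf, n)
  LoM <- matrix(NA_real_, n, n); HiM <- matrix(NA_real_, n, n)
  K <- rep(Inf, n + 1); SSE <- rep(Inf, n + 1); PRED <- integer(n + 1)
  K[1] <- 0; SSE[1] <- 0
  for (j in seq_len(n)) {
    u <- seq_len(j); len <- j - u + 1
    means <- (cum[j + 1] - cum[u]) / len
    lo_new <- means - halfw[len]; hi_new <- means + halfw[len]
    Lo[u] <- pmax(Lo[u], rev(cummax(rev(lo_new))))
    Hi[u] <- pmin(Hi[u], rev(cummin(rev(hi_new))))
    LoM[u, j] <- Lo[u]; HiM[u, j] <- Hi[u]
    feas <- which(Lo[u] <= Hi[u] & is.finite(K[u]))
    if (length(feas)) {
      mu <- clamp(means[feas], Lo[feas], Hi[feas])
      bsse <- (cum2[j + 1] - cum2[feas]) - 2 * mu * (cum[j + 1] - cum[feas]) +
        len[feas] * mu^2
      kc <- K[feas] + 1; sc <- SSE[feas] + bsse
      kmin <- min(kc)
      cand <- which(kc == kmin)
      best <- cand[which.min(sc[cand])]   # first min = leftmost block start
      K[j + 1] <- kmin; SSE[j + 1] <- sc[best]; PRED[j + 1] <- feas[best]
    }
  }
  # backtrack
  starts <- integer(0); j <- n
  while (j >= 1) { u <- PRED[j + 1]; starts <- c(u, starts); j <- u - 1 }
  ends <- c(starts[-1] - 1L, n)
  lo <- LoM[cbind(starts, ends)]; hi <- HiM[cbind(starts, ends)]
  raw <- (cum[ends + 1] - cum[starts]) / (ends - starts + 1)
  means <- clamp(raw, lo, hi)
  new_segmentation(starts[-1] - 1L, means, alpha, threshold, sigma,
                   cbind(lo = lo, hi = hi))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

block_bounds_direct <- function(cum, i, j, halfw) {
  lo <- -Inf; hi <- Inf
  for (v in i:j) {
    u <- i:v; len <- v - u + 1
    means <- (cum[v + 1] - cum[u]) / len
    lo <- max(lo, max(means - halfw[len]))
    hi <- min(hi, min(means + halfw[len]))
  }
  c(lo, hi)
}

block_feasible_direct <- function(y, cum, halfw) {
  n <- length(y)
  b <- block_bounds_direct(cum, 1L, n, halfw)
  b[1] <= b[2]
}

new_segmentation <- function(cp, means, alpha, threshold, sigma, band) {
  structure(list(changepoints = as.integer(cp), block_means = means,
                 n_blocks = length(means), alpha = alpha,
                 threshold = threshold, sigma = sigma, band = band),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation: %d block(s), alpha = %g\n", x$n_blocks, x$alpha))
  invisible(x)
}

#' Exhaustive change-point oracle (testing aid)
#'
#' Brute-force enumeration of all change-point configurations of increasing
#' size, returning the first (minimal) size admitting a fit that satisfies
#' the same multiscale constraint as [fit_smuce], with identical
#' tie-breaking (maximal likelihood, then leftmost change points). Only
#' intended for cross-checking the dynamic program on short sequences.
#'
#' @inheritParams fit_smuce
#' @param max_changepoints largest configuration size to try.
#' @return A `segmentation_result`.
#' @export
exhaustive_oracle <- function(y, alpha = 0.05, sigma = NULL, seed = 1,
                              mc_reps = 1000, threshold = NULL,
                              max_changepoints = length(y) - 1) {
  n <- length(y)
  if (n > 30) stop("exhaustive enumeration refused for length > 30")
  if (n == 1 || length(unique(y)) == 1L)
    return(fit_smuce(y, alpha, sigma, seed, mc_reps, threshold))
  if (is.null(sigma)) sigma <- estimate_sigma(y)
  if (sigma <= 0) return(fit_smuce(y, alpha, sigma, seed, mc_reps, threshold))
  if (is.null(threshold))
    threshold <- calibrate_threshold(n, alpha, mc_reps, seed)
  halfw <- sigma * (threshold + scale_penalty(n, seq_len(n))) /
    sqrt(seq_len(n))
  cum <- c(0, cumsum(y)); cum2 <- c(0, cumsum(y^2))
  eval_config <- function(cp) {      # cp: sorted 1-based jump-after indices
    starts <- c(1L, cp + 1L); ends <- c(cp, n)
    lo <- numeric(length(starts)); hi <- numeric(length(starts))
    for (b in seq_along(starts)) {
      bounds <- block_bounds_direct(cum, starts[b], ends[b], halfw)
      if (bounds[1] > bounds[2]) return(NULL)
      lo[b] <- bounds[1]; hi[b] <- bounds[2]
    }
    raw <- (cum[ends + 1] - cum[starts]) / (ends - starts + 1)
    mu <- clamp(raw, lo, hi)
    sse <- sum((cum2[ends + 1] - cum2[starts]) - 2 * mu * (cum[ends + 1] -
               cum[starts]) + (ends - starts + 1) * mu^2)
    list(cp = cp, mu = mu, sse = sse, lo = lo, hi = hi)
  }
  for (k in 0:max_changepoints) {
    cfgs <- if (k == 0) list(integer(0)) else
      apply(utils::combn(n - 1L, k), 2L, identity, simplify = FALSE)
    fits <- Filter(Negate(is.null), lapply(cfgs, eval_config))
    if (length(fits)) {
      sses <- vapply(fits, `[[`, numeric(1), "sse")
      best <- fits[abs(sses - min(sses)) < 1e-9]
      if (length(best) > 1) {   # leftmost change points
        ord <- order(vapply(best, function(f)
          paste(sprintf("%06d", f$cp), collapse = ""), character(1)))
        best <- best[ord]
      }
      f <- best[[1]]
      return(new_segmentation(f$cp, f$mu, alpha, threshold, sigma,
                              cbind(lo = f$lo, hi = f$hi)))
    }
  }
  stop("no feasible configuration within max_changepoints")
}
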