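# Brute-force reimplementations of the summary statistics, kept deliberately
# naive (explicit loops, no shared code with the package internals) so they
# can serve as independent oracles.

oracle_haps <- function(mat, L) {
  n <- nrow(mat)
  if (ncol(mat) == 0) return(1 / (n * L))
  keys <- character(n)
  for (i in seq_len(n)) keys[i] <- paste(mat[i, ], collapse = "/")
  length(unique(keys)) / (n * L)
}

oracle_wath <- function(mat, L) {
  n <- nrow(mat)
  a <- 0
  for (i in seq_len(n - 1)) a <- a + 1 / i
  ncol(mat) / (a * L)
}

oracle_pairwise <- function(mat, L) {
  n <- nrow(mat)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, sum(mat[i, ] != mat[j, ]) / L)
  if (!length(d)) return(c(apwd = 0, vapw = 0))
  c(apwd = mean(d), vapw = sum((d - mean(d))^2) / length(d))
}

oracle_hahe <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  if (S == 0) return(NA_real_)
  h <- numeric(S)
  for (s in seq_len(S)) {
    p1 <- sum(mat[, s] == 1) / n
    h[s] <- n / (n - 1) * (1 - (p1^2 + (1 - p1)^2))
  }
  mean(h)
}

oracle_nss <- function(mat) {
  S <- ncol(mat)
  if (S < 2) return(NA_real_)
  comp <- logical(S - 1)
  for (i in seq_len(S - 1)) {
    gametes <- unique(paste(mat[, i], mat[, i + 1]))
    comp[i] <- length(gametes) < 4
  }
  mean(comp)
}

oracle_maxchi <- function(mat) {
  S <- ncol(mat); n <- nrow(mat)
  if (S < 2 || n < 2) return(NA_real_)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mm <- as.integer(mat[i, ] != mat[j, ])
    for (k in seq_len(S - 1)) {
      a <- sum(mm[1:k]); b <- k - a
      cc <- sum(mm[(k + 1):S]); d <- (S - k) - cc
      den <- (a + b) * (cc + d) * (a + cc) * (b + d)
      chi <- if (den == 0) 0 else (a + b + cc + d) * (a * d - b * cc)^2 / den
      if (chi > best) best <- chi
    }
  }
  best
}

oracle_tajd <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  pi <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pi <- pi + sum(mat[i, ] != mat[j, ])
  pi <- pi / (n * (n - 1) / 2)
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# random small alignment with every column polymorphic
random_alignment <- function(n, S, L = 100) {
  mat <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    repeat {
      col <- stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8))
      if (any(col == 1) && any(col == 0)) break
    }
    mat[, s] <- col
  }
  pos <- sort(sample(0:(L - 1), S))
  hap_alignment(mat, pos, L)
}

# exact linear quantile regression for tiny n: the optimum passes through
# two data points; enumerate all pairs and minimise the check loss
oracle_rq <- function(x, y, tau) {
  n <- length(x)
  best <- NULL; best_loss <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i]); a <- y[i] - b * x[i]
    r <- y - a - b * x
    loss <- sum(r * (tau - (r < 0)))
    if (loss < best_loss) { best_loss <- loss; best <- c(a, b) }
  }
  best
}

# Trained models are expensive; train each once per test run, on fixed
# seeds chosen before any results were inspected.
.model_cache <- new.env(parent = emptyenv())

cached_neutral_model <- function() {
  if (is.null(.model_cache$neutral))
    .model_cache$neutral <- train_rho_model(theta = 0.01,
                                            demography_tag = "neutral",
                                            seed = 42)
  .model_cache$neutral
}

cached_demography_model <- function() {
  if (is.null(.model_cache$demography)) {
    lam <- cached_neutral_model()$lambda
    .model_cache$demography <- train_rho_model(
      theta = 0.01, demography_tag = "bottleneck_growth",
      seed = 43, lambda = lam)
  }
  .model_cache$demography
}
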