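#' @name summary-statistics
#' @title Per-segment summary statistics
#'
#' @description
#' The predictor set of the recombination-rate regression. All statistics
#' are computed from a [hap_alignment] and, where meaningful, normalised per
#' base pair so that segments of different lengths are comparable:
#'
#' * `stat_haps()` — number of distinct haplotypes divided by `n * L`.
#' * `stat_wath()` — Watterson's theta per bp, `S / (a_n * L)`.
#' * `stat_pairwise()` — mean (`apwd`) and population variance (`vapw`) of
#'   the per-bp Hamming distances over all haplotype pairs.
#' * `stat_hahe()` — mean per-site heterozygosity with the `n/(n-1)`
#'   small-sample factor.
#' * `stat_nss()` — neighbour similarity score: the fraction of adjacent
#'   segregating-site pairs that are compatible under the four-gamete test.
#' * `stat_maxchi()` — maximal chi-squared: the largest 2x2 chi-squared of
#'   mismatch counts left vs right of any split point, over all haplotype
#'   pairs and interior split positions.
#' * `stat_tajd()` — Tajima's D, used as an extra covariate when the model
#'   is trained under a demographic scenario.
#'
#' Statistics that need at least two segregating sites return `NA` below
#' that; `summarize_segment()` flags segments with `S <= 1` for imputation.
NULL

#' @rdname summary-statistics
#' @param aln a [hap_alignment].
#' @export
stat_haps <- function(aln) {
  h <- if (aln$S == 0) 1L else
    length(unique(apply(aln$mat, 1L, paste, collapse = "")))
  h / (aln$n * aln$length_bp)
}

harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

#' @rdname summary-statistics
#' @export
stat_wath <- function(aln) {
  stopifnot(aln$n >= 2)
  aln$S / (harmonic(aln$n - 1) * aln$length_bp)
}

#' @rdname summary-statistics
#' @export
stat_pairwise <- function(aln) {
  stopifnot(aln$n >= 2)
  if (aln$S == 0) return(c(apwd = 0, vapw = 0))
  d <- as.vector(stats::dist(aln$mat, method = "manhattan")) / aln$length_bp
  m <- mean(d)
  c(apwd = m, vapw = mean((d - m)^2))
}

#' @rdname summary-statistics
#' @export
stat_hahe <- function(aln) {
  if (aln$S == 0) return(NA_real_)
  p <- colMeans(aln$mat)
  mean(aln$n / (aln$n - 1) * (1 - (p^2 + (1 - p)^2)))
}

# TRUE iff a column pair shows at most 3 of the 4 gametes
four_gamete_compatible <- function(a, b) {
  length(unique(a * 2L + b)) < 4L
}

#' @rdname summary-statistics
#' @export
stat_nss <- function(aln) {
  if (aln$S < 2) return(NA_real_)
  comp <- vapply(seq_len(aln$S - 1), function(i)
    four_gamete_compatible(aln$mat[, i], aln$mat[, i + 1L]), logical(1))
  mean(comp)
}

# 2x2 chi-squared without continuity correction; 0 when a margin is empty
chisq2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  den <- r1 * r2 * c1 * c2
  ifelse(den == 0, 0, n * (a * d - b * c)^2 / den)
}

#' @rdname summary-statistics
#' @export
stat_maxchi <- function(aln) {
  if (aln$S < 2 || aln$n < 2) return(NA_real_)
  S <- aln$S
  pairs <- utils::combn(aln$n, 2)
  best <- 0
  for (j in seq_len(ncol(pairs))) {
    mm <- aln$mat[pairs[1, j], ] != aln$mat[pairs[2, j], ]
    cm <- cumsum(mm)
    tot <- cm[S]
    if (tot == 0) next
    k <- seq_len(S - 1)                      # split after site k
    a <- cm[k]; b <- k - a                   # left mismatches / matches
    cc <- tot - a; d <- (S - k) - cc         # right mismatches / matches
    best <- max(best, chisq2x2(a, b, cc, d))
  }
  best
}

#' @rdname summary-statistics
#' @export
stat_tajd <- function(aln) {
  n <- aln$n; S <- aln$S
  stopifnot(n >= 4)
  if (S == 0) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_total <- sum(as.vector(stats::dist(aln$mat, method = "manhattan"))) /
    choose(n, 2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Assemble the per-segment predictor vector
#'
#' Computes all regression predictors for one segment and flags segments
#' containing at most one SNP: these carry too little linkage information
#' and their rate estimates are later imputed from neighbouring segments.
#'
#' @param aln a [hap_alignment] for the segment.
#' @param include_tajd also compute Tajima's D (needed by
#'   demography-trained models; requires `n >= 4`).
#' @return A one-row `data.frame` with columns `haps`, `vapw`, `apwd`,
#'   `wath`, `hahe`, `maxchi`, `nss`, `tajd`, `snp_count`, `impute`.
#' @export
summarize_segment <- function(aln, include_tajd = FALSE) {
  pw <- stat_pairwise(aln)
  data.frame(
    haps = stat_haps(aln),
    vapw = pw[["vapw"]],
    apwd = pw[["apwd"]],
    wath = stat_wath(aln),
    hahe = stat_hahe(aln),
    maxchi = stat_maxchi(aln),
    nss = stat_nss(aln),
    tajd = if (include_tajd) stat_tajd(aln) else NA_real_,
    snp_count = aln$S,
    impute = aln$S <= 1L)
}
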