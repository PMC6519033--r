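#' Build a training table from a scenario grid
#'
#' Simulates every scenario of a constant-rate grid with the coalescent
#' engine and computes the per-segment summary statistics, yielding one
#' row per scenario with the true `rho` attached — the input for
#' [fit_rho_model] and [fit_bias_correction].
#'
#' @param grid a `data.frame` from [scenario_grid()] / [constant_rate_grid()].
#' @param demography `NULL` or a `demography_model`; defaults to the grid's
#'   `demography_tag`.
#' @param include_tajd compute Tajima's D as well.
#' @param seed simulation seed (overrides the grid's).
#' @return The grid with the summary-statistic columns appended.
#' @export
training_table <- function(grid, demography = NULL, include_tajd = FALSE,
                           seed = NULL) {
  if (is.null(seed)) seed <- grid$seed[1]
  if (is.null(demography) &&
      any(grid$demography_tag == "bottleneck_growth"))
    demography <- bottleneck_growth_demography()
  maps <- lapply(seq_len(nrow(grid)), function(i)
    recomb_map(grid$length_bp[i], numeric(0), grid$rho[i]))
  alns <- simulate_alignments(maps, grid$n, grid$theta, demography, seed)
  stats <- do.call(rbind, lapply(alns, summarize_segment,
                                 include_tajd = include_tajd))
  cbind(grid, stats)
}

#' Train a complete rate-estimation model
#'
#' One-call training pipeline: simulates a training replicate and an
#' independent calibration replicate of the constant-rate design, fits the
#' Box-Cox additive spline model and calibrates the quantile bias
#' correction. The returned model is tagged with the demography it was
#' trained under; [estimate_map] refuses to apply a model whose tag does
#' not match the requested scenario unless overridden.
#'
#' @param theta per-bp mutation rate of the training design.
#' @param demography_tag `"neutral"` or `"bottleneck_growth"`. Under the
#'   bottleneck-growth demography Tajima's D is added as a covariate.
#' @param train_replicates replicates of the 999-scenario design used for
#'   fitting (the calibration set always uses one extra, independent
#'   replicate).
#' @param seed master seed; training and calibration derive distinct
#'   streams from it.
#' @param quantiles bias-correction quantiles to calibrate.
#' @param lambda Box-Cox exponent: `"profile"` (maximum-likelihood choice)
#'   or a fixed value — pass a neutral model's `lambda` here when training
#'   the demography-aware model, which keeps the transform unchanged
#'   between the two.
#' @param calibration_segment_bp the bias correction is calibrated on
#'   simulated segments of this length only (default 1 kb, the
#'   recommended analysis segment length), so that the calibration
#'   curve's spread matches the noise level of the segments the pipeline
#'   actually scores; `NULL` pools all training lengths.
#' @return A fitted [rho_model][fit_rho_model] with bias corrections.
#' @export
train_rho_model <- function(theta = 0.01,
                            demography_tag = c("neutral", "bottleneck_growth"),
                            train_replicates = 2, seed = 1,
                            quantiles = c(0.25, 0.35, 0.45, 0.5),
                            lambda = "profile",
                            calibration_segment_bp = 1000) {
  demography_tag <- match.arg(demography_tag)
  include_tajd <- demography_tag == "bottleneck_growth"
  dem <- if (include_tajd) bottleneck_growth_demography()
  tr_grid <- constant_rate_grid(theta, demography_tag,
                                replicates = train_replicates, seed = seed)
  train <- training_table(tr_grid, dem, include_tajd, seed = seed)
  model <- fit_rho_model(train, include_tajd = include_tajd,
                         lambda = lambda,
                         meta = list(theta = theta,
                                     demography_tag = demography_tag,
                                     sample_sizes = c(10, 16, 20),
                                     lengths_bp = c(1000, 2000, 3000),
                                     train_replicates = train_replicates,
                                     seed = seed))
  cal_grid <- constant_rate_grid(theta, demography_tag, replicates = 1,
                                 seed = seed + 10000L)
  calib <- training_table(cal_grid, dem, include_tajd, seed = seed + 10000L)
  if (!is.null(calibration_segment_bp))
    calib <- calib[calib$length_bp == calibration_segment_bp, , drop = FALSE]
  fit_bias_correction(model, calib, quantiles)
}
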