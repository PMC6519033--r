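#' Constant-rate accuracy study
#'
#' Reproduces the constant-rate evaluation: simulates the 999-scenario
#' design (sample sizes 10/16/20, lengths 1/2/3 kb, 111 rho values
#' equidistant in `[0, 0.1]`, `theta = 0.01`), predicts each scenario's
#' rate with the (raw, uncorrected) regression model and reports the
#' coefficient of determination and the RMSE of `rho_hat` vs `rho` on the
#' natural scale. The evaluation replicate is simulated independently of
#' the training data.
#'
#' @param model a neutral [rho_model][fit_rho_model]; trained on the spot
#'   (with a seed derived from `seed`) when `NULL`.
#' @param theta per-bp mutation rate.
#' @param seed evaluation seed; training (if any) uses a shifted stream.
#' @return list with `table` (`data.frame` of `rho`, `rho_hat` and the
#'   scenario factors), `r_squared` (squared Pearson correlation), `rmse`.
#' @export
run_constant_rate_study <- function(model = NULL, theta = 0.01, seed = 1) {
  if (is.null(model))
    model <- train_rho_model(theta = theta, demography_tag = "neutral",
                             seed = seed + 20000L)
  grid <- constant_rate_grid(theta, "neutral", replicates = 1, seed = seed)
  tab <- training_table(grid, NULL, include_tajd = FALSE, seed = seed)
  sv <- tab
  for (p in model$predictors) {
    bad <- !is.finite(sv[[p]])
    sv[[p]][bad] <- mean(model$terms[[p]]$range)
  }
  pred <- suppressWarnings(predict_rho(model, sv))
  tab$rho_hat <- pred$rho_hat_raw
  err <- tab$rho_hat - tab$rho
  list(table = tab[, c("n", "length_bp", "rho", "rho_hat", "snp_count",
                       "impute")],
       r_squared = stats::cor(tab$rho, tab$rho_hat)^2,
       rmse = sqrt(mean(err^2)))
}

#' The 13 background rates of the two-hotspot demography study
#' @export
table2_background_rates <- function()
  c(0.0010, 0.0013, 0.0022, 0.0027, 0.0039, 0.0045, 0.0054, 0.0062,
    0.0071, 0.0080, 0.0085, 0.0091, 0.0100)

#' Two-hotspot map of the demography study
#'
#' 30 kb with two 1 kb hotspots starting at 10 kb and 20 kb, intensities
#' 20 and 35 times the background.
#'
#' @param background_rho per-bp background rate.
#' @export
table2_truth_map <- function(background_rho)
  hotspot_map(30000, background_rho,
              data.frame(start = c(10000, 20000), length = 1000,
                         intensity = c(20, 35)))

#' Demography (two-hotspot) evaluation study
#'
#' Evaluates the demography-trained estimator on samples of 16 sequences
#' of 30 kb simulated under the bottleneck-growth demography with the
#' two-hotspot map ([table2_truth_map]), for each requested background
#' rate: `replicates` independent maps are estimated with 1 kb segments,
#' `alpha = 0.05` and the 0.35 bias-correction quantile, and the RMSE
#' against the truth (1,000-point grid) is summarised per rate.
#'
#' @param model a bottleneck-growth [rho_model][fit_rho_model]; trained on
#'   the spot when `NULL`.
#' @param background_rhos background rates to evaluate (default all 13).
#' @param replicates replicates per rate, default 10.
#' @param seed master seed.
#' @param alpha,bias_quantile pipeline tuning.
#' @return `data.frame` with one row per background rate: `rho`,
#'   `mean_rmse`, `median_rmse`, `sd_rmse`.
#' @export
run_demography_study <- function(model = NULL,
                                 background_rhos = table2_background_rates(),
                                 replicates = 10, seed = 1,
                                 alpha = 0.05, bias_quantile = 0.35) {
  if (is.null(model))
    model <- train_rho_model(theta = 0.01,
                             demography_tag = "bottleneck_growth",
                             seed = seed + 30000L)
  dem <- bottleneck_growth_demography()
  rows <- lapply(seq_along(background_rhos), function(i) {
    bg <- background_rhos[i]
    truth <- table2_truth_map(bg)
    alns <- simulate_alignments(rep(list(truth), replicates), n = 16,
                                theta = 0.01, demography = dem,
                                seed = seed + i)
    rmse <- vapply(seq_len(replicates), function(r) {
      est <- estimate_map(alns[[r]], model, segment_length_bp = 1000,
                          alpha = alpha, bias_quantile = bias_quantile,
                          demography_tag = "bottleneck_growth",
                          seed = seed + i)
      evaluate_map(est, truth)$rmse
    }, numeric(1))
    data.frame(rho = bg, mean_rmse = mean(rmse),
               median_rmse = stats::median(rmse), sd_rmse = stats::sd(rmse))
  })
  do.call(rbind, rows)
}

#' Mutation-rate sensitivity study
#'
#' Accuracy of a model trained at `theta = 0.01` when applied to data of
#' varying diversity: simple-setup style truth maps (10 kb, one central
#' segment-aligned hotspot; background rates equidistant in
#' `[0.001, 0.03]`, intensities cycling through 5/10/15/20/40-fold,
#' hotspot lengths cycling through 2/1/0.5 kb) are estimated with 1 kb
#' segments under each `theta`, and the RMSE distribution is reported.
#' The same ancestral recombination graphs are reused across the `theta`
#' levels (only the mutation density differs), so the comparison across
#' mutation rates is paired. The model is deliberately *not* retrained
#' per theta, so `theta != 0.01` probes misspecification.
#'
#' @param model a neutral [rho_model][fit_rho_model]; trained when `NULL`.
#' @param thetas mutation rates to probe.
#' @param replicates simulated maps per theta.
#' @param seed master seed.
#' @return `data.frame` per theta: `theta`, `mean_rmse`, `sd_rmse`,
#'   `mean_snp_density` (mean SNPs per bp over segments).
#' @export
run_theta_sensitivity <- function(model = NULL,
                                  thetas = c(0.0025, 0.005, 0.01, 0.02),
                                  replicates = 10, seed = 1) {
  if (is.null(model))
    model <- train_rho_model(theta = 0.01, demography_tag = "neutral",
                             seed = seed + 20000L)
  bgs <- seq(0.001, 0.03, length.out = replicates)
  ints <- rep_len(c(5, 10, 15, 20, 40), replicates)
  lens <- rep_len(c(2000, 1000, 500), replicates)
  maps <- lapply(seq_len(replicates), function(r)
    hotspot_map(10000, bgs[r], data.frame(start = 4000, length = lens[r],
                                          intensity = ints[r])))
  rows <- lapply(thetas, function(th) {
    # same per-scenario seeds for every theta: identical genealogies,
    # different mutation densities
    alns <- simulate_alignments(maps, n = 16, theta = th, seed = seed)
    res <- vapply(seq_len(replicates), function(r) {
      est <- estimate_map(alns[[r]], model, segment_length_bp = 1000,
                          demography_tag = "neutral", seed = seed)
      c(evaluate_map(est, maps[[r]])$rmse,
        mean(est$segments$snp_count) / 1000)
    }, numeric(2))
    data.frame(theta = th, mean_rmse = mean(res[1, ]),
               sd_rmse = stats::sd(res[1, ]),
               mean_snp_density = mean(res[2, ]))
  })
  do.call(rbind, rows)
}
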