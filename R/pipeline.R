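#' Partition a sequence into analysis windows
#'
#' Contiguous, non-overlapping, half-open windows covering `[0, L)`. Give
#' either a window length (the last window absorbs any remainder) or a
#' window count `k` (equal lengths, remainder to the last window).
#'
#' @param L total sequence length in bp.
#' @param segment_length_bp window length in bp.
#' @param k alternatively, number of windows.
#' @return `data.frame` with columns `start`, `end`.
#' @export
segment_sequence <- function(L, segment_length_bp = NULL, k = NULL) {
  if (is.null(segment_length_bp) == is.null(k))
    stop("give exactly one of segment_length_bp or k")
  if (is.null(segment_length_bp)) segment_length_bp <- floor(L / k)
  if (segment_length_bp > L) stop("segment length exceeds sequence length")
  if (segment_length_bp < 400)
    warning("segments shorter than 400 bp carry little linkage information")
  starts <- seq(0, L - segment_length_bp, by = segment_length_bp)
  ends <- c(starts[-1], L)
  data.frame(start = starts, end = ends)
}

#' Impute rate estimates for SNP-sparse segments
#'
#' Segments with at most one SNP get the mean of the nearest non-flagged
#' estimates to their left and right (one-sided at the boundaries).
#'
#' @param rho_hat per-segment rate estimates.
#' @param flagged logical, which segments need imputation.
#' @return `rho_hat` with flagged entries filled in.
#' @export
impute_sparse <- function(rho_hat, flagged) {
  stopifnot(length(rho_hat) == length(flagged))
  if (all(flagged)) stop("all segments are SNP-sparse: sequence effectively monomorphic")
  if (!any(flagged)) return(rho_hat)
  good <- which(!flagged)
  for (i in which(flagged)) {
    left <- good[good < i]; right <- good[good > i]
    nb <- c(if (length(left)) rho_hat[max(left)],
            if (length(right)) rho_hat[min(right)])
    rho_hat[i] <- mean(nb)
  }
  rho_hat
}

#' Estimate a recombination map from a haplotype alignment
#'
#' The full estimation pipeline: split the sequence into segments, compute
#' per-segment summary statistics, predict the transformed rate with the
#' regression model, apply the quantile bias correction, back-transform,
#' impute SNP-sparse segments, and fit the multiscale change-point
#' estimator to the per-segment rate track (on the natural scale, which
#' detects hotspots better than the transformed scale). Block boundaries
#' are mapped back to bp coordinates and hotspots called against the
#' background-rate heuristic.
#'
#' @param aln a [hap_alignment] of the full region.
#' @param model a trained [rho_model][fit_rho_model].
#' @param segment_length_bp,k segmentation control, see
#'   [segment_sequence()].
#' @param alpha type-I error level of the change-point estimator.
#' @param bias_quantile bias-correction quantile (`NULL` for raw).
#' @param hotspot_factor fold-change over background defining a hotspot.
#' @param demography_tag expected training demography of the model;
#'   mismatches are an error unless `override_demography = TRUE`.
#' @param override_demography allow a model/scenario demography mismatch.
#' @param correction_stage where the bias correction acts: `"block"`
#'   (default) segments the raw rate track and calibrates the fitted block
#'   means — block averaging suppresses the per-segment noise before the
#'   steep low-rate part of the inverse calibration is applied;
#'   `"segment"` corrects every segment first and segments the corrected
#'   track.
#' @param segment_on_transformed segment the transformed-scale track
#'   instead of the natural-scale one (study flag).
#' @param seed seed for the threshold calibration.
#' @param mc_reps Monte-Carlo replicates for threshold calibration.
#' @return An object of class `estimated_map`: `map` (a [recomb_map]),
#'   `segments` (per-segment table with raw/corrected estimates and
#'   imputation flags), `segmentation` (the `segmentation_result`),
#'   `hotspots` (`data.frame` of `start`, `end` in bp), `background_rho`,
#'   and the configuration used.
#' @export
estimate_map <- function(aln, model, segment_length_bp = NULL, k = NULL,
                         alpha = 0.05, bias_quantile = 0.35,
                         hotspot_factor = 5,
                         demography_tag = NULL,
                         override_demography = FALSE,
                         correction_stage = c("block", "segment"),
                         segment_on_transformed = FALSE,
                         seed = 1, mc_reps = 1000) {
  correction_stage <- match.arg(correction_stage)
  if (is.null(segment_length_bp) && is.null(k)) segment_length_bp <- 1000
  stopifnot(inherits(aln, "hap_alignment"), inherits(model, "rho_model"))
  if (aln$S == 0) stop("empty alignment: no segregating sites")
  if (!is.null(demography_tag) && !override_demography &&
      !identical(model$meta$demography_tag, demography_tag))
    stop(sprintf(
      "model was trained under '%s' but '%s' was requested; set override_demography = TRUE to force",
      model$meta$demography_tag, demography_tag))
  include_tajd <- "tajd" %in% model$predictors
  windows <- segment_sequence(aln$length_bp, segment_length_bp, k)
  sv <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i)
    summarize_segment(window_alignment(aln, windows$start[i], windows$end[i]),
                      include_tajd = include_tajd)))
  # flagged rows may hold NA statistics; give the predictor placeholder
  # values there (their estimates are replaced by imputation anyway)
  sv_filled <- sv
  for (p in model$predictors) {
    bad <- !is.finite(sv_filled[[p]])
    sv_filled[[p]][bad] <- mean(model$terms[[p]]$range)
  }
  pred <- suppressWarnings(predict_rho(model, sv_filled, bias_quantile))
  rho_seg <- impute_sparse(ifelse(sv$impute, NA_real_, pred$rho_hat),
                           sv$impute)
  rho_raw <- impute_sparse(ifelse(sv$impute, NA_real_, pred$rho_hat_raw),
                           sv$impute)
  if (correction_stage == "block") {
    # segment the raw back-transformed track: block means average away the
    # per-segment noise, and the calibration curve is then inverted on the
    # (much more stable) block level
    track <- if (segment_on_transformed)
      impute_sparse(ifelse(sv$impute, NA_real_,
                           transformed_prediction(model, sv_filled)),
                    sv$impute) else rho_raw
    seg <- fit_smuce(track, alpha = alpha, seed = seed, mc_reps = mc_reps)
    block_means <- if (segment_on_transformed)
      pmax(inverse_boxcox(seg$block_means, model$lambda), 0) else
      pmax(seg$block_means, 0)
    if (!is.null(bias_quantile))
      block_means <- apply_bias_correction(model, block_means, bias_quantile)
  } else {
    track <- if (segment_on_transformed) {
      t_seg <- ifelse(sv$impute, NA_real_, pred$t_hat)
      impute_sparse(t_seg, sv$impute)
    } else rho_seg
    seg <- fit_smuce(track, alpha = alpha, seed = seed, mc_reps = mc_reps)
    block_means <- if (segment_on_transformed)
      pmax(inverse_boxcox(seg$block_means, model$lambda), 0) else
      pmax(seg$block_means, 0)
  }
  bp_breaks <- windows$end[seg$changepoints]
  map <- recomb_map(aln$length_bp, bp_breaks, block_means)
  hs <- call_hotspots(map, rho_seg, factor = hotspot_factor)
  structure(list(
    map = map, segments = cbind(windows, sv,
                                rho_hat_raw = pred$rho_hat_raw,
                                rho_hat = rho_seg),
    segmentation = seg, hotspots = hs$hotspots,
    background_rho = hs$background_rho,
    config = list(segment_length_bp = segment_length_bp, k = k,
                  alpha = alpha, bias_quantile = bias_quantile,
                  correction_stage = correction_stage,
                  hotspot_factor = hotspot_factor, seed = seed)),
    class = "estimated_map")
}

#' @export
print.estimated_map <- function(x, ...) {
  cat(sprintf("estimated_map: %g bp, %d block(s), %d hotspot(s), background rho %.4g\n",
              x$map$length_bp, n_blocks(x$map), nrow(x$hotspots),
              x$background_rho))
  invisible(x)
}

#' Call hotspots against a background-rate heuristic
#'
#' The background rate is the mean of all per-segment estimates strictly
#' below their median (a deliberately downward-biased estimate); if no
#' estimate falls strictly below the median (all equal), the common value
#' is used. Hotspots are maximal runs of map blocks whose rate strictly
#' exceeds `factor` times the background.
#'
#' @param map a [recomb_map].
#' @param rho_segments the per-segment estimates the background is derived
#'   from (defaults to the block rates themselves).
#' @param factor hotspot fold-change threshold, default 5.
#' @return list with `background_rho` and `hotspots` (`data.frame` of
#'   `start`, `end`).
#' @export
call_hotspots <- function(map, rho_segments = NULL, factor = 5) {
  if (is.null(rho_segments)) rho_segments <- map$rates
  med <- stats::median(rho_segments)
  below <- rho_segments[rho_segments < med]
  background <- if (length(below)) mean(below) else med
  hot <- map$rates > factor * background
  bounds <- c(0, map$breakpoints, map$length_bp)
  runs <- rle(hot)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1L
  hs <- data.frame(start = bounds[starts_idx[runs$values]],
                   end = bounds[ends_idx[runs$values] + 1L])
  list(background_rho = background, hotspots = hs)
}

#' Compare an estimated map with the truth
#'
#' Quality measures for a piecewise-constant estimate against the true
#' map: RMSE of the per-bp rate on an equidistant grid of `grid_points`
#' positions; WRMSE, the RMSE over the estimated blocks weighted by block
#' length over total length (the true rate within a block is its
#' length-weighted average); PCH, the proportion of true hotspots with a
#' non-empty intersection with a detected hotspot region; PCB, the same
#' for background blocks vs detected background; and AP = (PCH + PCB)/2.
#' Detected regions come from the estimated map's own
#' `factor`-times-background rule ([call_hotspots]); true hotspots are the
#' blocks of the true map exceeding `factor` times its minimal rate.
#'
#' @param estimated an `estimated_map` from [estimate_map] or a
#'   [recomb_map].
#' @param truth the true [recomb_map] (same length).
#' @param grid_points grid size for the RMSE, default 1000.
#' @param factor hotspot fold-change threshold.
#' @return one-row `data.frame`: `rmse`, `wrmse`, `pch`, `pcb`, `ap`.
#' @export
evaluate_map <- function(estimated, truth, grid_points = 1000, factor = 5) {
  est_map <- if (inherits(estimated, "estimated_map")) estimated$map
             else estimated
  if (est_map$length_bp != truth$length_bp)
    stop("estimated and true maps cover different lengths")
  L <- truth$length_bp
  grid <- (seq_len(grid_points) - 0.5) / grid_points * L
  rmse <- sqrt(mean((rho_at(est_map, grid) - rho_at(truth, grid))^2))

  bounds <- c(0, est_map$breakpoints, L)
  w <- diff(bounds) / L
  true_avg <- vapply(seq_along(est_map$rates), function(i)
    block_average(truth, bounds[i], bounds[i + 1]), numeric(1))
  wrmse <- sqrt(sum(w * (est_map$rates - true_avg)^2))

  det <- if (inherits(estimated, "estimated_map"))
    list(background_rho = estimated$background_rho,
         hotspots = estimated$hotspots)
    else call_hotspots(est_map, factor = factor)
  tb <- c(0, truth$breakpoints, L)
  true_hot <- truth$rates > factor * min(truth$rates)
  hot_iv <- cbind(tb[-length(tb)][true_hot], tb[-1][true_hot])
  bg_iv <- cbind(tb[-length(tb)][!true_hot], tb[-1][!true_hot])
  det_hot <- as.matrix(det$hotspots)
  det_bg <- complement_intervals(det_hot, L)
  pch <- prop_intersecting(hot_iv, det_hot)
  pcb <- prop_intersecting(bg_iv, det_bg)
  data.frame(rmse = rmse, wrmse = wrmse, pch = pch, pcb = pcb,
             ap = (pch + pcb) / 2)
}

# length-weighted average of the true rate over [a, b)
block_average <- function(map, a, b) {
  bounds <- c(0, map$breakpoints, map$length_bp)
  lo <- pmax(bounds[-length(bounds)], a)
  hi <- pmin(bounds[-1], b)
  len <- pmax(hi - lo, 0)
  sum(len * map$rates) / (b - a)
}

complement_intervals <- function(iv, L) {
  if (!nrow(iv)) return(cbind(0, L))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  starts <- c(0, iv[, 2]); ends <- c(iv[, 1], L)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

# fraction of target intervals with non-empty overlap with any detected one
prop_intersecting <- function(targets, detected) {
  if (!nrow(targets)) return(NA_real_)
  if (!nrow(detected)) return(0)
  hit <- vapply(seq_len(nrow(targets)), function(i)
    any(detected[, 1] < targets[i, 2] & detected[, 2] > targets[i, 1]),
    logical(1))
  mean(hit)
}
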