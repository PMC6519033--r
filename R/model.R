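#' Box-Cox transform and its inverse
#'
#' `boxcox_transform()` maps a positive rate to
#' `(rho^lambda - 1) / lambda` (or `log(rho)` for `lambda = 0`);
#' `inverse_boxcox()` maps back, clamping arguments below the transform's
#' domain to 0 so that back-transformed rates are always non-negative.
#'
#' @param rho positive rate(s).
#' @param t transformed value(s).
#' @param lambda Box-Cox exponent.
#' @export
boxcox_transform <- function(rho, lambda) {
  if (any(rho <= 0)) stop("Box-Cox transform requires rho > 0")
  if (lambda == 0) log(rho) else (rho^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @export
inverse_boxcox <- function(t, lambda) {
  if (lambda == 0) return(exp(t))
  base <- pmax(lambda * t + 1, 0)
  base^(1 / lambda)
}

# ---- linear quantile regression (check-loss IRLS) ------------------------

#' Linear quantile regression of y on x
#'
#' Minimises the check loss `sum(r * (tau - (r < 0)))` for a straight line
#' by iteratively reweighted least squares. Two parameters only; used for
#' the estimator's bias correction on the transformed scale.
#'
#' @param x,y numeric vectors.
#' @param tau quantile in (0, 1).
#' @param maxit,tol iteration controls.
#' @return `c(intercept, slope)`.
#' @export
rq_linear <- function(x, y, tau, maxit = 200, tol = 1e-10) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1)
  b <- stats::coef(stats::lm(y ~ x))
  eps <- 1e-8 * max(stats::sd(y), 1e-12)
  for (it in seq_len(maxit)) {
    r <- y - b[1] - b[2] * x
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    bn <- fit$coefficients
    if (max(abs(bn - b)) < tol * (1 + max(abs(b)))) { b <- bn; break }
    b <- bn
  }
  unname(b)
}

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# smooth monotone quantile curve of y on x: check-loss IRLS on a
# truncated-power cubic spline basis, evaluated on a dense grid and
# projected onto non-decreasing functions. Returned as an interpolation
# table (grid = x, value = fitted tau-quantile of y).
rq_spline_monotone <- function(x, y, tau, df = 5, grid_points = 200,
                               maxit = 200, tol = 1e-9) {
  knots <- unique(stats::quantile(x, seq(0, 1, length.out = df + 1)))
  basis <- function(z) {
    z <- clamp(z, knots[1], knots[length(knots)])
    B <- outer(z, knots[-c(1, length(knots))], function(a, b) pmax(a - b, 0)^3)
    cbind(1, z, z^2, z^3, B)
  }
  X <- basis(x)
  b <- stats::lm.fit(X, y)$coefficients
  b[is.na(b)] <- 0
  eps <- 1e-8 * max(stats::sd(y), 1e-12)
  for (it in seq_len(maxit)) {
    r <- y - X %*% b
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, as.numeric(w))
    bn <- fit$coefficients; bn[is.na(bn)] <- 0
    if (max(abs(bn - b)) < tol * (1 + max(abs(b)))) { b <- bn; break }
    b <- bn
  }
  grid <- seq(min(x), max(x), length.out = grid_points)
  val <- as.numeric(basis(grid) %*% b)
  val <- stats::isoreg(grid, val)$yf              # enforce monotonicity
  val <- val + 1e-9 * (grid - grid[1])            # break exact flats
  list(grid = grid, value = val)
}

# invert a monotone calibration curve (grid = transformed true rate,
# value = fitted quantile of the transformed raw estimate): given raw
# values t, return the true-rate abscissa, extending linearly beyond the
# calibrated range with the boundary slopes
invert_correction_table <- function(tab, t) {
  g <- tab$grid; v <- tab$value
  m <- length(g)
  k <- max(2L, ceiling(m * 0.1))
  slope_lo <- (g[k] - g[1]) / (v[k] - v[1])
  slope_hi <- (g[m] - g[m - k + 1]) / (v[m] - v[m - k + 1])
  out <- stats::approx(v, g, xout = clamp(t, v[1], v[m]),
                       ties = "ordered")$y
  lo <- t < v[1]; hi <- t > v[m]
  out[lo] <- g[1] + slope_lo * (t[lo] - v[1])
  out[hi] <- g[m] + slope_hi * (t[hi] - v[m])
  out
}

apply_correction <- function(bc, t) {
  if (identical(bc$type, "calibration_linear"))
    (t - bc$coef[1]) / bc$coef[2]
  else invert_correction_table(bc, t)
}

# ---- model fitting -------------------------------------------------------

model_predictors <- function(include_tajd)
  c("haps", "vapw", "apwd", "wath", "hahe", "maxchi", "nss",
    if (include_tajd) "tajd")

gam_formula <- function(predictors, data, k = 10) {
  terms <- vapply(predictors, function(p) {
    nu <- length(unique(data[[p]]))
    kk <- max(3, min(k, nu - 1))
    sprintf("s(%s, bs = 'cr', k = %d)", p, kk)
  }, character(1))
  stats::as.formula(paste("t_rho ~", paste(terms, collapse = " + ")))
}

#' Fit the constant-rate regression model
#'
#' Fits the additive model `t(rho) = f_1(z_1) + ... + f_q(z_q)` where
#' `t` is the Box-Cox transform and the `f_j` are cubic regression splines
#' of the per-segment summary statistics, estimated by [mgcv::gam] with
#' GCV smoothing. The Box-Cox exponent `lambda` is chosen by profile
#' maximum likelihood over `lambda_grid` (Gaussian likelihood of the
#' additive fit plus the transform's Jacobian), then frozen into the model.
#' For portable persistence each fitted smooth is distilled to a dense
#' interpolation table spanning the training range of its predictor; all
#' predictions are evaluated through these tables, so a saved-and-reloaded
#' model reproduces predictions exactly.
#'
#' Rows with `rho <= 0` cannot enter the transform and are dropped with a
#' message, as are rows flagged for imputation (at most one SNP).
#'
#' @param training table with the predictor columns and a `rho` column;
#'   typically from [training_table()].
#' @param include_tajd add Tajima's D as an eighth covariate
#'   (demography-aware models).
#' @param lambda either a fixed Box-Cox exponent or `"profile"`.
#' @param lambda_grid candidate exponents for the profile search.
#' @param grid_points size of the per-smooth interpolation tables.
#' @param meta list of training metadata stored verbatim in the model.
#' @return An object of class `rho_model`: `lambda`, `intercept`,
#'   `terms` (per-predictor grid/value tables and training ranges),
#'   `bias_correction` (empty until [fit_bias_correction]), `r_squared`
#'   and `term_p_values` on the transformed scale, `meta`.
#' @export
fit_rho_model <- function(training, include_tajd = FALSE,
                          lambda = "profile",
                          lambda_grid = seq(0.05, 1, by = 0.05),
                          grid_points = 400, meta = list()) {
  preds <- model_predictors(include_tajd)
  missing_cols <- setdiff(c(preds, "rho"), names(training))
  if (length(missing_cols))
    stop("training table lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- training$rho > 0 & !Reduce(`|`, lapply(training[preds], is.na))
  if ("impute" %in% names(training)) keep <- keep & !training$impute
  dropped <- sum(!keep)
  if (dropped) message(sprintf("dropping %d rows (rho <= 0, NA or sparse)",
                               dropped))
  dat <- training[keep, , drop = FALSE]
  for (p in preds) {
    if (length(unique(dat[[p]])) < 4)
      stop(sprintf("predictor '%s' is (nearly) constant: rank-deficient design", p))
  }
  if (identical(lambda, "profile")) {
    ll <- vapply(lambda_grid, function(lam) {
      dat$t_rho <- boxcox_transform(dat$rho, lam)
      g <- mgcv::gam(gam_formula(preds, dat), data = dat)
      n <- nrow(dat)
      -n / 2 * log(sum(stats::residuals(g)^2) / n) +
        (lam - 1) * sum(log(dat$rho))
    }, numeric(1))
    lambda <- lambda_grid[which.max(ll)]
  }
  dat$t_rho <- boxcox_transform(dat$rho, lambda)
  g <- mgcv::gam(gam_formula(preds, dat), data = dat)
  smry <- mgcv::summary.gam(g)
  # distill each centred smooth onto a dense grid
  med <- vapply(preds, function(p) stats::median(dat[[p]]), numeric(1))
  terms <- lapply(preds, function(p) {
    rng <- range(dat[[p]])
    grid <- seq(rng[1], rng[2], length.out = grid_points)
    nd <- as.data.frame(as.list(med))[rep(1, grid_points), , drop = FALSE]
    nd[[p]] <- grid
    tm <- stats::predict(g, newdata = nd, type = "terms")
    col <- grep(sprintf("s\\(%s\\)", p), colnames(tm))
    list(grid = grid, value = unname(tm[, col]), range = rng)
  })
  names(terms) <- preds
  model <- structure(list(
    version = 1L,
    lambda = lambda,
    intercept = unname(stats::coef(g)[1]),
    predictors = preds,
    terms = terms,
    bias_correction = list(),
    r_squared = smry$r.sq,
    term_p_values = stats::setNames(as.numeric(smry$s.table[, "p-value"]),
                                    preds),
    meta = meta), class = "rho_model")
  model
}

#' @export
print.rho_model <- function(x, ...) {
  cat(sprintf("rho_model: lambda = %g, predictors: %s\n", x$lambda,
              paste(x$predictors, collapse = ", ")))
  if (length(x$bias_correction))
    cat("  bias-correction quantiles:",
        paste(names(x$bias_correction), collapse = ", "), "\n")
  invisible(x)
}

# additive predictor on the transformed scale; inputs clamped to the
# training hull (clamping counted via the "clamped" attribute)
transformed_prediction <- function(model, newdata) {
  eta <- rep(model$intercept, nrow(newdata))
  clamped <- 0L
  for (p in model$predictors) {
    x <- newdata[[p]]
    if (is.null(x)) stop("missing predictor: ", p)
    tm <- model$terms[[p]]
    out <- x < tm$range[1] | x > tm$range[2]
    clamped <- clamped + sum(out, na.rm = TRUE)
    x <- clamp(x, tm$range[1], tm$range[2])
    eta <- eta + stats::spline(tm$grid, tm$value, xout = x,
                               method = "natural")$y
  }
  attr(eta, "clamped") <- clamped
  eta
}

#' Predict per-segment recombination rates
#'
#' Evaluates the additive predictor for each row of `newdata`, optionally
#' applies the stored quantile bias correction on the transformed scale,
#' and back-transforms; rates are floored at 0. Predictor values outside
#' the training hull are clamped to it (with a warning).
#'
#' @param model a fitted [rho_model][fit_rho_model].
#' @param newdata `data.frame` of summary vectors.
#' @param bias_quantile a quantile present in the model's bias-correction
#'   table, or `NULL` for the raw model prediction.
#' @return `data.frame` with `rho_hat` (final, `>= 0`), `rho_hat_raw`
#'   (back-transformed uncorrected), and `t_hat` (transformed-scale value
#'   after any correction).
#' @export
predict_rho <- function(model, newdata, bias_quantile = NULL) {
  eta <- transformed_prediction(model, newdata)
  if (attr(eta, "clamped") > 0)
    warning(sprintf("%d predictor value(s) outside training hull were clamped",
                    attr(eta, "clamped")))
  raw <- inverse_boxcox(as.numeric(eta), model$lambda)
  t_hat <- as.numeric(eta)
  if (!is.null(bias_quantile)) {
    key <- format_quantile(bias_quantile)
    bc <- model$bias_correction[[key]]
    if (is.null(bc))
      stop("no bias correction for quantile ", bias_quantile,
           "; available: ", paste(names(model$bias_correction), collapse = ", "))
    t_hat <- apply_correction(bc, t_hat)
  }
  data.frame(rho_hat = pmax(inverse_boxcox(t_hat, model$lambda), 0),
             rho_hat_raw = pmax(raw, 0), t_hat = t_hat)
}

format_quantile <- function(q) sprintf("q%s", format(q))

#' Calibrate the quantile-regression bias correction
#'
#' The raw regression estimates suffer from attenuation: low rates are
#' overestimated on average and high rates underestimated, because the
#' summary statistics only weakly separate rates at short segment lengths
#' and the fit regresses towards the training mean. The correction
#' therefore works as a classical inverse calibration on the transformed
#' scale: on an independent calibration table, the `(1 - q)`-quantile
#' curve of the transformed raw estimate *given* the transformed true
#' rate is fitted by quantile regression (by default a smooth monotone
#' curve; `form = "linear"` for a straight line), and corrected estimates
#' are obtained by inverting that curve. By quantile duality, inverting
#' the upper `(1 - q)` curve yields a lower `q`-bound for the true rate
#' given the estimate, so a small `q` (e.g. the default 0.35 of the
#' pipeline) gives deliberately conservative, downward-shrunk rates —
#' favouring background specificity — while `q = 0.5` is the median
#' calibration.
#'
#' @param model a fitted [rho_model][fit_rho_model].
#' @param calibration table like the training table, simulated
#'   independently of it.
#' @param quantiles quantile labels to calibrate.
#' @param form `"spline"` (default) or `"linear"`.
#' @return The model with `bias_correction` filled in (one monotone
#'   calibration curve or coefficient pair per quantile).
#' @export
fit_bias_correction <- function(model, calibration,
                                quantiles = c(0.25, 0.35, 0.45, 0.5),
                                form = c("spline", "linear")) {
  form <- match.arg(form)
  keep <- calibration$rho > 0 &
    !Reduce(`|`, lapply(calibration[model$predictors], is.na))
  if ("impute" %in% names(calibration)) keep <- keep & !calibration$impute
  dat <- calibration[keep, , drop = FALSE]
  t_true <- boxcox_transform(dat$rho, model$lambda)
  t_raw <- suppressWarnings(predict_rho(model, dat)$t_hat)
  bc <- lapply(quantiles, function(q) {
    tau <- 1 - q
    if (form == "linear") {
      co <- rq_linear(t_true, t_raw, tau)
      if (co[2] <= 0)
        stop(sprintf("bias correction at q = %g has non-positive slope", q))
      list(type = "calibration_linear", coef = co)
    } else {
      tab <- rq_spline_monotone(t_true, t_raw, tau)
      c(list(type = "calibration_spline"), tab)
    }
  })
  if (form == "spline" && length(bc) > 1) {
    # independently fitted quantile curves can cross; rearrange on the
    # shared grid so that a larger tau always gives the higher curve
    vals <- vapply(bc, `[[`, numeric(length(bc[[1]]$value)), "value")
    ord <- order(1 - quantiles)                 # increasing tau
    vals[, ord] <- t(apply(vals[, ord, drop = FALSE], 1, sort))
    for (i in seq_along(bc)) bc[[i]]$value <- vals[, i]
  }
  names(bc) <- vapply(quantiles, format_quantile, character(1))
  model$bias_correction <- bc
  model
}

#' Apply a stored bias correction to raw estimates
#'
#' Convenience wrapper: maps raw back-transformed rates through the linear
#' correction on the transformed scale, `rho = t^{-1}(a_q + b_q * t(rho_raw))`,
#' flooring at 0.
#'
#' @param model a [rho_model][fit_rho_model] with bias corrections.
#' @param rho_raw raw rate estimates (`> 0`; zeros are kept at 0).
#' @param q quantile, default 0.35.
#' @export
apply_bias_correction <- function(model, rho_raw, q = 0.35) {
  key <- format_quantile(q)
  bc <- model$bias_correction[[key]]
  if (is.null(bc))
    stop("no bias correction for quantile ", q, "; available: ",
         paste(names(model$bias_correction), collapse = ", "))
  out <- numeric(length(rho_raw))
  pos <- rho_raw > 0
  out[pos] <- pmax(inverse_boxcox(
    apply_correction(bc, boxcox_transform(rho_raw[pos], model$lambda)),
    model$lambda), 0)
  out
}

# ---- persistence ---------------------------------------------------------

#' Save / load a fitted model
#'
#' Models are persisted as a single self-describing JSON file holding the
#' Box-Cox exponent, the per-predictor interpolation tables, the
#' bias-correction coefficients and the training metadata. The round trip
#' is exact: a reloaded model gives bit-identical predictions.
#'
#' @param model a [rho_model][fit_rho_model].
#' @param path file path.
#' @export
save_rho_model <- function(model, path) {
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_rho_model
#' @export
load_rho_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$terms <- lapply(x$terms, function(tm)
    list(grid = as.numeric(tm$grid), value = as.numeric(tm$value),
         range = as.numeric(tm$range)))
  x$bias_correction <- lapply(x$bias_correction, function(bc) {
    bc$coef <- as.numeric(bc$coef)
    bc$grid <- as.numeric(bc$grid); bc$value <- as.numeric(bc$value)
    bc[!vapply(bc, function(e) length(e) == 0, logical(1))]
  })
  x$term_p_values <- unlist(x$term_p_values)
  structure(x, class = "rho_model")
}
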