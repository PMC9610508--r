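#' Mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @return scalar MSE.
#' @export
mse <- function(y, yhat) {
  check_pair(y, yhat)
  mean((y - yhat)^2)
}

#' Mean absolute error
#' @param y,yhat numeric vectors of equal length.
#' @return scalar MAE.
#' @export
mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

check_pair <- function(y, yhat) {
  if (length(y) == 0) stop("empty input")
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
}

#' Pearson correlation coefficient
#'
#' Covariance over the product of standard deviations. Undefined when either
#' argument has zero variance; such cases return `NA` with attribute
#' `"degenerate" = TRUE` rather than 0, and are excluded (with a count) from
#' report averages.
#'
#' @param y,yhat numeric vectors of equal length.
#' @return scalar in `[-1, 1]`, or flagged `NA`.
#' @export
pearson_cc <- function(y, yhat) {
  check_pair(y, yhat)
  sy <- stats::sd(y); syh <- stats::sd(yhat)
  if (sy == 0 || syh == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(y, yhat)
}

#' SSIM parameter set
#'
#' @param K1,K2 the two stabilisation constants, defaults 0.01 and 0.03.
#' @param L dynamic range of the values; 1 for conductivities in `[0, 1]`.
#' @return list with `C1 = (K1 L)^2` and `C2 = (K2 L)^2` (1e-4 and 9e-4 at
#'   the defaults).
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = 1) {
  list(K1 = K1, K2 = K2, L = L, C1 = (K1 * L)^2, C2 = (K2 * L)^2)
}

#' Structural similarity index (single global window)
#'
#' `SSIM = (2 m_y m_yhat + C1)(2 s_yyhat + C2) /
#'         ((m_y^2 + m_yhat^2 + C1)(s_y^2 + s_yhat^2 + C2))`
#' computed once over the whole volume with population (divide-by-N)
#' moments. Equals 1 for identical images.
#'
#' @param y,yhat numeric vectors with values in `[0, L]`.
#' @param params from [ssim_params()].
#' @return scalar SSIM.
#' @export
ssim <- function(y, yhat, params = ssim_params()) {
  check_pair(y, yhat)
  if (any(y < 0 | y > params$L) || any(yhat < 0 | yhat > params$L))
    stop(sprintf("values must lie in [0, %g]", params$L))
  n <- length(y)
  my <- mean(y); myh <- mean(yhat)
  vy <- mean((y - my)^2); vyh <- mean((yhat - myh)^2)
  cov <- mean((y - my) * (yhat - myh))
  ((2 * my * myh + params$C1) * (2 * cov + params$C2)) /
    ((my^2 + myh^2 + params$C1) * (vy + vyh + params$C2))
}

#' Huber loss
#'
#' Quadratic branch `0.5 (y - yhat)^2` where the absolute error is at most
#' `delta`, linear branch `delta |y - yhat| - 0.5 delta^2` otherwise,
#' averaged over elements. Combines the smoothness of MSE with the outlier
#' robustness of MAE.
#'
#' @param y,yhat numeric vectors of equal length.
#' @param delta positive branch threshold.
#' @return scalar loss.
#' @export
huber_loss <- function(y, yhat, delta = 0.05) {
  check_pair(y, yhat)
  if (delta <= 0) stop("delta must be positive")
  e <- abs(y - yhat)
  mean(ifelse(e <= delta, 0.5 * e^2, delta * e - 0.5 * delta^2))
}

#' Per-sample metric report for predictions against targets
#'
#' Computes Huber loss (delta = 0.05 by default), MAE, MSE, Pearson CC and
#' global SSIM for every row pair and their means. Samples with a degenerate
#' (zero-variance) prediction or target are excluded from the CC mean and
#' counted.
#'
#' @param targets,predictions `N x p` matrices (rows are samples).
#' @param delta Huber threshold used in the report.
#' @param ssim_p SSIM parameters.
#' @return a `metrics_report`: data frame `per_sample` plus `means` (named
#'   vector `loss`, `mae`, `mse`, `cc`, `ssim`) and `cc_excluded`.
#' @export
metrics_report <- function(targets, predictions, delta = 0.05,
                           ssim_p = ssim_params()) {
  targets <- as.matrix(targets); predictions <- as.matrix(predictions)
  stopifnot(all(dim(targets) == dim(predictions)))
  n <- nrow(targets)
  per <- data.frame(loss = numeric(n), mae = numeric(n), mse = numeric(n),
                    cc = numeric(n), ssim = numeric(n))
  for (i in seq_len(n)) {
    y <- targets[i, ]; yh <- predictions[i, ]
    per$loss[i] <- huber_loss(y, yh, delta)
    per$mae[i] <- mae(y, yh)
    per$mse[i] <- mse(y, yh)
    per$cc[i] <- as.numeric(pearson_cc(y, yh))
    per$ssim[i] <- ssim(y, yh, ssim_p)
  }
  cc_ok <- !is.na(per$cc)
  means <- c(loss = mean(per$loss), mae = mean(per$mae), mse = mean(per$mse),
             cc = mean(per$cc[cc_ok]), ssim = mean(per$ssim))
  structure(list(per_sample = per, means = means,
                 cc_excluded = sum(!cc_ok)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>  (means over",
      nrow(x$per_sample), "samples)\n")
  print(round(x$means, 5))
  if (x$cc_excluded > 0)
    cat(sprintf("  [%d degenerate CC samples excluded]\n", x$cc_excluded))
  invisible(x)
}

#' Evaluate a reconstruction model on a sample set
#'
#' Reconstructs every signal and scores the predictions against the
#' ground-truth coarse conductivity vectors.
#'
#' @param model a trained `mit_model` (see [build_model()]).
#' @param signals `N x p` raw (unstandardized) differential signals.
#' @param targets `N x n_coarse` ground-truth vectors.
#' @param delta Huber threshold for the report.
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, signals, targets, delta = 0.05) {
  preds <- reconstruct(model, signals)$vectors
  metrics_report(targets, preds, delta = delta)
}

#' Build the two synthetic robustness cases
#'
#' Case 1: two deliberately overlapping cuboids (sigma = 0 S/m) forming one
#' non-cuboid object with a chosen maximum extent (13 cm at torso scale) in
#' the central region of the body — a shape class absent from training.
#' Case 2: a single cuboid with an unseen conductivity (0.8 S/m). Both are
#' simulated through the standard forward + noise + coarsening path.
#'
#' @param caches a `scan_cache` on the fine grid.
#' @param dconfig the `dataset_config` (for noise level and coarsening).
#' @param params `physics_params`.
#' @param max_extent_cm long-axis extent of the overlap union.
#' @param case2_sigma unseen conductivity for case 2.
#' @param edge_cm base cuboid edge for both cases (default 8).
#' @return list of two samples, each with `signal` (flattened differential),
#'   `target` (flattened coarse truth), `label`.
#' @export
make_special_cases <- function(caches, dconfig, params = physics_params(),
                               max_extent_cm = 13, case2_sigma = 0.8,
                               edge_cm = 8) {
  grid <- caches$grid
  bg <- conductivity_grid(grid, dconfig$background)
  S_norm <- scan_body(bg, caches, params)
  center <- grid$extent_cm / 2
  build <- function(perts, label) {
    sig <- array(dconfig$background, grid$shape)
    for (p in perts) sig <- paint_cuboid(sig, grid, p)
    fine <- conductivity_grid(grid, sig)
    S_E <- scan_body(fine, caches, params)
    S_D <- differential_signal(S_E, S_norm, snr_db = dconfig$snr_db)
    list(signal = flatten_signal(S_D),
         target = flatten_fortran(coarsen(fine, dconfig$coarsen_factor)),
         label = label, fine = fine)
  }
  # case 1: two cuboids of edge `edge_cm`, offset along x so their union
  # spans max_extent_cm; overlap = 2*edge - extent
  shift <- max_extent_cm - edge_cm
  if (shift <= 0 || shift >= edge_cm)
    stop("max_extent_cm must lie in (edge_cm, 2 * edge_cm)")
  o1 <- round(center - edge_cm / 2); o1[1] <- round(center[1] - max_extent_cm / 2)
  o2 <- o1; o2[1] <- o1[1] + shift
  case1 <- build(list(cuboid_perturbation(o1, rep(edge_cm, 3), 0.0),
                      cuboid_perturbation(o2, rep(edge_cm, 3), 0.0)),
                 "overlap-union")
  # case 2: one centred cuboid with the unseen conductivity
  oc <- round(center - edge_cm / 2)
  case2 <- build(list(cuboid_perturbation(oc, rep(edge_cm, 3), case2_sigma)),
                 sprintf("sigma-%g", case2_sigma))
  list(case1, case2)
}
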