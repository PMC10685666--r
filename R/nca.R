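#' Non-compartmental analysis of a concentration-time profile
#'
#' Model-free metrics: Cmax/Tmax read off the grid; AUC0-t by the linear
#' trapezoidal rule to the last observation; the terminal slope `lambda_z`
#' by log-linear regression over a tail chosen by the terminal rule (default:
#' among all tails of >= `min_points` positive concentrations strictly after
#' Tmax, the one with the best adjusted R-squared); and
#' `AUC0-inf = AUC0-t + C_last / lambda_z`. When no valid terminal phase
#' exists the extrapolated quantities are returned as `NA` rather than
#' erroring.
#'
#' @param profile a [plasma_profile()] with >= 3 positive concentrations.
#' @param min_points minimum tail length for the terminal regression.
#' @return object of class `nca_metrics`: `cmax` (ug/L), `tmax` (h),
#'   `auc_t`, `auc_inf` (ug*h/L), `lambda_z` (1/h), `t_half_z` (h),
#'   `pct_extrapolated` (%), `n_lambda` (points used).
#' @export
compute_nca <- function(profile, min_points = 3L) {
  stopifnot(inherits(profile, "plasma_profile"))
  t <- profile$time_h; y <- profile$conc_ug_per_L
  if (sum(y > 0) < 3L) stopf("need at least 3 positive concentrations")
  cmax <- max(y)
  tmax <- t[which.max(y)]
  auc_t <- trapz(t, y)
  # terminal regression on positive tail strictly after Tmax
  cand <- which(t > tmax & y > 0)
  lambda_z <- NA_real_; n_lambda <- NA_integer_
  if (length(cand) >= min_points) {
    ks <- seq(min_points, length(cand))
    res <- lapply(ks, function(k) {
      idx <- tail(cand, k)
      fit <- lm(log(y[idx]) ~ t[idx])
      slope <- unname(coef(fit)[2])
      if (!is.finite(slope) || slope >= 0) return(NULL)
      r2 <- 1 - sum(fit$residuals^2) /
        max(sum((log(y[idx]) - mean(log(y[idx])))^2), .Machine$double.eps)
      list(k = k, slope = slope, r2adj = 1 - (1 - r2) * (k - 1) / (k - 2))
    })
    res <- res[!vapply(res, is.null, TRUE)]
    if (length(res)) {
      r2s <- vapply(res, `[[`, 0, "r2adj")
      # ties within 1e-4 of the best adjusted fit go to the longest tail
      best <- res[[max(which(r2s >= max(r2s) - 1e-4))]]
      lambda_z <- -best$slope; n_lambda <- best$k
    }
  }
  y_last <- tail(y[y > 0], 1)
  if (is.finite(lambda_z)) {
    auc_inf <- auc_t + y_last / lambda_z
    pct_extra <- 100 * (auc_inf - auc_t) / auc_inf
    t_half_z <- log(2) / lambda_z
  } else {
    auc_inf <- NA_real_; pct_extra <- NA_real_; t_half_z <- NA_real_
  }
  structure(list(cmax = cmax, tmax = tmax, auc_t = auc_t, auc_inf = auc_inf,
                 lambda_z = lambda_z, t_half_z = t_half_z,
                 pct_extrapolated = pct_extra, n_lambda = n_lambda),
            class = "nca_metrics")
}

#' @export
print.nca_metrics <- function(x, ...) {
  cat(sprintf("NCA: Cmax %.4g ug/L at %.3g h; AUC0-t %.4g, AUC0-inf %s ug*h/L\n",
              x$cmax, x$tmax, x$auc_t,
              if (is.na(x$auc_inf)) "NA" else sprintf("%.4g", x$auc_inf)))
  if (!is.na(x$lambda_z))
    cat(sprintf("  lambda_z %.4g 1/h (t1/2 %.3g h, %d pts, %.2f%% extrapolated)\n",
                x$lambda_z, x$t_half_z, x$n_lambda, x$pct_extrapolated))
  invisible(x)
}

#' Predicted/observed metric ratios with a two-fold verdict
#'
#' Per-metric ratios predicted/observed for Cmax, AUC0-t and AUC0-inf, and
#' the conventional model-verification verdict that every ratio lies within
#' two-fold (0.5 to 2.0).
#'
#' @param pred,obs [compute_nca()] results (or named lists with `cmax`,
#'   `auc_t`, `auc_inf`).
#' @return list: `ratios` (named numeric), `within_twofold` (per metric),
#'   `verdict` (all metrics within two-fold).
#' @export
pred_obs_ratio <- function(pred, obs) {
  metrics <- c("cmax", "auc_t", "auc_inf")
  p <- unlist(pred[metrics]); o <- unlist(obs[metrics])
  if (any(!is.finite(p)) || any(!is.finite(o)))
    stopf("both metric sets must be complete (finite cmax, auc_t, auc_inf)")
  if (any(o == 0)) stopf("observed metrics must be non-zero")
  ratios <- setNames(p / o, metrics)
  within <- ratios >= 0.5 & ratios <= 2.0
  list(ratios = ratios, within_twofold = within, verdict = all(within))
}
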