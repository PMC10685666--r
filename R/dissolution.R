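#' In-vitro dissolution profile
#'
#' Cumulative percent dissolved versus time for one formulation in one
#' medium, stored as raw assay means (values up to 105% are tolerated for
#' assay overshoot and clamped to 100 only at use time). Means may decrease
#' by at most `tol_decrease` percentage points between adjacent samples.
#'
#' @param times_min sampling times, min; positive, increasing.
#' @param mean_pct mean percent dissolved per time (0..105).
#' @param sd_pct standard deviation per time, percentage points.
#' @param medium_ph dissolution medium pH (conventionally 1.2, 4.5 or 6.8).
#' @param n_units number of dosage units averaged (conventionally 6).
#' @param tol_decrease allowed non-monotonicity, percentage points.
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times_min, mean_pct, sd_pct = 0,
                                medium_ph = NA_real_, n_units = 6L,
                                tol_decrease = 2) {
  if (length(times_min) == 0L) stopf("empty dissolution profile")
  if (length(mean_pct) != length(times_min))
    stopf("times_min and mean_pct must have equal length")
  if (any(times_min <= 0) || any(diff(times_min) <= 0))
    stopf("times_min must be positive and strictly increasing")
  if (any(mean_pct < 0 | mean_pct > 105))
    stopf("mean_pct must lie in [0, 105] (assay overshoot tolerance)")
  if (any(diff(mean_pct) < -tol_decrease))
    stopf("mean_pct decreases by more than %g points between samples",
          tol_decrease)
  sd_pct <- rep_len(sd_pct, length(times_min))
  if (any(sd_pct < 0)) stopf("sd_pct must be >= 0")
  structure(list(times_min = as.numeric(times_min),
                 mean_pct = as.numeric(mean_pct),
                 sd_pct = sd_pct, medium_ph = medium_ph,
                 n_units = as.integer(n_units)),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("dissolution profile (pH %s, n = %d units): %d points, %s\n",
              format(x$medium_ph), x$n_units, length(x$times_min),
              sprintf("%.1f%% at %g min", tail(x$mean_pct, 1),
                      tail(x$times_min, 1))))
  invisible(x)
}

# clamped, monotonized fractions used by every consumer
profile_fractions <- function(profile) {
  cummax(pmin(profile$mean_pct, 100)) / 100
}

#' Fraction dissolved at arbitrary times
#'
#' Monotone piecewise-linear interpolant anchored at (0 min, 0), clamped at
#' the observed plateau beyond the last sample.
#'
#' @param profile a [dissolution_profile()].
#' @param t_min times, min (>= 0); vectorized.
#' @return fractions in \[0, 1\].
#' @export
release_fraction <- function(profile, t_min) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (any(t_min < 0)) stopf("t_min must be >= 0")
  f <- profile_fractions(profile)
  approx(c(0, profile$times_min), c(0, f), xout = t_min, rule = 2)$y
}

#' Instantaneous dissolution hazard implied by a profile
#'
#' The rate at which remaining solid dissolves, `h(t) = f'(t) / (1 - f(t))`,
#' from the piecewise-linear interpolant. The hazard is capped at `cap`
#' (1/min) as the profile approaches completion. Beyond the last sampled
#' time, if release is complete (within `plateau_tol` of 1) the hazard is 0;
#' otherwise the final in-segment hazard is held constant, a first-order
#' continuation of the observed tail so that an incompletely sampled profile
#' still releases its remaining drug rather than freezing it.
#'
#' @inheritParams release_fraction
#' @param cap hazard ceiling, 1/min.
#' @param plateau_tol completeness tolerance on the final fraction.
#' @return hazards, 1/min.
#' @export
release_hazard <- function(profile, t_min, cap = 1, plateau_tol = 1e-3) {
  stopifnot(inherits(profile, "dissolution_profile"))
  f <- profile_fractions(profile)
  tk <- c(0, profile$times_min)
  fk <- c(0, f)
  slopes <- diff(fk) / diff(tk)               # per segment
  f_last <- tail(fk, 1)
  # hazard inside the last segment (used for tail continuation)
  haz_seg <- function(i, t) {
    if (slopes[i] <= 0) return(0)
    ft <- fk[i] + slopes[i] * (t - tk[i])
    if (ft >= 1 - 1e-12) return(cap)
    min(slopes[i] / (1 - ft), cap)
  }
  n_seg <- length(slopes)
  tail_h <- if (f_last >= 1 - plateau_tol) 0 else
    haz_seg(n_seg, tail(tk, 1))
  vapply(t_min, function(t) {
    if (t < 0) stopf("t_min must be >= 0")
    if (t >= tail(tk, 1)) return(if (f_last >= 1 - plateau_tol) 0 else tail_h)
    i <- findInterval(t, tk, rightmost.closed = TRUE)
    i <- max(min(i, n_seg), 1L)
    haz_seg(i, t)
  }, 0)
}

#' Fit a Weibull release model to a dissolution profile
#'
#' Least-squares fit of `f(t) = fmax * (1 - exp(-(t/mdt)^b))` (percent scale)
#' by Levenberg-Marquardt with a deterministic start heuristic (`fmax` from
#' the plateau, `mdt` from the 63.2% crossing, `b = 1`).
#'
#' @param profile a [dissolution_profile()] with >= 4 points.
#' @return list with `fmax` (%), `mdt` (min), `b` (shape), `rmse` (%), and
#'   `fitted` (% at the profile times).
#' @export
weibull_fit <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  t <- profile$times_min
  y <- pmin(profile$mean_pct, 100)
  if (length(t) < 4L) stopf("need at least 4 points for a Weibull fit")
  fmax0 <- max(max(y), 1)
  frac <- y / fmax0
  i <- which(frac >= 0.632)[1]
  mdt0 <- if (is.na(i)) max(t) else if (i == 1) t[1] else
    approx(frac[c(i - 1, i)], t[c(i - 1, i)], xout = 0.632)$y
  fit <- try(minpack.lm::nlsLM(
    y ~ fmax * (1 - exp(-(t / mdt)^b)),
    start = list(fmax = fmax0, mdt = max(mdt0, 0.5), b = 1),
    lower = c(fmax = 1, mdt = 0.05, b = 0.1),
    upper = c(fmax = 110, mdt = 1e4, b = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stopf("Weibull fit failed to converge: %s", attr(fit, "condition")$message)
  cf <- coef(fit)
  fitted_pct <- cf[["fmax"]] * (1 - exp(-(t / cf[["mdt"]])^cf[["b"]]))
  list(fmax = cf[["fmax"]], mdt = cf[["mdt"]], b = cf[["b"]],
       rmse = sqrt(mean((y - fitted_pct)^2)), fitted = fitted_pct)
}

#' Smooth Weibull release input
#'
#' An analytic release curve `f(t) = (fmax/100) * (1 - exp(-(t/mdt)^b))`
#' usable wherever a [dissolution_profile()] is accepted as an oral-model
#' release input; its hazard is exact rather than interpolated.
#'
#' @param fmax plateau, percent.
#' @param mdt mean dissolution time parameter, min.
#' @param b shape (b = 1 is first-order release).
#' @return object of class `weibull_release`.
#' @export
weibull_release <- function(fmax = 100, mdt = 10, b = 1) {
  check_scalar(fmax, "fmax", 0, 105, strict_lower = TRUE)
  check_scalar(mdt, "mdt", 0, strict_lower = TRUE)
  check_scalar(b, "b", 0, strict_lower = TRUE)
  structure(list(fmax = fmax, mdt = mdt, b = b), class = "weibull_release")
}

weibull_fraction <- function(w, t_min) {
  (w$fmax / 100) * (1 - exp(-(pmax(t_min, 0) / w$mdt)^w$b))
}

weibull_hazard <- function(w, t_min, cap = 1) {
  # h = F'/(1-F) with F the fraction of the *dose*; if fmax < 100 the
  # remaining fraction never dissolves and the hazard tends to a finite limit
  t <- pmax(t_min, 1e-9)
  Fd <- weibull_fraction(w, t)
  dens <- (w$fmax / 100) * exp(-(t / w$mdt)^w$b) * w$b *
    (t / w$mdt)^(w$b - 1) / w$mdt
  pmin(dens / pmax(1 - Fd, 1e-9), cap)
}

#' f2 similarity factor between two dissolution profiles
#'
#' `f2 = 50 * log10(100 / sqrt(1 + mean((R - T)^2)))` on the mean percent
#' curves over the common time grid. Values >= 50 conventionally denote
#' similarity. Optionally truncates time points after both profiles exceed
#' 85% (regulatory convention; off by default so the full grid is used).
#'
#' @param ref,test [dissolution_profile()] objects on identical time grids
#'   with at least 3 common points.
#' @param truncate_after_85 drop points after both curves exceed 85%?
#' @return the f2 value (100 for identical profiles).
#' @export
f2_similarity <- function(ref, test, truncate_after_85 = FALSE) {
  stopifnot(inherits(ref, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(ref$times_min) != length(test$times_min) ||
      any(ref$times_min != test$times_min))
    stopf("profiles must share an identical time grid")
  r <- pmin(ref$mean_pct, 100)
  t_ <- pmin(test$mean_pct, 100)
  if (truncate_after_85) {
    over <- r > 85 & t_ > 85
    first_over <- which(over)[1]
    if (!is.na(first_over) && first_over < length(r)) {
      keep <- seq_len(first_over)
      r <- r[keep]; t_ <- t_[keep]
    }
  }
  if (length(r) < 3L) stopf("need at least 3 common time points")
  50 * log10(100 / sqrt(1 + mean((r - t_)^2)))
}

#' Is a profile rapidly dissolving?
#'
#' TRUE iff the interpolated mean exceeds 85% strictly at 15 min (the
#' biowaiver convention for very-rapid/rapid classification boundaries).
#'
#' @inheritParams release_fraction
#' @return logical.
#' @export
rapid_dissolution <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (max(profile$times_min) < 15)
    stopf("profile must cover t = 15 min")
  release_fraction(profile, 15) > 0.85
}

#' R-squared between predicted and observed plasma curves
#'
#' The predicted curve is linearly interpolated onto the observed sampling
#' grid and compared by [r_squared()]; used to score how well a
#' dissolution-driven simulation tracks an observed profile.
#'
#' @param predicted,observed [plasma_profile()] objects; observed times must
#'   lie within the predicted time support, with >= 3 common points.
#' @return unitless R-squared.
#' @export
profile_correlation_r2 <- function(predicted, observed) {
  stopifnot(inherits(predicted, "plasma_profile"),
            inherits(observed, "plasma_profile"))
  if (nrow(observed) < 3L) stopf("need at least 3 observed points")
  if (min(observed$time_h) < min(predicted$time_h) - 1e-9 ||
      max(observed$time_h) > max(predicted$time_h) + 1e-9)
    stopf("observed times must lie within the predicted time support")
  pred_on_obs <- approx(predicted$time_h, predicted$conc_ug_per_L,
                        xout = observed$time_h)$y
  r_squared(observed$conc_ug_per_L, pred_on_obs)
}
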