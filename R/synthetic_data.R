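# Seeded generators that emulate the study inputs that are never published
# with papers of this kind: unit-level dissolution curves and single-dose
# oral plasma datasets with known ground truth.

#' Generate a synthetic dissolution profile
#'
#' Emulates a mean dissolution curve from `n_units` dosage units: each unit
#' follows a Weibull release curve `fmax * (1 - exp(-(t/mdt)^b))` with
#' additive assay noise (`noise_sd` percentage points, truncated to
#' \[0, 105\]); unit curves are monotonized (cumulative maximum, as cumulative
#' release cannot decrease) and averaged. Deterministic given the seed. The
#' default grid is the conventional immediate-release sampling schedule
#' (5, 10, 15, 20, 35, 45, 60 min).
#'
#' @param fmax,mdt_min,b Weibull parameters (% plateau, time scale in min,
#'   shape).
#' @param noise_sd per-sample assay noise SD, percentage points.
#' @param times_min sampling grid, min.
#' @param n_units number of units averaged.
#' @param medium_ph label for the dissolution medium.
#' @param seed RNG seed.
#' @return a [dissolution_profile()] with the generating parameters attached
#'   as attribute `truth`.
#' @export
synth_dissolution_profile <- function(fmax = 100, mdt_min = 10, b = 1.2,
                                      noise_sd = 2,
                                      times_min = c(5, 10, 15, 20, 35, 45, 60),
                                      n_units = 6, medium_ph = 4.5,
                                      seed = 1) {
  check_scalar(noise_sd, "noise_sd", 0)
  w <- weibull_release(fmax, mdt_min, b)
  truth_pct <- 100 * weibull_fraction(w, times_min)
  mean_pct <- with_seed(seed, {
    units <- replicate(n_units, {
      y <- truth_pct + rnorm(length(times_min), 0, noise_sd)
      cummax(pmin(pmax(y, 0), 105))
    })
    rowMeans(units)
  })
  sd_pct <- if (noise_sd == 0) rep(0, length(times_min)) else {
    # recompute per-unit spread for the SD column
    with_seed(seed, {
      units <- replicate(n_units, {
        y <- truth_pct + rnorm(length(times_min), 0, noise_sd)
        cummax(pmin(pmax(y, 0), 105))
      })
      apply(units, 1, sd)
    })
  }
  prof <- dissolution_profile(times_min, mean_pct, sd_pct,
                              medium_ph = medium_ph, n_units = n_units)
  attr(prof, "truth") <- list(fmax = fmax, mdt_min = mdt_min, b = b,
                              noise_sd = noise_sd, seed = seed)
  prof
}

#' Generate synthetic single-dose oral plasma datasets with known truth
#'
#' Simulates the oral compartment model (first-order absorption into the
#' given disposition model) on a sampling grid and perturbs each
#' concentration with lognormal proportional error of the given CV,
#' producing one profile per subject. The generating parameters are attached
#' for recovery studies.
#'
#' @param disp a [disposition_params()] (the ground truth).
#' @param ka true first-order absorption rate, 1/h.
#' @param dose_mg dose, mg.
#' @param times sampling grid, h.
#' @param prop_cv proportional residual CV (0 for noise-free).
#' @param n_subjects number of replicate subjects.
#' @param tlag true absorption lag, h.
#' @param seed RNG seed.
#' @return list of [plasma_profile()] objects (one per subject) with
#'   attribute `truth`.
#' @export
synth_plasma_dataset <- function(disp, ka, dose_mg = 20,
                                 times = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4,
                                           6, 8, 12, 16, 24, 36, 48),
                                 prop_cv = 0.1, n_subjects = 1, tlag = 0,
                                 seed = 1) {
  stopifnot(inherits(disp, "disposition_params"))
  check_scalar(prop_cv, "prop_cv", 0)
  mu <- oral_model_conc(disp, ka, tlag, dose_mg, times)
  sdlog <- sqrt(log(1 + prop_cv^2))
  profs <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    y <- if (prop_cv == 0) mu else mu * rlnorm(length(mu), 0, sdlog)
    plasma_profile(times, y, dose_mg = dose_mg,
                   label = sprintf("synthetic subject %d", s))
  }))
  attr(profs, "truth") <- list(disp = disp, ka = ka, tlag = tlag,
                               dose_mg = dose_mg, prop_cv = prop_cv,
                               seed = seed)
  profs
}

#' Construct a test formulation achieving a target exposure ratio
#'
#' Builds a test-formulation dissolution curve by slowing the reference
#' Weibull time scale (`mdt * s`), searching the scaling `s` so that the
#' mechanistically simulated test/reference ratio of the target metric is
#' within `tol` of `target_ratio`. Only Cmax can be moved this way when
#' absorption is complete: under apparent-clearance (linear) disposition,
#' AUC0-inf equals `F * dose / CL`, so with the absorbed fraction pinned
#' near 1 a requested AUC ratio away from 1 is unattainable and raises an
#' error explaining why.
#'
#' @inheritParams simulate_oral
#' @param ref_weibull a [weibull_release()] describing the reference
#'   formulation.
#' @param target_ratio desired test/reference metric ratio, in (0.5, 2).
#' @param metric `"cmax"` or `"auc_inf"`.
#' @param tol acceptance tolerance on the realized ratio.
#' @param s_max largest allowed slowing factor.
#' @return list: `ref`, `test` ([weibull_release()] objects),
#'   `realized_ratio`, `scaling`, and the two simulations.
#' @export
make_formulation_pair <- function(compound, acat, disp,
                                  ref_weibull = weibull_release(100, 6, 1.5),
                                  target_ratio = 0.9,
                                  metric = c("cmax", "auc_inf"),
                                  times = seq(0, 72, by = 0.05),
                                  tol = 0.02, s_max = 60) {
  metric <- match.arg(metric)
  if (target_ratio <= 0.5 || target_ratio >= 2)
    stopf("target_ratio must lie in (0.5, 2)")
  sim_ref <- simulate_oral(compound, acat, disp, ref_weibull, times)
  m_ref <- compute_nca(sim_ref$plasma)
  if (metric == "auc_inf" && sim_ref$fraction_absorbed >= 0.95 &&
      acat$hepatic_mode == "apparent" && abs(target_ratio - 1) > tol)
    stopf(paste("target AUC ratio %.3g is unattainable by dissolution-rate",
                "changes: with complete absorption (F = %.3f) and apparent",
                "clearance, AUC0-inf = dose/CL regardless of release rate;",
                "only Cmax can move. Use an explicit bioavailability",
                "multiplier for AUC differences."),
          target_ratio, sim_ref$fraction_absorbed)
  ratio_at <- function(s) {
    tw <- weibull_release(ref_weibull$fmax, ref_weibull$mdt * s,
                          ref_weibull$b)
    sim <- simulate_oral(compound, acat, disp, tw, times)
    m <- compute_nca(sim$plasma)
    list(ratio = unlist(m[metric]) / unlist(m_ref[metric]), sim = sim,
         release = tw)
  }
  if (abs(target_ratio - 1) <= tol) {
    r1 <- ratio_at(1)
    return(list(ref = ref_weibull, test = r1$release,
                realized_ratio = unname(r1$ratio), scaling = 1,
                sim_ref = sim_ref, sim_test = r1$sim))
  }
  if (target_ratio > 1)
    stopf("slowing the test formulation can only reduce %s; %s", metric,
          "target ratios > 1 are not reachable from this reference")
  f <- function(s) ratio_at(s)$ratio - target_ratio
  lo <- 1; hi <- 2
  while (f(hi) > 0 && hi < s_max) hi <- hi * 2
  if (f(min(hi, s_max)) > 0)
    stopf("target ratio %.3g not reached even at scaling %g; %s",
          target_ratio, s_max,
          "the metric is insensitive to dissolution rate in this model")
  root <- uniroot(f, c(lo, min(hi, s_max)), tol = 1e-3)
  res <- ratio_at(root$root)
  if (abs(res$ratio - target_ratio) > tol)
    stopf("search finished %.4g away from the target ratio (tol %.3g)",
          abs(res$ratio - target_ratio), tol)
  list(ref = ref_weibull, test = res$release,
       realized_ratio = unname(res$ratio), scaling = root$root,
       sim_ref = sim_ref, sim_test = res$sim)
}
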