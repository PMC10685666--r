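#' Virtual population specification for crossover trials
#'
#' Describes the between/within-subject variability applied multiplicatively
#' to model-predicted exposure metrics. For each metric `m` with total
#' fractional CV `cv_m`, the log-variance is `sigma2 = ln(1 + cv^2)`; each
#' subject carries a shared (between-subject) lognormal factor with variance
#' `w * sigma2` and each administration period an independent residual with
#' variance `(1 - w) * sigma2`, so the total CV of a single observation is
#' `cv_m`. In a paired crossover the shared factor cancels and only the
#' residual variance drives the confidence interval width.
#'
#' @param n_subjects subjects per trial (default 46).
#' @param cv_cmax total fractional CV applied to Cmax (default 0.40).
#' @param cv_auc total fractional CV applied to AUC0-t and AUC0-inf
#'   (default 0.15).
#' @param w within-subject split: fraction of the log-variance that is
#'   between-subject (default 0.5).
#' @param seed RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 46, cv_cmax = 0.40, cv_auc = 0.15,
                            w = 0.5, seed = 1) {
  if (n_subjects < 2) stopf("need at least 2 subjects")
  check_scalar(cv_cmax, "cv_cmax", 0, strict_lower = TRUE)
  check_scalar(cv_auc, "cv_auc", 0, strict_lower = TRUE)
  check_scalar(w, "w", 0, 1)
  structure(list(n_subjects = as.integer(n_subjects), cv_cmax = cv_cmax,
                 cv_auc = cv_auc, w = w, seed = seed),
            class = "population_spec")
}

be_metric_names <- c("cmax", "auc_t", "auc_inf")

#' Generate subject variability multipliers
#'
#' Draws, for each subject and metric, the shared between-subject factor and
#' the two per-period residual factors described in [population_spec()].
#' Deterministic given the seed.
#'
#' @param spec a [population_spec()].
#' @return list with arrays `eta` (subjects x metrics) and `eps`
#'   (subjects x 2 periods x metrics), all lognormal multipliers with median
#'   1, plus the spec.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_subjects
  sigma2 <- c(cmax = log(1 + spec$cv_cmax^2),
              auc_t = log(1 + spec$cv_auc^2),
              auc_inf = log(1 + spec$cv_auc^2))
  # standard-normal draws are made explicitly and scaled afterwards, so the
  # RNG stream is identical across CV and w settings (w only rescales)
  with_seed(spec$seed, {
    eta <- sapply(be_metric_names, function(m)
      exp(sqrt(spec$w * sigma2[[m]]) * rnorm(n)))
    eps <- array(NA_real_, c(n, 2, 3),
                 dimnames = list(NULL, c("ref", "test"), be_metric_names))
    for (m in be_metric_names) for (f in 1:2)
      eps[, f, m] <- exp(sqrt((1 - spec$w) * sigma2[[m]]) * rnorm(n))
    list(eta = matrix(eta, n, 3, dimnames = list(NULL, be_metric_names)),
         eps = eps, spec = spec)
  })
}

as_be_metrics <- function(x, what) {
  if (inherits(x, "oral_sim")) x <- compute_nca(x$plasma)
  if (inherits(x, "nca_metrics") || is.list(x)) x <- unlist(x[be_metric_names])
  if (is.numeric(x) && !is.null(names(x))) x <- x[be_metric_names]
  if (length(x) != 3L || any(!is.finite(x)) || any(x <= 0))
    stopf("%s must provide finite positive cmax, auc_t and auc_inf", what)
  setNames(as.numeric(x), be_metric_names)
}

#' Run one virtual 2x2 crossover bioequivalence trial
#'
#' Each subject receives both formulations; the subject-period metric is the
#' model-predicted metric times the subject's shared factor times the period
#' residual. The analysis is the standard paired log-scale one: with
#' `d_s = ln(m_test,s) - ln(m_ref,s)` (the shared factor cancels),
#' `GMR = 100 * exp(mean d)` and the 90% CI is
#' `100 * exp(mean d -+ t(0.95, n-1) * sd(d) / sqrt(n))`. A metric passes iff
#' its CI lies inside \[80.00, 125.00\] inclusive; the trial passes iff all
#' three metrics pass. Pass/fail is computed on unrounded values. With zero
#' residual variance the CI degenerates to the point GMR.
#'
#' @param metrics_ref,metrics_test model-predicted metrics for the reference
#'   and test formulation: an [oral_sim] result, an [nca_metrics] object, or
#'   a named vector with `cmax`, `auc_t`, `auc_inf`.
#' @param population a [generate_population()] result.
#' @return object of class `be_trial`: per-metric data.frame `table`
#'   (`gmr_pct`, `ci90_lo_pct`, `ci90_hi_pct`, `pass`), `overall_pass`, and
#'   the per-subject metric array `subject_metrics`.
#' @export
run_crossover_trial <- function(metrics_ref, metrics_test, population) {
  mr <- as_be_metrics(metrics_ref, "metrics_ref")
  mt <- as_be_metrics(metrics_test, "metrics_test")
  eta <- population$eta; eps <- population$eps
  n <- nrow(eta)
  subj <- array(NA_real_, c(n, 2, 3),
                dimnames = list(NULL, c("ref", "test"), be_metric_names))
  tab <- data.frame(metric = be_metric_names, gmr_pct = NA_real_,
                    ci90_lo_pct = NA_real_, ci90_hi_pct = NA_real_,
                    pass = NA)
  for (j in seq_along(be_metric_names)) {
    m <- be_metric_names[j]
    subj[, "ref", j] <- mr[[m]] * eta[, j] * eps[, "ref", m]
    subj[, "test", j] <- mt[[m]] * eta[, j] * eps[, "test", m]
    d <- log(subj[, "test", j]) - log(subj[, "ref", j])
    mu <- mean(d); s <- sd(d)
    half <- if (s == 0) 0 else qt(0.95, n - 1) * s / sqrt(n)
    lo <- 100 * exp(mu - half); hi <- 100 * exp(mu + half)
    tab$gmr_pct[j] <- 100 * exp(mu)
    tab$ci90_lo_pct[j] <- lo
    tab$ci90_hi_pct[j] <- hi
    tab$pass[j] <- lo >= 80 & hi <= 125
  }
  structure(list(table = tab, overall_pass = all(tab$pass),
                 subject_metrics = subj, n_subjects = n),
            class = "be_trial")
}

#' @export
print.be_trial <- function(x, ...) {
  cat(sprintf("virtual 2x2 crossover, n = %d: %s\n", x$n_subjects,
              if (x$overall_pass) "BE PASS" else "BE FAIL"))
  t2 <- x$table
  t2[2:4] <- lapply(t2[2:4], function(v) sprintf("%.2f", v))
  print(t2, row.names = FALSE)
  invisible(x)
}

#' Run a series of independent virtual bioequivalence trials
#'
#' Repeats [run_crossover_trial()] with an independent population per trial
#' (seed = `base_seed + trial index`) and aggregates per-metric mean/min/max
#' of the GMR and CI bounds plus the pass count across trials.
#'
#' @inheritParams run_crossover_trial
#' @param spec a [population_spec()]; its seed field is overridden per trial.
#' @param n_trials number of repeated trials (default 10).
#' @param base_seed base RNG seed.
#' @return object of class `be_series`: `trials` (list of [be_trial]
#'   results), `pass_count`, `n_trials` and `summary` (per metric: mean,
#'   min, max of GMR and CI bounds).
#' @export
run_trial_series <- function(metrics_ref, metrics_test, spec,
                             n_trials = 10, base_seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (n_trials < 1) stopf("n_trials must be >= 1")
  trials <- lapply(seq_len(n_trials), function(i) {
    sp <- spec; sp$seed <- base_seed + i
    run_crossover_trial(metrics_ref, metrics_test, generate_population(sp))
  })
  agg <- lapply(c(gmr_pct = "gmr_pct", ci90_lo_pct = "ci90_lo_pct",
                  ci90_hi_pct = "ci90_hi_pct"), function(col) {
    vals <- sapply(trials, function(tr) setNames(tr$table[[col]],
                                                 tr$table$metric))
    data.frame(metric = rownames(vals), mean = rowMeans(vals),
               min = apply(vals, 1, min), max = apply(vals, 1, max),
               row.names = NULL)
  })
  structure(list(trials = trials,
                 pass_count = sum(vapply(trials, `[[`, TRUE, "overall_pass")),
                 n_trials = n_trials, summary = agg, spec = spec,
                 base_seed = base_seed),
            class = "be_series")
}

#' @export
print.be_series <- function(x, ...) {
  cat(sprintf("virtual BE series: %d trials, n = %d subjects each\n",
              x$n_trials, x$spec$n_subjects))
  fmt <- function(m, i) sprintf("%.2f (%.2f, %.2f)",
                                x$summary[[m]]$mean[i],
                                x$summary[[m]]$min[i], x$summary[[m]]$max[i])
  for (i in seq_along(be_metric_names))
    cat(sprintf("  %-8s GMR %s; 90%% CI %s to %s\n",
                x$summary$gmr_pct$metric[i], fmt("gmr_pct", i),
                fmt("ci90_lo_pct", i), fmt("ci90_hi_pct", i)))
  cat(sprintf("  in-silico BE judgment: %d / %d\n", x$pass_count, x$n_trials))
  invisible(x)
}

#' Mechanistic virtual bioequivalence study
#'
#' Simulates the reference and test formulations through the oral absorption
#' model with their respective dissolution inputs, extracts Cmax, AUC0-t and
#' AUC0-inf, then runs a repeated virtual crossover series. An optional
#' `test_bioavailability` multiplier scales the test arm's metrics, a
#' transparent device for exposure (AUC) differences that dissolution-rate
#' changes alone cannot produce when absorption is complete.
#'
#' @inheritParams simulate_oral
#' @param release_ref,release_test dissolution inputs for the two
#'   formulations.
#' @param spec a [population_spec()].
#' @param n_trials repeated trials (default 10).
#' @param test_bioavailability relative bioavailability multiplier applied
#'   to all test-arm metrics (default 1).
#' @return a [run_trial_series()] result with the two simulations attached
#'   as attributes `sim_ref` and `sim_test`.
#' @export
virtual_be_study <- function(compound, acat, disp, release_ref, release_test,
                             spec = population_spec(),
                             times = seq(0, 72, by = 0.05),
                             n_trials = 10, test_bioavailability = 1) {
  sim_ref <- simulate_oral(compound, acat, disp, release_ref, times)
  sim_test <- simulate_oral(compound, acat, disp, release_test, times)
  m_ref <- as_be_metrics(sim_ref, "reference simulation")
  m_test <- as_be_metrics(sim_test, "test simulation") * test_bioavailability
  out <- run_trial_series(m_ref, m_test, spec, n_trials = n_trials)
  attr(out, "sim_ref") <- sim_ref
  attr(out, "sim_test") <- sim_test
  attr(out, "model_ratio") <- m_test / m_ref
  out
}
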