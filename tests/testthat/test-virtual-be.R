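test_that("population multipliers honor the stated CVs", {
  # vanishing CV: all multipliers collapse to 1
  tiny <- generate_population(population_spec(n_subjects = 5,
                                              cv_cmax = 1e-9,
                                              cv_auc = 1e-9, seed = 1))
  expect_equal(max(abs(tiny$eta - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(tiny$eps - 1)), 0, tolerance = 1e-6)

  # lognormal moment check at n = 10000: total multiplier CV ~ 0.40
  big <- generate_population(population_spec(n_subjects = 10000,
                                             cv_cmax = 0.40, cv_auc = 0.15,
                                             seed = 42))
  total_cmax <- big$eta[, "cmax"] * big$eps[, "ref", "cmax"]
  expect_equal(sd(total_cmax) / mean(total_cmax), 0.40, tolerance = 0.02)
  total_auc <- big$eta[, "auc_t"] * big$eps[, "ref", "auc_t"]
  expect_equal(sd(total_auc) / mean(total_auc), 0.15, tolerance = 0.02)

  # default spec mirrors the published study set-up
  spec <- population_spec()
  expect_equal(spec$n_subjects, 46L)
  expect_equal(spec$cv_cmax, 0.40)
  expect_equal(spec$cv_auc, 0.15)

  # determinism: same seed reproduces, different seed differs
  a <- generate_population(population_spec(seed = 9))
  b <- generate_population(population_spec(seed = 9))
  c <- generate_population(population_spec(seed = 10))
  expect_identical(a$eta, b$eta)
  expect_false(identical(a$eta, c$eta))
})

test_that("identical formulations with zero variability give a point pass", {
  m <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  pop <- generate_population(population_spec(n_subjects = 12,
                                             cv_cmax = 1e-9, cv_auc = 1e-9,
                                             seed = 1))
  tr <- run_crossover_trial(m, m, pop)
  expect_equal(tr$table$gmr_pct, rep(100, 3), tolerance = 1e-4)
  expect_equal(tr$table$ci90_lo_pct, tr$table$gmr_pct, tolerance = 1e-3)
  expect_true(tr$overall_pass)
})

test_that("the confidence interval equals the hand-computed t-interval", {
  m_ref <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  m_test <- m_ref * 0.93
  pop <- generate_population(population_spec(n_subjects = 4, seed = 77))
  tr <- run_crossover_trial(m_ref, m_test, pop)
  # independent oracle: unroll the four subjects' log-ratios per metric
  for (j in 1:3) {
    d <- log(tr$subject_metrics[, "test", j]) -
      log(tr$subject_metrics[, "ref", j])
    half <- qt(0.95, 3) * sd(d) / 2
    expect_equal(tr$table$gmr_pct[j], 100 * exp(mean(d)), tolerance = 1e-12)
    expect_equal(tr$table$ci90_lo_pct[j], 100 * exp(mean(d) - half),
                 tolerance = 1e-12)
    expect_equal(tr$table$ci90_hi_pct[j], 100 * exp(mean(d) + half),
                 tolerance = 1e-12)
  }
})

test_that("a large true shift fails bioequivalence", {
  m <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  pop <- generate_population(population_spec(n_subjects = 46, seed = 5))
  tr <- run_crossover_trial(m, m * 0.70, pop)
  expect_false(tr$overall_pass)
  expect_true(all(tr$table$ci90_hi_pct < 100))
})

test_that("trial series aggregates pass counts and summaries", {
  m <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  spec_tiny <- population_spec(cv_cmax = 0.01, cv_auc = 0.01, seed = 1)
  s <- run_trial_series(m, m, spec_tiny, n_trials = 10, base_seed = 1)
  expect_equal(s$pass_count, 10)

  spec_paper <- population_spec(seed = 1)
  s2 <- run_trial_series(m, m * 0.75, spec_paper, n_trials = 10,
                         base_seed = 1)
  expect_equal(s2$pass_count, 0)

  s3 <- run_trial_series(m, m * 0.90, spec_paper, n_trials = 10,
                         base_seed = 1)
  expect_s3_class(s3, "be_series")
  expect_true(all(c("gmr_pct", "ci90_lo_pct", "ci90_hi_pct") %in%
                    names(s3$summary)))
  expect_true(all(s3$summary$gmr_pct$min <= s3$summary$gmr_pct$mean &
                    s3$summary$gmr_pct$mean <= s3$summary$gmr_pct$max))
  expect_true(s3$pass_count >= 0 && s3$pass_count <= 10)
  expect_output(print(s3), "BE judgment")
})

test_that("the shared subject factor cancels except through residual variance", {
  m_ref <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  m_test <- m_ref * 0.92
  d_of <- function(w) {
    pop <- generate_population(population_spec(n_subjects = 20, w = w,
                                               seed = 31))
    tr <- run_crossover_trial(m_ref, m_test, pop)
    log(tr$subject_metrics[, "test", 1]) - log(tr$subject_metrics[, "ref", 1])
  }
  d0 <- d_of(0)     # all variance in the residual
  d6 <- d_of(0.6)   # same normal draws, residual sd scaled by sqrt(0.4)
  scale <- sqrt((1 - 0.6) / (1 - 0))
  expect_equal(d6 - log(0.92), (d0 - log(0.92)) * scale, tolerance = 1e-10)
})

test_that("CI half-width shrinks as one over the square root of n", {
  m <- c(cmax = 10, auc_t = 55, auc_inf = 56)
  half_width <- function(n) {
    hw <- sapply(1:30, function(s) {
      pop <- generate_population(population_spec(n_subjects = n, seed = 200 + s))
      tr <- run_crossover_trial(m, m, pop)
      log(tr$table$ci90_hi_pct[1]) - log(tr$table$ci90_lo_pct[1])
    })
    mean(hw)
  }
  h12 <- half_width(12); h46 <- half_width(46); h184 <- half_width(184)
  expect_equal(h12 / h46, sqrt(46 / 12), tolerance = 0.15)
  expect_equal(h46 / h184, sqrt(184 / 46), tolerance = 0.15)
})

test_that("mechanistic study wires dissolution through to the verdict", {
  mod <- atorvastatin_model()
  s <- virtual_be_study(mod$compound, mod$acat, mod$disp,
                        release_ref = rapid_release(),
                        release_test = weibull_release(100, 9, 1.5),
                        spec = population_spec(seed = 1),
                        times = coarse_times(96, 0.25), n_trials = 4)
  expect_s3_class(s, "be_series")
  ratio <- attr(s, "model_ratio")
  expect_true(all(ratio > 0.8 & ratio < 1.05))
  # slightly slower test dissolution: AUC essentially unchanged
  expect_equal(unname(ratio["auc_inf"]), 1, tolerance = 0.02)
})
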