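test_that("release fraction interpolates, anchors at zero and clamps", {
  p <- dissolution_profile(c(10, 20), c(40, 80))
  expect_equal(release_fraction(p, 0), 0)
  expect_equal(release_fraction(p, 10), 0.40)
  expect_equal(release_fraction(p, 15), 0.60)
  expect_equal(release_fraction(p, 100), 0.80)  # plateau hold
  expect_error(release_fraction(p, -1), ">= 0")
})

test_that("release fraction is monotone and bounded for random profiles", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tt <- sort(runif(n, 1, 60))
    y <- cummax(runif(n, 0, 104)) + runif(n, -1, 0)  # small dips allowed
    y <- pmin(pmax(y, 0), 105)
    p <- dissolution_profile(tt, y, tol_decrease = 2)
    f <- release_fraction(p, seq(0, 90, by = 0.5))
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("dissolution hazard recovers first-order release and time scaling", {
  k <- 0.1  # 1/min
  tt <- seq(2, 60, by = 2)
  p <- dissolution_profile(tt, 100 * (1 - exp(-k * tt)))
  h <- release_hazard(p, seq(3, 20, by = 1))
  expect_equal(h, rep(k, length(h)), tolerance = 0.05)

  # doubling dissolution speed doubles the hazard pointwise
  p2 <- dissolution_profile(tt / 2, 100 * (1 - exp(-k * tt)))
  expect_equal(release_hazard(p2, c(4, 6, 8)),
               2 * release_hazard(p, 2 * c(4, 6, 8)), tolerance = 1e-9)

  # complete profiles have zero hazard on the plateau
  pc <- dissolution_profile(c(5, 10, 15, 20), c(60, 90, 100, 100))
  expect_equal(release_hazard(pc, c(17, 25, 100)), c(0, 0, 0))
})

test_that("Weibull fitting recovers known parameters and nests b = 1", {
  tt <- c(5, 10, 15, 20, 35, 45, 60)
  w <- weibull_release(100, 10, 1.2)
  p <- dissolution_profile(tt, 100 * vbesim:::weibull_fraction(w, tt))
  fit <- weibull_fit(p)
  expect_equal(fit$fmax, 100, tolerance = 1e-3)
  expect_equal(fit$mdt, 10, tolerance = 1e-3)
  expect_equal(fit$b, 1.2, tolerance = 1e-3)

  w1 <- weibull_release(95, 12, 1)
  p1 <- dissolution_profile(tt, 95 * (1 - exp(-tt / 12)))
  expect_equal(weibull_fit(p1)$b, 1, tolerance = 1e-3)

  pn <- synth_dissolution_profile(100, 10, 1.2, noise_sd = 2, seed = 5)
  expect_lte(weibull_fit(pn)$rmse, 2.5)
})

test_that("f2 reproduces closed-form offsets and is symmetric", {
  tt <- c(5, 10, 15, 20, 35, 45, 60)
  base <- c(20, 40, 55, 65, 75, 80, 83)
  ref <- dissolution_profile(tt, base)
  expect_equal(f2_similarity(ref, ref), 100.0)
  off10 <- dissolution_profile(tt, base - 10)
  expect_equal(f2_similarity(ref, off10), 50 * log10(100 / sqrt(101)),
               tolerance = 1e-12)
  expect_equal(f2_similarity(ref, off10), 49.89, tolerance = 1e-3)
  off2 <- dissolution_profile(tt, base - 2)
  expect_equal(f2_similarity(ref, off2), 82.53, tolerance = 1e-2)
  expect_equal(f2_similarity(off10, ref), f2_similarity(ref, off10))
  # f2 strictly decreases as a uniform offset grows
  f2s <- sapply(c(2, 4, 6, 8, 10), function(d)
    f2_similarity(ref, dissolution_profile(tt, base - d)))
  expect_true(all(diff(f2s) < 0))
  expect_error(f2_similarity(ref, dissolution_profile(tt[-1], base[-1])),
               "time grid")
})

test_that("rapid-dissolution classification is strict at 85% by 15 min", {
  tt <- c(5, 10, 15, 20)
  expect_true(rapid_dissolution(dissolution_profile(tt, c(50, 80, 90, 95))))
  expect_false(rapid_dissolution(dissolution_profile(tt, c(0, 0, 0, 0))))
  expect_false(rapid_dissolution(dissolution_profile(tt, c(50, 75, 85, 95))))
  expect_error(rapid_dissolution(dissolution_profile(c(5, 10), c(50, 80))),
               "15 min")
})

test_that("predicted-observed curve correlation uses the observed grid", {
  obs <- plasma_profile(c(1, 2, 4, 8), c(10, 8, 5, 2))
  pred_same <- plasma_profile(seq(0, 10, 0.5),
                              approx(c(0, 1, 2, 4, 8, 10),
                                     c(0, 10, 8, 5, 2, 1),
                                     xout = seq(0, 10, 0.5))$y)
  expect_equal(profile_correlation_r2(pred_same, obs), 1.0)
  flat <- plasma_profile(c(0, 10), rep(mean(obs$conc_ug_per_L), 2))
  expect_equal(profile_correlation_r2(flat, obs), 0.0)
  # pass/fail around the conventional 0.85 gate
  expect_true(profile_correlation_r2(pred_same, obs) > 0.85)
})

test_that("oral simulation agrees between a profile and its Weibull fit", {
  mod <- atorvastatin_model()
  tt <- c(5, 10, 15, 20, 35, 45, 60)
  w <- weibull_release(100, 8, 1.3)
  prof <- dissolution_profile(tt, 100 * vbesim:::weibull_fraction(w, tt))
  fit <- weibull_fit(prof)
  expect_lte(fit$rmse, 1)
  sim_tab <- simulate_oral(mod$compound, mod$acat, mod$disp, prof,
                           times = coarse_times())
  sim_wb <- simulate_oral(mod$compound, mod$acat, mod$disp, w,
                          times = coarse_times())
  cmax_tab <- compute_nca(sim_tab$plasma)$cmax
  cmax_wb <- compute_nca(sim_wb$plasma)$cmax
  expect_equal(cmax_tab, cmax_wb, tolerance = 0.02)
})
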