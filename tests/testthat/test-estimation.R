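test_that("r_squared matches hand arithmetic and handles edge cases", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0.0)
  expect_equal(r_squared(obs, c(1.1, 1.9, 3.2, 3.8)), 1 - 0.10 / 5.0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("least-squares AIC evaluates and validates correctly", {
  expect_equal(aic_rss(10, 10, 3), 6)
  expect_equal(aic_rss(8, 0.5, 2), 8 * log(0.5 / 8) + 4)
  expect_error(aic_rss(10, 0, 3), "perfect fit")
  expect_error(aic_rss(3, 1, 3), "n_obs > n_params")
})

test_that("noise-free two-compartment data are recovered to 0.1%", {
  truth <- disposition_params(2, cl_app = 20, vc_app = 50,
                              k12 = 0.8, k21 = 0.3)
  d <- synth_plasma_dataset(truth, ka = 1.5, dose_mg = 20, prop_cv = 0,
                            seed = 1)
  fit <- fit_compartment_model(d[[1]], 2, multistart = 5, seed = 0)
  cf <- coef(fit)
  expect_equal(unname(cf["cl_app"]), 20, tolerance = 1e-3)
  expect_equal(unname(cf["vc_app"]), 50, tolerance = 1e-3)
  expect_equal(unname(cf["ka"]), 1.5, tolerance = 1e-3)
  expect_equal(unname(cf["k12"]), 0.8, tolerance = 1e-3)
  expect_gte(fit$r2, 0.999)
})

test_that("model selection follows AIC with documented tie-breaks", {
  # stub candidates carrying the published-style (R2, AIC) triples: the
  # 3-compartment entry has the highest R2 and lowest AIC and must win
  stub <- function(n_comp, r2, aic, n_params) {
    structure(list(params = list(n_comp = n_comp), n_params = n_params,
                   t_half = 10, r2 = r2, aic = aic),
              class = "pk_fit")
  }
  fits <- list(stub(1L, 0.7487, -36.06, 4),
               stub(2L, 0.8531, -53.58, 6),
               stub(3L, 0.9249, -60.99, 8))
  expect_equal(select_model(fits)$params$n_comp, 3L)
  tab <- attr(select_model(fits), "selection_table")
  expect_equal(tab$aic, c(-36.06, -53.58, -60.99))
  expect_equal(tab$selected, c(FALSE, FALSE, TRUE))

  # single candidate returns itself
  expect_equal(select_model(fits[2])$params$n_comp, 2L)

  # AIC governs when AIC and R2 disagree (extra parameter buys R2 but
  # loses on the penalty)
  pair <- list(stub(2L, 0.990, -50, 6), stub(3L, 0.991, -47, 8))
  expect_equal(select_model(pair)$params$n_comp, 2L)

  # exact AIC ties go to fewer parameters
  tie <- list(stub(3L, 0.99, -50, 8), stub(2L, 0.98, -50, 6))
  expect_equal(select_model(tie)$params$n_comp, 2L)
})

test_that("selection is invariant to concentration unit rescaling", {
  truth <- disposition_params(2, cl_app = 20, vc_app = 50,
                              k12 = 0.8, k21 = 0.3)
  d <- synth_plasma_dataset(truth, ka = 1.5, dose_mg = 20, prop_cv = 0.08,
                            seed = 7)[[1]]
  d_scaled <- plasma_profile(d$time_h, d$conc_ug_per_L * 1000,
                             dose_mg = attr(d, "dose_mg"))
  fits <- lapply(list(d, d_scaled), function(p)
    lapply(1:2, function(k) fit_compartment_model(p, k, multistart = 4,
                                                  seed = 0)))
  sel <- lapply(fits, select_model)
  expect_equal(sel[[1]]$params$n_comp, sel[[2]]$params$n_comp)
  # log weighting: the weighted RSS itself is scale invariant
  expect_equal(sel[[1]]$rss, sel[[2]]$rss, tolerance = 1e-4)
})

test_that("fits are deterministic given the seed", {
  truth <- disposition_params(1, cl_app = 15, vc_app = 40)
  d <- synth_plasma_dataset(truth, ka = 1.2, prop_cv = 0.1, seed = 3)[[1]]
  f1 <- fit_compartment_model(d, 1, multistart = 6, seed = 11)
  f2 <- fit_compartment_model(d, 1, multistart = 6, seed = 11)
  expect_identical(coef(f1), coef(f2))
})

test_that("pk_fit methods expose the fitted model", {
  truth <- disposition_params(1, cl_app = 15, vc_app = 40)
  d <- synth_plasma_dataset(truth, ka = 1.2, prop_cv = 0, seed = 1)[[1]]
  f <- fit_compartment_model(d, 1, multistart = 3, seed = 0)
  expect_named(coef(f), c("cl_app", "vc_app", "ka"))
  expect_length(predict(f, c(1, 2, 3)), 3)
  expect_equal(predict(f), fitted(f))
  expect_equal(length(residuals(f)), f$n_obs)
  expect_output(print(f), "1-compartment fit")
  s <- summary(f)
  expect_true(all(c("r2", "aic", "t_half") %in% names(s)))
})
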