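test_that("Caco-2 to Peff calibration is anchored and log-linear", {
  expect_equal(caco2_to_peff(2.08e-6), 1.536e-4, tolerance = 1e-12)
  expect_equal(caco2_to_peff(4.16e-6), 2 * 1.536e-4, tolerance = 1e-12)
  expect_equal(caco2_to_peff(2.08e-7), 1.536e-5, tolerance = 1e-12)
  expect_gt(caco2_to_peff(5e-6, slope = 0.7), caco2_to_peff(4e-6, slope = 0.7))
  expect_error(caco2_to_peff(0), "> 0")
})

test_that("zero permeability means no absorption and full excretion", {
  mod <- atorvastatin_model()
  cmp <- mod$compound
  cmp$peff <- 1e-12  # effectively impermeable
  sim <- simulate_oral(cmp, mod$acat, mod$disp, "instantaneous",
                       times = coarse_times(120, 0.5))
  expect_lt(max(sim$plasma$conc_ug_per_L), 1e-4)
  expect_gt(sim$fraction_excreted, 0.995)
  expect_lt(sim$fraction_absorbed, 1e-3)
})

test_that("halving every ASF cannot increase the fraction absorbed", {
  mod <- atorvastatin_model()
  sim_full <- simulate_oral(mod$compound, mod$acat, mod$disp,
                            rapid_release(), times = coarse_times())
  acat_half <- mod$acat
  acat_half$asf <- acat_half$asf / 2
  sim_half <- simulate_oral(mod$compound, acat_half, mod$disp,
                            rapid_release(), times = coarse_times())
  expect_lte(sim_half$fraction_absorbed, sim_full$fraction_absorbed)
})

test_that("dose linearity holds in apparent mode", {
  mod <- atorvastatin_model()
  s20 <- simulate_oral(mod$compound, mod$acat, mod$disp, rapid_release(),
                       times = coarse_times(), dose_mg = 20)
  s40 <- simulate_oral(mod$compound, mod$acat, mod$disp, rapid_release(),
                       times = coarse_times(), dose_mg = 40)
  m20 <- compute_nca(s20$plasma); m40 <- compute_nca(s40$plasma)
  expect_equal(m40$cmax, 2 * m20$cmax, tolerance = 1e-6)
  expect_equal(m40$auc_t, 2 * m20$auc_t, tolerance = 1e-6)
})

test_that("well-stirred mode responds to the blood-to-plasma ratio", {
  mod <- atorvastatin_model()
  acat_ws <- acat_spec(asf = mod$acat$asf, hepatic_mode = "wellstirred",
                       q_h = 90)
  # systemic-scale clearance for the well-stirred demonstration
  disp <- disposition_params(3, cl_app = 50, vc_app = 16.02,
                             k12 = 1.2677, k21 = 0.65964,
                             k13 = 0.07081, k31 = 0.04706)
  cmax_at_rbp <- function(rbp) {
    cmp <- mod$compound; cmp$rbp <- rbp
    sim <- simulate_oral(cmp, acat_ws, disp, rapid_release(),
                         times = coarse_times(24, 0.1))
    compute_nca(sim$plasma)$cmax
  }
  cm <- vapply(c(2, 4, 8), cmax_at_rbp, 0)
  expect_true(all(diff(cm) > 0))
  # extraction above unity is refused rather than silently clamped
  cmp_low <- mod$compound; cmp_low$rbp <- 0.5
  expect_error(simulate_oral(cmp_low, acat_ws, disp, rapid_release(),
                             times = coarse_times(24, 0.5)),
               "extraction")
})

test_that("gut mass balance closes at every output time", {
  mod <- atorvastatin_model()
  for (rel in list("instantaneous", rapid_release())) {
    sim <- simulate_oral(mod$compound, mod$acat, mod$disp, rel,
                         times = coarse_times(96, 0.5))
    expect_lte(sim$mass_balance_residual, 1e-3)
    expect_equal(sim$fraction_absorbed + sim$fraction_excreted +
                   sim$fraction_in_lumen, 1, tolerance = 1e-3)
    expect_equal(sum(sim$segment_absorbed), sim$fraction_absorbed,
                 tolerance = 1e-9)
  }
})

test_that("sensitivity analysis holds everything fixed except the target", {
  mod <- atorvastatin_model()
  base <- simulate_oral(mod$compound, mod$acat, mod$disp, rapid_release(),
                        times = coarse_times())
  base_m <- compute_nca(base$plasma)
  one <- parameter_sensitivity(mod$compound, mod$acat, mod$disp,
                               rapid_release(), coarse_times(),
                               param = "asf.duodenum",
                               grid = mod$acat$asf[["duodenum"]])
  expect_equal(nrow(one), 1L)
  expect_equal(one$cmax, base_m$cmax, tolerance = 1e-9)
  expect_equal(one$auc_t, base_m$auc_t, tolerance = 1e-9)

  expect_error(parameter_sensitivity(mod$compound, mod$acat, mod$disp,
                                     rapid_release(), coarse_times(),
                                     param = "asf.nonsense", grid = 1),
               "unknown segment|valid paths")
  expect_error(parameter_sensitivity(mod$compound, mod$acat, mod$disp,
                                     rapid_release(), coarse_times(),
                                     param = "bogus", grid = 1),
               "valid paths")
})
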