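# Shared fixtures: literature-derived atorvastatin parameter set and small
# helpers to keep the heavier simulations on coarse grids.

ator_disposition <- function() {
  disposition_params(3, cl_app = 358.3, vc_app = 16.02,
                     k12 = 1.2677, k21 = 0.65964,
                     k13 = 0.07081, k31 = 0.04706)
}

# observed 20 mg clinical summary metrics (literature fixture)
ator_observed_20mg <- c(cmax = 10.81, auc_t = 53.59, auc_inf = 55.56)

rapid_release <- function() weibull_release(100, 6, 1.5)

coarse_times <- function(t_end = 48, dt = 0.2) seq(0, t_end, by = dt)

random_disposition <- function(n_comp) {
  cl <- runif(1, 5, 50); vc <- runif(1, 20, 100)
  switch(n_comp,
         disposition_params(1, cl, vc),
         disposition_params(2, cl, vc,
                            k12 = runif(1, 0.5, 1.5), k21 = runif(1, 0.2, 0.5)),
         disposition_params(3, cl, vc,
                            k12 = runif(1, 0.5, 1.5), k21 = runif(1, 0.2, 0.5),
                            k13 = runif(1, 0.05, 0.12),
                            k31 = runif(1, 0.03, 0.08)))
}

recovery_times <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36, 48, 72)
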