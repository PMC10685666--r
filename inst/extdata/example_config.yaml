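# Complete run configuration for the 20 mg atorvastatin example:
# literature compound record, apparent 3-compartment disposition fitted from
# oral data, calibrated ACAT absorption scale factors, and the population
# settings used for the repeated virtual bioequivalence study
# (46 subjects, CV 40% for Cmax and 15% for AUC, 10 trials).
seed: 1
compound:
  name: atorvastatin
  mw: 558.65
  logp: 4.434
  pka: 4.71
  rbp: 7.61
  fu: 0.0504
  papp_caco2: 2.08e-6
  dose_mg: 20
disposition:
  n_comp: 3
  cl_app: 358.3
  vc_app: 16.02
  k12: 1.2677
  k21: 0.65964
  k13: 0.07081
  k31: 0.04706
acat:
  hepatic_mode: apparent
  asf:
    stomach: 0
    duodenum: 0.4
    jejunum1: 0.4
    jejunum2: 0.4
    ileum1: 0.4
    ileum2: 0.4
    ileum3: 0.4
    caecum: 1.2
    colon: 1.2
population:
  n_subjects: 46
  cv_cmax: 0.40
  cv_auc: 0.15
  w: 0.5
  seed: 1
simulation:
  t_end_h: 72
  dt_h: 0.05
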