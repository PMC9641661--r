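# Reference configuration of the mir9step package.
#
# Basic model: h* = alpha_h * mu_X / (mu_h * alpha_X) = 1. The X branch
# is five-fold slower than Her6 (mu_X = 0.2 vs mu_h = 1), so a sharp
# input change opens a transient window of several hours in which Her6
# is dipped before the loop re-adapts.
#
# Extended model: with Her6 adapted at h* = 1, Y is repressed to ~0.003
# (single low fixed point). The coupled system is bistable; an
# instantaneous miR-9 fold change of ~5.9 is the switching threshold.
seed: 1
basic_model:
  alpha_h: 1.0
  mu_h: 1.0
  alpha_X: 0.2
  mu_X: 0.2
extended_model:
  alpha_Y: 0.1
  beta_Y: 2.0
  mu_Y: 1.0
  y_on_h: {n: 5, p0: 0.3}   # p0 here is p1: sets the low Her6 level
  h_on_y: {n: 5, p0: 0.5}
  y_self: {n: 4, p0: 0.3}
  gate_basal_only: false
profile:
  kind: steps
  m0: 1.0
  t0: 0.0
  t1: 150.0
  steps:
    - {t: 10.0, fold: 1.5}
    - {t: 40.0, fold: 8.0}
locus_model:
  n_cells: 500
  decay_rate: 0.5           # mature miR-9 turnover, 1/hour
  basal: 0.35               # mature miR-9 from unmodelled sources
  t0: 24.0                  # hpf
  t1: 48.0
  dt: 0.01
  loci:
    - {name: pri-mir-9-5, onset_mean: 30.0, onset_sd: 1.0, production_rate: 0.0375}
    - {name: pri-mir-9-4, onset_mean: 30.0, onset_sd: 1.0, production_rate: 0.0375}
    - {name: pri-mir-9-1, onset_mean: 36.5, onset_sd: 1.0, production_rate: 1.375}
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
experiment:
  name: linear-vs-step
  m0: 1.0
  m_end: 12.0
  t_change: [10.0, 40.0]
  first_fold: 1.5
  t_end: 150.0
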