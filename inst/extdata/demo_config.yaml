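# Demo pipeline config: one synthetic 81-core plot, modest grid sizes so
# the full run finishes in well under a minute.
seed: 42
output_dir: firekrige_demo
design:
  spacings: [2, 2, 4, 4, 8, 8, 4, 2]
  n_rows: 9
  row_spacing: 2
  plot_size: 50
simulate:
  response:
    beta: [20.0, 0.1, 0.0]
    sigma2: 400
    phi: 3
    tau2_rel: 0.7
  lipids:
    profile_plot: glade_crown
    total_mean: 205.25
    total_sd: 140.9
    profile_conc: 200
krige:
  variables: [value]
  n_phi: 25
  n_tau: 25
  n_draws: 5000
  prediction_spacing: 2
  loo: true
  loo_n_phi: 10
  loo_n_tau: 10
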