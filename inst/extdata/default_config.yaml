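# Default configuration: acquisition geometry, standard stimulus, simulator
# cell parameters (tuned so that the standard 25-AP/50-Hz sweep yields
# population medians near peak ~60 %dF/F, RT ~1.2 s, DT1 ~2.6 s and resting
# fluorescence ~440 a.u.), population distributions, preprocessing and
# fitting parameters.
acquisition:
  n_samples: 20000
  duration_s: 28.16
  pixels: 76
  pixel_pitch_um: 9.3
protocol:
  onset_time_s: 5.0
  pulse_frequency_hz: 50.0
  train_duration_s: 0.5
  pulse_width_ms: 0.1
cell:
  baseline_ca: 0.15
  influx_per_ap: 0.033
  k_serca: 0.20
  k_pmca: 0.42
  indicator_kon: 1.0
  indicator_koff: 0.75
  indicator_total: 1.0
  hill_n: 2.0
  f_rest: 411.0
  f_gain: 950.0
  noise_sd: 25.0
  bath_ca_factor: 1.0
population:
  n_animals: 20
  cells_per_animal: 10
  distributions:
    baseline_ca: {dist: fixed, value: 0.15}
    influx_per_ap: {dist: lognormal, meanlog: -3.52, sdlog: 0.7}
    k_serca: {dist: normal, mean: 0.20, sd: 0.04, min: 0.03}
    k_pmca: {dist: normal, mean: 0.42, sd: 0.05, min: 0.05}
    indicator_kon: {dist: fixed, value: 1.0}
    indicator_koff: {dist: normal, mean: 0.75, sd: 0.05, min: 0.20}
    indicator_total: {dist: fixed, value: 1.0}
    hill_n: {dist: fixed, value: 2.0}
    f_rest: {dist: normal, mean: 411.0, sd: 95.0, min: 60.0}
    f_gain: {dist: normal, mean: 950.0, sd: 95.0, min: 150.0}
    noise_sd: {dist: fixed, value: 25.0}
    bath_ca_factor: {dist: fixed, value: 1.0}
preprocessing:
  filter_order: 4
  filter_cutoff_hz: 10.0
  smooth_window: 15
  smooth_iterations: 3
  baseline_window_s: [0.5, 4.5]
fitting:
  rise_degree: 3
  tau_bounds_s: [0.05, 60.0]
  n_starts: 5
  decay_max_points: 2000
  responder_threshold_pct: 5.0
  resting_window_s: 0.1
conditions:
  tg_block_fraction: 0.1
  ph_block_fraction: 0.2
  ca_factors: {normal-Ca: 1.0, high-Ca: 2.0, no-added-Ca: 0.1}
exclusion:
  resting_quantile: 0.995
  prestim_sd_quantile: 0.995
stats:
  dip_n_boot: 1000
  alpha: 0.05
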