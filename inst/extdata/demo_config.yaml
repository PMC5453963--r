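# Demonstration run: one poor-regime year (2013) and one good-regime year
# (2015), both sexes, scaled-down sample sizes. Load with
# load_run_config() or pass to the CLI script via --config.
scale: 0.2
seed: 42
n_perm: 100
levels: [50.0, 95.0, 99.0]
cell: 0.05
buffer_km: 200.0
fpt_r_max: 50.0
fpt_r_by: 1.0
fpt_sample_step: 1.0
env_n_days: 3
gen:
  colony:
    lon: -9.6
    lat: 39.3833
  fix_interval_min: 5.0
  n_patches: 3
  patch_radius_km: 5.0
  commute_speed: 35.0
  patch_speed: 8.0
  rest_speed: 0.8
  commute_rho: 0.9
  ars_rho: 0.3
  rest_frac_min: 0.05
strata:
  - group: female
    year: 2013
    regime: poor
    nao_winter: -2.0
    n_trips: 22
    n_birds: 5
    dur_mean: 2.8
    dur_sd: 0.9
    ltst_ratio: 0.9
    dist_mean: 542.9
    dist_sd: 87.3
    ars_mean: 38.3
    ars_sd: 5.8
    d13c_mean: -19.3
    d13c_sd: 0.4
    d15n_mean: 13.4
    d15n_sd: 0.3
    sea_b: 1.2
    bci_mean: -0.8
    bci_sd: 0.2
    gain_mean: 34.3
    gain_sd: 8.3
  - group: male
    year: 2013
    regime: poor
    nao_winter: -2.0
    n_trips: 20
    n_birds: 4
    dur_mean: 2.0
    dur_sd: 1.2
    ltst_ratio: 0.5
    dist_mean: 209.1
    dist_sd: 66.9
    ars_mean: 28.7
    ars_sd: 5.6
    d13c_mean: -18.3
    d13c_sd: 0.5
    d15n_mean: 14.1
    d15n_sd: 0.5
    sea_b: 0.7
    bci_mean: -0.4
    bci_sd: 0.3
    gain_mean: 40.9
    gain_sd: 7.7
  - group: female
    year: 2015
    regime: good
    nao_winter: 3.6
    n_trips: 30
    n_birds: 7
    dur_mean: 1.5
    dur_sd: 0.7
    ltst_ratio: 0.4
    dist_mean: 58.4
    dist_sd: 21.0
    ars_mean: 16.3
    ars_sd: 4.9
    d13c_mean: -17.2
    d13c_sd: 0.6
    d15n_mean: 13.2
    d15n_sd: 0.3
    sea_b: 0.9
    bci_mean: 1.2
    bci_sd: 0.3
    gain_mean: 88.1
    gain_sd: 5.6
  - group: male
    year: 2015
    regime: good
    nao_winter: 3.6
    n_trips: 63
    n_birds: 11
    dur_mean: 1.3
    dur_sd: 0.6
    ltst_ratio: 0.2
    dist_mean: 74.4
    dist_sd: 21.9
    ars_mean: 14.2
    ars_sd: 3.5
    d13c_mean: -17.5
    d13c_sd: 0.3
    d15n_mean: 13.9
    d15n_sd: 0.3
    sea_b: 0.5
    bci_mean: 1.4
    bci_sd: 0.4
    gain_mean: 90.0
    gain_sd: 4.7
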