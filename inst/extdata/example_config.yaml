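# Example configuration for the bretropy CLI. Every field is optional;
# absent fields take the documented defaults of simulation_config() /
# analysis_config(). Simulation and analysis fields may live in one file.
seed: 1
n_experiments: 3
n_wells: 3
dt: 30
baseline_duration: 300
total_duration: 2100
conditions:
  - label: vehicle
    amplitude: 0
    noise: {family: gaussian_iid, sigma: 0.004}
  - label: AngII
    amplitude: 0.05
    rate: 0.004
    noise: {family: gaussian_iid, sigma: 0.004}
  - label: LVV-H7
    amplitude: 0
    noise:
      family: burst_renewal
      sigma: 0.006
      burst_rate_scale: 60
      burst_tail: 1.5
      burst_amplitude: 0.02
      burst_decay: 0.02
  - label: AngII+LVV-H7
    amplitude: 0.09
    rate: 0.008
    noise: {family: gaussian_iid, sigma: 0.002}
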