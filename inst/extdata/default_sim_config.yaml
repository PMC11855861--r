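# Default synthetic-cohort configuration (see ?simulation_config for units).
n_meth: 6
n_sal: 6
k_true: 2.4
q0_logmean_meth: 1.93
q0_logsd_meth: 0.65
q0_logmean_sal: 0.10
q0_logsd_sal: 0.55
alpha_logmean_meth: -6.34
alpha_logsd_meth: 0.70
alpha_logmean_sal: -3.90
alpha_logsd_sal: 0.50
noise_sd_log10: 0.1
n_genes: 2000
frac_linked: 0.025
slope_linked: 0.5
baseline_logmean: 3.5
baseline_logsd: 1.0
theta: 10
libsize_jitter: 0.05
drop_meth_sample: true
region: PFC
seed: 1
unit_dose: 0.05
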