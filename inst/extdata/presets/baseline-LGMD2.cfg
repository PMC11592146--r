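# baseline-LGMD2 selectivity profile
preset = baseline-LGMD2
gating_enabled = 0
frame_interval = 30
tau3 = 90
tau4 = 90
omega_ffi = 20
omega1 = 4
omega2 = 0.5
th_ffi = 1
tau_on = 15
tau_off = 90
bias_on = 0.5
bias_off = 1
inhib_kernel_size = 5
group_kernel_size = 3
decay_threshold = 15
decay_coeff = 0
alpha6 = 1.5
alpha7 = 10
t_spi = 5
spike_mp_level = 0.8
n_sp = 5
n_ts = 9
sfa_tau = 270
sfa_mode = highpass
sfa_rise_tol = 0.02
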