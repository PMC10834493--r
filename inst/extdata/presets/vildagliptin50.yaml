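# Generator preset mimicking a fast-releasing BCS class I 50 mg tablet
# study: near-complete release by the first sampling time, slight late
# decline, heteroscedastic replicate SDs (% units) per time point, n = 3.
params:
  f_inf: 99
  tau: 3
  beta: 1
  decay: 0.04
  noise_sd: [0.90, 0.94, 0.94, 0.91, 0.97]
  n_reps: 3
times: [10, 15, 20, 30, 45]
test_deltas:
  V-1: {f_inf: 1.0, tau: -0.3}
  V-2: {f_inf: 3.0}
  V-3: {f_inf: -0.5}
  V-4: {f_inf: -1.5, tau: 0.2}
  V-5: {f_inf: -2.0, decay: 0.01}
  V-6: {f_inf: 0.3}
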