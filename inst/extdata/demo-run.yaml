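# Demo pipeline configuration: synthetic session generated by model 2
# (gamma gain 2, beta gain -1, Tp 0.2 s, Td 0.2 s), 5% force noise,
# 30 trials. fs is reduced from the hardware 2048 Hz to 512 Hz to keep the
# demo fast; all analysis frequencies (<= 90 Hz) are unaffected.
simulate:
  n_trials: 30
  fs: 512
  true_model_id: 2
  true_params:
    Kp1: 2.0
    Kp2: -1.0
    Tp: 0.2
    Td: 0.2
  noise_sd: 0.05
pair: auto
fs_feature: 100
model_ids: [1, 2, 3, 4, 5, 6, 7, 8]
cv:
  scheme: effort_split
seed: 1
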