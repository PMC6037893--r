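# Example synthetic cohort: DLB-like archetype, 5 subjects.
# Band fractions emulate a theta-heavy slowed EEG with a 6.9 Hz dominant
# rhythm; coupling is a weak phase-lagged chain across neighboring channels.
group_label: dlb
n_subjects: 5
seed: 7
jitter:
  dominant_freq: 0.5
  band_fractions: 0.02
  coupling_strength: 0.05
  noise_sd: 0.05
template:
  dominant_freq: 6.9
  band_fractions:
    delta: 0.41
    theta: 0.34
    alpha1: 0.07
    alpha2: 0.04
    beta: 0.06
    gamma: 0.08
  noise_sd: 0.3
  n_channels: 21
  fs: 500
  epoch_length_s: 8
  n_epochs: 4
  coupling:
    - [1, 2, 0.785, 0.15]
    - [2, 3, 0.785, 0.15]
    - [3, 4, 0.785, 0.15]
    - [4, 5, 0.785, 0.15]
    - [5, 6, 0.785, 0.15]
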