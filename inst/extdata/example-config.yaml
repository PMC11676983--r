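# Example pipeline config: 5'-toehold construct with asymmetric FAM/BHQ1
# modification, measured every 10 s for 90 min in triplicate.
system:
  toehold_orientation: five_prime
  modification: asymmetric
  reporter_species: X4
  ka: 1.74e-4          # nM^-1 s^-1
  kd: 8.51e-4          # nM^-1 s^-1
  toehold_length: 6
  recognition_length: 20
initial:
  x1: 10.0             # nM
  x2: 10.0
  x3: 0.0
  x4: 0.0
protocol:
  sample_interval: 10  # s
  duration: 5400       # s
  n_replicates: 3
  noise_sd: 0.02       # on the normalized scale
  f0: 100              # a.u.
  f100: 1000
  seed: 42
fit:
  n_starts: 25
  exclude_before: 0    # s; set >= 120 to drop the stabilization window
theory:
  "6": 5.0e-4          # nM^-1 s^-1
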