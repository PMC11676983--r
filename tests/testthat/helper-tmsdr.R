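# Shared fixtures: the four reference reporter configurations and small
# builders for noiseless and noisy substitution-ratio courses.

default_init <- function() reaction_state(10, 10)

noiseless_course <- function(ka, kd, init = default_init(),
                             tt = seq(0, 5400, by = 10)) {
  sys <- tmsdr_system(ka = ka, kd = kd)
  data.frame(time_s = tt, ratio = closed_form_extent(sys, init, tt) / init[["x1"]])
}

# Generate a triplicate noisy dataset, normalize and aggregate it.
noisy_summary <- function(ka, kd, seed, init = default_init(), ...) {
  sys <- tmsdr_system(ka = ka, kd = kd)
  ds <- generate_dataset(sys, init, synthetic_protocol(seed = seed, ...))
  calib <- calibration_set(ds$baseline, ds$positive_control)
  aggregate_replicates(lapply(ds$reaction, normalize_to_substitution,
                              calib = calib))
}

# Equal-initials equilibrium substitution ratio has the independent closed
# form sqrt(K)/(1 + sqrt(K)) with K = ka/kd; used as an oracle in tests.
equal_initials_eq_ratio <- function(ka, kd) {
  s <- sqrt(ka / kd)
  s / (1 + s)
}
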