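# shared fixtures: noise-free generator configs and hand-built profiles

quiet_cfg <- function(seed = 1L) {
  synth_config(seed = seed, noise_sd_sensorgram = 0,
               noise_sd_relaxation = 0, noise_sd_shift_h = 0,
               noise_sd_shift_hetero = 0, snr_intensity = Inf)
}

# the spec-free PRE profile builder used across PRE tests: constant error,
# optional per-residue offsets
make_pre_profile <- function(residues, pre, err = 0.05,
                             condition = "apo") {
  tibble::tibble(residue_index = residues, pre = pre, pre_err = err,
                 condition = condition)
}

# independent closed-form evaluation of the two-phase association model
# (crossed pairing), written out as plain arithmetic
oracle_assoc <- function(kon1, kon2, koff1, koff2, b1, b2, conc, t) {
  k1 <- conc * kon1 + koff2
  k2 <- conc * kon2 + koff1
  kon1 * conc * b1 / (kon1 * conc + koff2) * (1 - exp(-k1 * t)) +
    kon2 * conc * b2 / (kon2 * conc + koff1) * (1 - exp(-k2 * t))
}
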