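# shared fixtures: small parameter sets and synthetic-data shortcuts

ref_low_coh <- function() ddm_params(v = 0.060, a = 0.151, z = 0.151 / 2,
                                    t0 = 0.435)
ref_high_coh <- function() ddm_params(v = 0.172, a = 0.151, z = 0.151 / 2,
                                     t0 = 0.402)
ref_arrows <- function() ddm_params(v = 0.803, a = 0.214, z = 0.098,
                                       t0 = 0.219)
ref_bias_params <- function(z) ddm_params(v = 0.0952, a = 0.137, z = z,
                                        t0 = 0.289)

# fast-responding parameter set for EEG fixtures (short epochs)
eeg_ddm_params <- function() ddm_params(v = 0.25, a = 0.12, t0 = 0.35)

# behavioral trials + synthetic EEG in one call; the round-trip study
# conditions (300 trials, 8 uV lateralization, default noise) live here
make_synth_eeg <- function(seed, n = 300, amplitude = 8, artifacts = NULL,
                           noise = list(white = 4, pink = 4, common = 3)) {
  tt <- ddm_simulate(eeg_ddm_params(), n = n, seed = seed)
  ge <- simulate_eeg(tt, extra_channels = character(0),
                     amplitude_uv = amplitude, noise = noise,
                     artifacts = artifacts, seed = seed + 10000)
  list(trials = tt, epochs = ge$epochs, truth = ge$truth)
}

# hand-built noiseless epochs: a known waveform on C4 for left-hand trials
make_manual_epochs <- function(wave, n_trials = 4, sfreq = 250,
                               hand = rep("left", n_trials), rt_ms = 600) {
  ns <- length(wave)
  time_ms <- seq(0, by = 1000 / sfreq, length.out = ns) - 200
  data <- array(0, c(n_trials, 3, ns))
  for (i in seq_len(n_trials)) {
    sgn <- if (hand[i] == "left") 1 else -1
    data[i, 2, ] <- sgn * wave   # C4
    data[i, 1, ] <- -sgn * wave  # C3 (mirror)
  }
  eeg_epochs(data / 2, sfreq = sfreq, ch_names = c("C3", "C4", "EOG"),
             time_ms = time_ms, resp_ms = rep(rt_ms, n_trials),
             hand = hand, eog = "EOG")
}

# lrp_waveform constructor for measure tests
make_lrp <- function(time_ms, amplitude, locking = "stimulus") {
  structure(list(time_ms = time_ms, amplitude = amplitude,
                 n = 1L, locking = locking, condition = NA_character_),
            class = "lrp_waveform")
}
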