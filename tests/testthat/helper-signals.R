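# Shared fixtures, built in code. fs matches the accelerometer rate.
FS <- 208.03

# noisy tone: unit sinusoid at f plus colored noise at a given RMS-ratio SNR
noisy_tone <- function(f, duration_s = 60, snr = 3, kind = "pink", seed = 1,
                       fs = FS) {
  tone <- gen_pure_sine(f, fs, duration_s)
  tone$value + gen_colored_noise(kind, nrow(tone), (1 / sqrt(2)) / snr, seed = seed)
}

# indices after a warm-up, for steady-state assertions
after_warmup <- function(n, warmup_s = 5, fs = FS) {
  seq_len(n) > round(warmup_s * fs)
}

# naive moving-average oracle: direct mean of the last min(i, W) values
naive_moving_average <- function(x, W) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - W + 1):i]), numeric(1))
}

# circular mean of angles in degrees
circ_mean_deg <- function(deg) {
  r <- deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}
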