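# Offline validation and statistics: the band-pass + Hilbert oracle,
# wrap-corrected phase error, median instantaneous frequency, per-trial
# severity change, state-amplitude profiles with Bonferroni-corrected
# resampling limits, and the rank-sum envelope comparison.

#' Hilbert-transform oracle phase and envelope
#'
#' The offline gold standard the real-time tracker is validated against:
#' zero-phase 1-9 Hz Butterworth band-pass, then the analytic signal. Phase
#' uses the same convention as the tracker (0 degrees at the positive peak,
#' degrees in \[0, 360)); the envelope is the analytic-signal modulus.
#'
#' @param x Single-channel signal (g), at least 10 s long.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 1 and 9).
#' @return A tibble with columns `time_s`, `phase_deg`, `envelope`.
#' @export
oracle_phase_envelope <- function(x, fs, low = 1, high = 9) {
  check_scalar_pos(fs, "fs")
  check_that(length(x) >= 10 * fs,
             "`x` must be at least 10 s long for a stable oracle")
  bp <- offline_bandpass(x, fs, low, high)
  z <- hilbert_analytic(bp)
  tibble(time_s = (seq_along(x) - 1) / fs,
         phase_deg = wrap_deg(atan2(Im(z), Re(z)) * 180 / pi),
         envelope = Mod(z))
}

#' Wrap-corrected phase error
#'
#' Per-sample absolute difference between two phase tracks, corrected for
#' wrapping (circular distance, in \[0, 180\] degrees), summarized as an
#' arithmetic mean and SD. Exclude warm-up before calling.
#'
#' @param est,oracle Phase sequences in degrees, equal length.
#' @return A one-row tibble: `mean_deg`, `sd_deg`, `n`.
#' @export
phase_error <- function(est, oracle) {
  check_that(length(est) == length(oracle),
             "`est` and `oracle` must have equal length")
  err <- circ_dist(est, oracle)
  tibble(mean_deg = mean(err), sd_deg = sd(err), n = length(err))
}

#' Median instantaneous frequency of an oracle phase track
#'
#' First difference of the unwrapped oracle phase times `fs / 360`, median
#' over the segment, reported at 0.1 Hz resolution.
#'
#' @param oracle Output of [oracle_phase_envelope()], or a numeric phase
#'   sequence in degrees.
#' @param fs Sampling rate in Hz.
#' @param segment Optional integer sample indices to summarize (default:
#'   all); must span at least 1 s.
#' @return Median instantaneous frequency in Hz, rounded to 0.1 Hz.
#' @export
median_instantaneous_frequency <- function(oracle, fs, segment = NULL) {
  phase <- if (is.data.frame(oracle)) oracle$phase_deg else as.numeric(oracle)
  segment <- segment %||% seq_along(phase)
  check_that(length(segment) >= fs, "`segment` must span at least 1 s")
  d <- diff(phase[segment])
  d <- (d + 180) %% 360 - 180       # unwrap steps to (-180, 180]
  round(median(d * fs / 360), 1)
}

#' Per-trial change in tremor severity
#'
#' Percentage change of the median envelope in a stimulation window
#' relative to a baseline window:
#' `100 * (median(stim) - median(baseline)) / median(baseline)`.
#' A zero baseline median corresponds to absent tremor; the trial is
#' flagged undefined rather than scored.
#'
#' @param envelope Envelope samples (g).
#' @param stim_window,baseline_window Integer indices into `envelope`.
#' @return A one-row tibble: `change_percent`, `undefined`.
#' @export
trial_change <- function(envelope, stim_window, baseline_window) {
  check_that(length(stim_window) > 0 && length(baseline_window) > 0,
             "both windows must be non-empty")
  base <- median(envelope[baseline_window])
  if (base <= 0) {
    return(tibble(change_percent = NA_real_, undefined = TRUE))
  }
  tibble(change_percent = 100 * (median(envelope[stim_window]) - base) / base,
         undefined = FALSE)
}

#' State-amplitude profile with Bonferroni-corrected resampling limits
#'
#' For each stimulation state, the median per-trial change in tremor
#' severity with two-sided confidence limits under a sign-flip resampling
#' null (randomly negating each trial's change, which is exchangeable when
#' stimulation has no effect), at the Bonferroni-corrected level
#' `alpha / n_comparisons` split two-sided. A state is significant when its
#' observed median falls outside its corrected limits. States with fewer
#' than three trials are marked untestable.
#'
#' @param trials Data frame with columns `state` and `change_percent` (one
#'   row per trial).
#' @param alpha Family-wise level (default 0.05).
#' @param n_comparisons Number of states corrected for (default: the number
#'   of distinct states present; the in-clinic protocol has 8).
#' @param ndraws Resampling draws per state (default 10000).
#' @param seed Integer seed for the resampling.
#' @return A `state_profile` tibble: `state`, `n_trials`, `median_change`,
#'   `lower`, `upper`, `significant`, `untestable`.
#' @export
profile_significance <- function(trials, alpha = 0.05, n_comparisons = NULL,
                                 ndraws = 10000, seed = 1L) {
  check_that(all(c("state", "change_percent") %in% names(trials)),
             "`trials` must have columns state, change_percent")
  states <- unique(trials$state)
  n_comparisons <- n_comparisons %||% length(states)
  p_lo <- alpha / (2 * n_comparisons)
  out <- with_seed(seed, purrr::map_dfr(states, function(st) {
    ch <- trials$change_percent[trials$state == st]
    ch <- ch[is.finite(ch)]
    if (length(ch) < 3) {
      return(tibble(state = st, n_trials = length(ch),
                    median_change = if (length(ch)) median(ch) else NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    significant = NA, untestable = TRUE))
    }
    null_medians <- cpp_signflip_medians(ch, as.integer(ndraws))
    lims <- quantile(null_medians, c(p_lo, 1 - p_lo), names = FALSE)
    med <- median(ch)
    tibble(state = st, n_trials = length(ch), median_change = med,
           lower = lims[1], upper = lims[2],
           significant = med < lims[1] | med > lims[2], untestable = FALSE)
  }))
  class(out) <- c("state_profile", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- n_comparisons
  out
}

#' Rank-sum comparison of two tremor envelopes
#'
#' Two-sample Wilcoxon rank-sum test (normal approximation with tie
#' correction), as used to compare the baseline envelope with the final
#' minute of continuous stimulation. The reported statistic is the rank sum
#' of the first sample.
#'
#' @param envelope_a,envelope_b Envelope samples (g), non-empty.
#' @return A one-row tibble: `statistic` (rank sum of `envelope_a`),
#'   `p_value` (two-sided).
#' @export
envelope_rank_compare <- function(envelope_a, envelope_b) {
  check_that(length(envelope_a) > 0 && length(envelope_b) > 0,
             "both samples must be non-empty")
  wt <- wilcox.test(envelope_a, envelope_b, exact = FALSE, correct = FALSE)
  n1 <- length(envelope_a)
  tibble(statistic = unname(wt$statistic) + n1 * (n1 + 1) / 2,
         p_value = wt$p.value)
}

#' Tracker error with high-pass versus band-pass pre-filtering
#'
#' The offline characterization suite: unit sinusoids across the tremor
#' band plus pink or brown noise, tracked after (a) 0.1 Hz high-pass
#' filtering only and (b) 1-9 Hz zero-phase band-pass filtering, each
#' scored against the band-pass + Hilbert oracle with warm-up excluded.
#' The tracker acts as an adaptive band-pass filter, so (a) should trail
#' (b) only slightly -- the design claim is by no more than 0.6 degrees.
#'
#' @param freqs Tone frequencies in Hz (default 2:8).
#' @param noise_kinds Colored-noise kinds (default pink and brown).
#' @param seeds Noise seeds (default 1:10).
#' @param snr Signal-to-noise ratio as an RMS ratio (default 3).
#' @param fs Sampling rate in Hz.
#' @param G Tracker gain.
#' @param duration_s Tone duration in seconds (default 60).
#' @param warmup_s Warm-up excluded from scoring (default 5).
#' @return A tibble with one row per (frequency, noise kind, seed):
#'   `f_hz`, `noise`, `seed`, `err_highpass_deg`, `err_bandpass_deg`.
#' @seealso [prefilter_error_gap()] for the suite-level summary.
#' @export
prefilter_error_suite <- function(freqs = 2:8, noise_kinds = c("pink", "brown"),
                                  seeds = 1:10, snr = 3, fs = 208.03, G = 0.25,
                                  duration_s = 60, warmup_s = 5) {
  check_scalar_pos(snr, "snr")
  grid <- tidyr::expand_grid(f_hz = freqs, noise = noise_kinds, seed = seeds)
  noise_rms <- (1 / sqrt(2)) / snr      # unit-amplitude tone RMS over snr
  purrr::pmap_dfr(grid, function(f_hz, noise, seed) {
    tone <- gen_pure_sine(f_hz, fs, duration_s)
    x <- tone$value + gen_colored_noise(noise, nrow(tone), noise_rms, seed = seed)
    keep <- seq_along(x) > round(warmup_s * fs)
    oracle <- oracle_phase_envelope(x, fs)
    x_hp <- filter_apply(make_highpass(fs), x)
    x_bp <- offline_bandpass(x, fs)
    est_hp <- track_phase(x_hp, fs, fc = f_hz, G = G)
    est_bp <- track_phase(x_bp, fs, fc = f_hz, G = G)
    tibble(f_hz = f_hz, noise = noise, seed = seed,
           err_highpass_deg = phase_error(est_hp$phi_deg[keep],
                                          oracle$phase_deg[keep])$mean_deg,
           err_bandpass_deg = phase_error(est_bp$phi_deg[keep],
                                          oracle$phase_deg[keep])$mean_deg)
  })
}

#' Suite-level pre-filtering error gap
#'
#' Difference of suite mean phase errors, high-pass minus band-pass, from
#' [prefilter_error_suite()] output.
#'
#' @param suite Output of [prefilter_error_suite()].
#' @return Difference in degrees (positive when high-pass trails).
#' @export
prefilter_error_gap <- function(suite) {
  mean(suite$err_highpass_deg) - mean(suite$err_bandpass_deg)
}
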