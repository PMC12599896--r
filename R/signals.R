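# Synthetic tremor and characterization signals: pure/noisy sinusoids,
# colored noise, and full triaxial scenarios with ground-truth phase,
# dominant axis and center frequency.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a pure sinusoid with its true phase track
#'
#' Test tone for tracker characterization: `amplitude * cos(2 pi f t +
#' phase0)`, sampled at `fs`. Phase 0 deg is the positive peak, matching the
#' tracker's phasor convention.
#'
#' @param f Tone frequency in Hz; must satisfy `0 < f < fs/2`.
#' @param fs Sampling rate in Hz (default 208.03, the accelerometer rate).
#' @param duration_s Duration in seconds.
#' @param amplitude Peak amplitude in g.
#' @param phase0 Initial phase in degrees.
#' @return A tibble with columns `time_s`, `value` (g) and `phase_true_deg`
#'   (degrees in \[0, 360)).
#' @examples
#' tone <- gen_pure_sine(5, duration_s = 2)
#' head(tone)
#' @export
gen_pure_sine <- function(f, fs = 208.03, duration_s = 10, amplitude = 1,
                          phase0 = 0) {
  check_scalar_pos(f, "f")
  check_scalar_pos(fs, "fs")
  check_scalar_pos(duration_s, "duration_s")
  check_that(f < fs / 2, "`f` must be below the Nyquist frequency fs/2")
  n <- round(duration_s * fs)
  idx <- seq_len(n) - 1
  phase_deg <- wrap_deg(360 * f * idx / fs + phase0)
  tibble(
    time_s = idx / fs,
    value = amplitude * cospi((360 * f * idx / fs + phase0) / 180),
    phase_true_deg = phase_deg
  )
}

#' Generate colored (pink or brown) noise
#'
#' Emulates real-world accelerometer noise. Pink (1/f power) noise is built
#' by spectrally shaping white Gaussian noise with a 1/sqrt(f) amplitude
#' mask; brown (1/f^2) noise by cumulative summation of white noise. Both are
#' mean-removed and normalized to an exact RMS of `scale`.
#'
#' @param kind `"pink"` or `"brown"`.
#' @param n Number of samples.
#' @param scale Target RMS in g; 0 yields an all-zero sequence.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Numeric vector of length `n`.
#' @export
gen_colored_noise <- function(kind, n, scale = 1, seed = NULL) {
  check_that(is.character(kind) && length(kind) == 1 && kind %in% c("pink", "brown"),
             "`kind` must be one of \"pink\", \"brown\"")
  check_that(is.numeric(n) && length(n) == 1 && n >= 1 && n == round(n),
             "`n` must be a positive integer number of samples")
  check_that(is.numeric(scale) && length(scale) == 1 && scale >= 0,
             "`scale` must be a non-negative RMS in g")
  if (scale == 0) return(numeric(n))
  x <- with_seed(seed, {
    w <- rnorm(n)
    if (kind == "brown") {
      cumsum(w)
    } else {
      # symmetric 1/sqrt(f) amplitude mask; DC bin zeroed for zero mean.
      # Shaped at a 2-3-5-smooth length and truncated (stationary, so the
      # truncation keeps the spectrum).
      m <- fast_fft_len(n)
      wm <- if (m > n) c(w, rnorm(m - n)) else w
      fw <- fft(wm)
      k <- 0:(m - 1)
      fbin <- pmin(k, m - k)           # symmetric frequency index
      mask <- ifelse(fbin == 0, 0, 1 / sqrt(fbin))
      Re(fft(fw * mask, inverse = TRUE) / m)[seq_len(n)]
    }
  })
  x <- x - mean(x)
  x * scale / sqrt(mean(x^2))
}

#' Define a synthetic tremor scenario
#'
#' A scenario states everything the generator needs: per-axis amplitude
#' envelopes, a center-frequency trajectory, cessation intervals where the
#' oscillation vanishes (tremor stopping, as seen clinically for a minute or
#' more), DC offsets (gravity/temperature drift), colored noise, and a seed.
#'
#' Envelopes may be a single number (constant, g), a data frame with columns
#' `time_s`/`value` (interpolated), or a function of time. The frequency
#' trajectory may be a single number or a data frame `time_s`/`f_hz`
#' (piecewise-constant); it must stay within the 2-8 Hz tremor band.
#'
#' @param duration_s Total duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param envelope Named list with elements `x`, `y`, `z` (missing axes are
#'   zero), each a constant, data frame, or function, in g.
#' @param freq Center-frequency trajectory in Hz (see above).
#' @param cessation Data frame with columns `start_s`, `end_s`: intervals
#'   where the oscillatory component of all axes is zero.
#' @param dc_offset Length-3 numeric (x, y, z) DC offsets in g.
#' @param noise_kind `"none"`, `"pink"` or `"brown"`.
#' @param noise_scale Noise RMS in g (per axis, independent realizations).
#' @param phase0 Initial oscillation phase in degrees.
#' @param envelope_method Interpolation for data-frame envelopes: `"linear"`
#'   or `"constant"`.
#' @param seed Integer seed making the generated record reproducible.
#' @return An object of class `tremor_scenario`.
#' @seealso [gen_tremor_record()]
#' @export
tremor_scenario <- function(duration_s, fs = 208.03,
                            envelope = list(y = 1),
                            freq = 5,
                            cessation = NULL,
                            dc_offset = c(0, 0, 0),
                            noise_kind = c("none", "pink", "brown"),
                            noise_scale = 0,
                            phase0 = 0,
                            envelope_method = c("linear", "constant"),
                            seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  envelope_method <- match.arg(envelope_method)
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(fs, "fs")
  check_that(is.list(envelope) && all(names(envelope) %in% c("x", "y", "z")),
             "`envelope` must be a named list with elements among x, y, z")
  fvals <- if (is.data.frame(freq)) freq$f_hz else freq
  check_that(all(fvals >= 2 & fvals <= 8),
             "center-frequency trajectory must stay within the 2-8 Hz tremor band")
  check_that(fs > 2 * max(fvals), "`fs` must exceed twice the maximum frequency (Nyquist)")
  if (!is.null(cessation)) {
    check_that(is.data.frame(cessation) &&
                 all(c("start_s", "end_s") %in% names(cessation)),
               "`cessation` must be a data frame with columns start_s, end_s")
    check_that(all(cessation$start_s >= 0) && all(cessation$end_s <= duration_s) &&
                 all(cessation$start_s < cessation$end_s),
               "cessation intervals must lie within [0, duration_s]")
  }
  check_that(length(dc_offset) == 3, "`dc_offset` must have 3 elements (x, y, z)")
  check_that(is.numeric(noise_scale) && noise_scale >= 0,
             "`noise_scale` must be a non-negative RMS in g")
  structure(
    list(duration_s = duration_s, fs = fs, envelope = envelope, freq = freq,
         cessation = cessation, dc_offset = as.numeric(dc_offset),
         noise_kind = noise_kind, noise_scale = noise_scale, phase0 = phase0,
         envelope_method = envelope_method, seed = as.integer(seed)),
    class = "tremor_scenario"
  )
}

#' @export
print.tremor_scenario <- function(x, ...) {
  cat(sprintf("<tremor_scenario> %.5g s at %g Hz, axes {%s}, noise %s (RMS %g g), seed %d\n",
              x$duration_s, x$fs, paste(names(x$envelope), collapse = ", "),
              x$noise_kind, x$noise_scale, x$seed))
  invisible(x)
}

env_fun <- function(spec, method) {
  if (is.null(spec)) return(function(t) numeric(length(t)))
  if (is.function(spec)) return(spec)
  if (is.data.frame(spec)) {
    check_that(all(c("time_s", "value") %in% names(spec)),
               "data-frame envelopes need columns time_s, value")
    return(approxfun(spec$time_s, spec$value, method = method, rule = 2))
  }
  force(spec)
  function(t) rep(as.numeric(spec), length(t))
}

freq_fun <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.data.frame(spec)) {
    check_that(all(c("time_s", "f_hz") %in% names(spec)),
               "data-frame frequency trajectories need columns time_s, f_hz")
    return(approxfun(spec$time_s, spec$f_hz, method = "constant", rule = 2))
  }
  force(spec)
  function(t) rep(as.numeric(spec), length(t))
}

#' Generate a triaxial tremor record from a scenario
#'
#' Each axis is `envelope(t) * cos(phi(t)) + dc + noise`, with the phase
#' integrated from the frequency trajectory (phase-continuous: frequency
#' steps create no phase jump). Ground-truth tracks are attached per sample:
#' true phase, true center frequency, and the true dominant axis (the axis
#' with the largest instantaneous envelope; `NA` where all envelopes are
#' zero, e.g. during cessation).
#'
#' @param scenario A [tremor_scenario()].
#' @return A `tremor_record`: a tibble with columns `sample_index`, `time_s`,
#'   `ax_g`, `ay_g`, `az_g`, `phase_true_deg`, `axis_true`, `fc_true_hz`,
#'   with the sampling rate in `attr(, "fs")`.
#' @examples
#' rec <- gen_tremor_record(tremor_scenario(duration_s = 5, freq = 4))
#' attr(rec, "fs")
#' @export
gen_tremor_record <- function(scenario) {
  check_that(inherits(scenario, "tremor_scenario"), "`scenario` must be a tremor_scenario")
  fs <- scenario$fs
  n <- round(scenario$duration_s * fs)
  idx <- seq_len(n) - 1
  t <- idx / fs

  f_t <- freq_fun(scenario$freq)(t)
  # phase-continuous integration (left Riemann sum)
  phi_deg <- scenario$phase0 + c(0, cumsum(360 * f_t[-n] / fs))
  osc <- cospi(phi_deg / 180)

  envs <- vapply(c("x", "y", "z"), function(ax) {
    env_fun(scenario$envelope[[ax]], scenario$envelope_method)(t)
  }, numeric(n))
  check_that(all(envs >= 0), "amplitude envelopes must be non-negative")

  if (!is.null(scenario$cessation)) {
    for (r in seq_len(nrow(scenario$cessation))) {
      off <- t >= scenario$cessation$start_s[r] & t < scenario$cessation$end_s[r]
      envs[off, ] <- 0
    }
  }

  noise <- matrix(0, n, 3)
  if (scenario$noise_kind != "none" && scenario$noise_scale > 0) {
    noise <- with_seed(scenario$seed, {
      vapply(1:3, function(i)
        gen_colored_noise(scenario$noise_kind, n, scenario$noise_scale),
        numeric(n))
    })
  }

  sig <- envs * osc + matrix(scenario$dc_offset, n, 3, byrow = TRUE) + noise

  any_on <- rowSums(envs) > 0
  axis_true <- c("x", "y", "z")[max.col(envs, ties.method = "first")]
  axis_true[!any_on] <- NA_character_

  out <- tibble(
    sample_index = idx,
    time_s = t,
    ax_g = sig[, 1], ay_g = sig[, 2], az_g = sig[, 3],
    phase_true_deg = wrap_deg(phi_deg),
    axis_true = axis_true,
    fc_true_hz = f_t
  )
  new_tremor_record(out, fs = fs, scenario = scenario)
}

new_tremor_record <- function(df, fs, scenario = NULL) {
  out <- as_tibble(df)
  attr(out, "fs") <- fs
  attr(out, "scenario") <- scenario
  class(out) <- c("tremor_record", class(out))
  out
}

#' Assemble a triaxial record from raw channels
#'
#' @param ax,ay,az Per-axis acceleration in g (equal lengths).
#' @param fs Sampling rate in Hz.
#' @param truth Optional data frame with any of `phase_true_deg`,
#'   `axis_true`, `fc_true_hz`, one row per sample.
#' @return A `tremor_record` tibble.
#' @export
tremor_record <- function(ax, ay, az, fs, truth = NULL) {
  check_scalar_pos(fs, "fs")
  check_that(length(ax) == length(ay) && length(ay) == length(az),
             "all three channels must have equal length")
  n <- length(ax)
  out <- tibble(sample_index = seq_len(n) - 1L,
                time_s = (seq_len(n) - 1) / fs,
                ax_g = as.numeric(ax), ay_g = as.numeric(ay), az_g = as.numeric(az))
  if (!is.null(truth)) {
    check_that(nrow(truth) == n, "truth, when present, must match the signal length")
    for (col in intersect(c("phase_true_deg", "axis_true", "fc_true_hz"), names(truth)))
      out[[col]] <- truth[[col]]
  }
  new_tremor_record(out, fs = fs)
}

#' Sampling-design arithmetic for the tremor band
#'
#' The design constants behind the accelerometer rate: the Nyquist rate for
#' the top of the tracked band, and the minimum rate resolving a given number
#' of equally spaced phases per cycle.
#'
#' @param f_max Highest tracked frequency in Hz (default 8).
#' @param phases_per_cycle Phases to resolve per cycle (default 6, i.e.
#'   60-degree resolution).
#' @return A one-row tibble with `nyquist_hz` and `min_design_hz`.
#' @export
sampling_design <- function(f_max = 8, phases_per_cycle = 6) {
  tibble(f_max_hz = f_max,
         nyquist_hz = 2 * f_max,
         phases_per_cycle = phases_per_cycle,
         min_design_hz = phases_per_cycle * f_max)
}
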