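# Butterworth designs (second-order sections, bilinear transform) and the
# streaming / zero-phase filtering used before phase tracking and by the
# offline oracle. No DSP package ships with the target environment, so the
# classic designs are implemented here and verified against an independent
# reference in the test suite.

# Analog Butterworth prototype poles (unit cutoff), left half plane.
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Design a digital Butterworth filter as a zpk triple via the bilinear
# transform, then pack into second-order sections. `w` is the cutoff in Hz
# (length 2 for band-pass).
butter_sos <- function(order, w, type = c("low", "high", "band"), fs) {
  type <- match.arg(type)
  check_scalar_pos(fs, "fs")
  check_that(all(w > 0) && all(w < fs / 2),
             sprintf("cutoff frequencies must lie in (0, fs/2) = (0, %g) Hz", fs / 2))
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)

  p <- butter_prototype(order)
  z <- complex(0)
  k <- 1
  if (type == "low") {
    W <- warp(w)
    p <- W * p
    k <- W^order
  } else if (type == "high") {
    W <- warp(w)
    p <- W / p
    z <- rep(0 + 0i, order)
    # gain unchanged: prod(-p_proto) = 1 for a Butterworth prototype
  } else {
    check_that(length(w) == 2 && w[1] < w[2], "band edges must satisfy low < high")
    W1 <- warp(w[1]); W2 <- warp(w[2])
    BW <- W2 - W1
    W0sq <- W1 * W2
    phalf <- p * BW / 2
    disc <- sqrt(phalf^2 - W0sq)
    p <- c(phalf + disc, phalf - disc)
    z <- rep(0 + 0i, order)
    k <- BW^order
  }

  # bilinear transform s -> 2 fs (z-1)/(z+1)
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  zpk2sos(zd, pd, kd)
}

# Pack conjugate pole pairs (and matched zero pairs) into 6-column SOS rows.
# Small-order designs only: every pole/zero occurs in a conjugate pair (or is
# real and paired with another real one).
zpk2sos <- function(z, p, k) {
  pair_up <- function(v) {
    used <- rep(FALSE, length(v))
    pairs <- list()
    for (i in seq_along(v)) {
      if (used[i]) next
      used[i] <- TRUE
      j <- which(!used & abs(v - Conj(v[i])) < 1e-8)[1]
      if (is.na(j)) j <- which(!used)[1]
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(v[i], v[j])
    }
    pairs
  }
  pp <- pair_up(p)
  zp <- pair_up(z)
  ns <- length(pp)
  # greedy: match each pole pair (unit-circle-closest first) to nearest zero pair
  ord <- order(vapply(pp, function(q) abs(1 - abs(q[1])), numeric(1)))
  pp <- pp[ord]
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    dists <- vapply(zp, function(q) abs(q[1] - pp[[s]][1]), numeric(1))
    j <- which.min(dists)
    zz <- zp[[j]]
    zp <- zp[-j]
    b <- Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2]))
    a <- Re(c(1, -(pp[[s]][1] + pp[[s]][2]), pp[[s]][1] * pp[[s]][2]))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_freqz <- function(sos, f, fs) {
  zi <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * zi + sos[s, 3] * zi^2
    den <- sos[s, 4] + sos[s, 5] * zi + sos[s, 6] * zi^2
    h <- h * num / den
  }
  h
}

#' Streaming high-pass filter for accelerometer offset removal
#'
#' Designs the order-2 Butterworth high-pass (second-order sections, direct
#' form I) used to remove the DC/gravity offset before phase tracking. The
#' default 0.1 Hz cutoff sits far below the 2-8 Hz tremor band, so the
#' filter strips drift while leaving tremor phase essentially untouched.
#'
#' The returned object is stateful (an environment), so it can be driven one
#' sample at a time with [filter_step()] exactly as device firmware would, or
#' over a whole vector with [filter_apply()]; both paths produce identical
#' output.
#'
#' @param fs Sampling rate in Hz.
#' @param cutoff High-pass cutoff in Hz (default 0.1).
#' @param order Filter order (default 2).
#' @return An object of class `streaming_filter`.
#' @examples
#' hp <- make_highpass(fs = 208.03)
#' y <- filter_apply(hp, rep(0.5, 1000))  # DC decays toward zero
#' @export
make_highpass <- function(fs, cutoff = 0.1, order = 2) {
  check_scalar_pos(fs, "fs")
  check_scalar_pos(cutoff, "cutoff")
  check_that(cutoff < fs / 2, "`cutoff` must be below the Nyquist frequency fs/2")
  sos <- butter_sos(order, cutoff, "high", fs)
  new_streaming_filter(sos, meta = list(type = "highpass", order = order,
                                        cutoff_hz = cutoff, fs_hz = fs))
}

new_streaming_filter <- function(sos, meta) {
  env <- new.env(parent = emptyenv())
  env$sos <- sos
  env$zi <- matrix(0, nrow(sos), 4)
  env$meta <- meta
  class(env) <- "streaming_filter"
  env
}

#' @export
print.streaming_filter <- function(x, ...) {
  cat(sprintf("<streaming_filter> %s order %d, cutoff %s Hz, fs %g Hz\n",
              x$meta$type, x$meta$order,
              paste(x$meta$cutoff_hz, collapse = "-"), x$meta$fs_hz))
  cat("second-order sections (b0 b1 b2 a0 a1 a2):\n")
  print(x$sos)
  invisible(x)
}

#' Advance a streaming filter by one sample
#'
#' @param filt A `streaming_filter` from [make_highpass()].
#' @param sample One input sample (g). Non-finite input is rejected: on the
#'   device it would signal a sensor fault.
#' @return The filtered output sample. The filter's internal delay state is
#'   advanced in place.
#' @export
filter_step <- function(filt, sample) {
  check_that(length(sample) == 1, "`sample` must be a single value")
  check_finite(sample, "sample")
  res <- cpp_sosfilt(filt$sos, as.numeric(sample), filt$zi)
  filt$zi <- res$zi
  res$y
}

#' Run a streaming filter over a whole signal
#'
#' Identical to calling [filter_step()] sample by sample (the filter is
#' causal); provided for speed.
#'
#' @inheritParams filter_step
#' @param x Input signal (numeric vector, g).
#' @return Filtered signal, same length as `x`.
#' @export
filter_apply <- function(filt, x) {
  check_finite(x, "x")
  res <- cpp_sosfilt(filt$sos, as.numeric(x), filt$zi)
  filt$zi <- res$zi
  res$y
}

#' Reset a streaming filter's delay state to zero
#'
#' @inheritParams filter_step
#' @return The filter, invisibly.
#' @export
filter_reset <- function(filt) {
  filt$zi <- matrix(0, nrow(filt$sos), 4)
  invisible(filt)
}

# Per-section direct-form-I state equal to the steady state for a unit input
# step, chained through the cascade. Used to suppress filtfilt edge
# transients (scale by the first padded sample).
sos_zi_step <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 4)
  u <- 1
  for (s in seq_len(ns)) {
    yss <- u * sum(sos[s, 1:3]) / sum(sos[s, 4:6])
    zi[s, ] <- c(u, u, yss, yss)
    u <- yss
  }
  zi
}

sosfiltfilt <- function(sos, x) {
  n <- length(x)
  padlen <- 3 * (2 * nrow(sos) + 1)
  check_that(n > padlen,
             sprintf("signal too short for zero-phase filtering: need > %d samples, got %d",
                     padlen, n))
  onepass <- function(v) {
    ext <- c(2 * v[1] - rev(v[2:(padlen + 1)]),
             v,
             2 * v[length(v)] - rev(v[(length(v) - padlen):(length(v) - 1)]))
    zi <- sos_zi_step(sos) * ext[1]
    y <- cpp_sosfilt(sos, ext, zi)$y
    y[(padlen + 1):(padlen + length(v))]
  }
  rev(onepass(rev(onepass(x))))
}

#' Zero-phase band-pass filter (offline oracle pre-filter)
#'
#' Forward-backward order-2 Butterworth band-pass, 1-9 Hz by default: the
#' pre-filter applied before the Hilbert transform when validating the
#' real-time tracker offline. Zero-phase by construction, so it introduces no
#' phase bias into the oracle.
#'
#' @param x Single-channel signal (g).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 1 and 9).
#' @return Filtered signal, same length as `x`.
#' @export
offline_bandpass <- function(x, fs, low = 1, high = 9) {
  check_scalar_pos(fs, "fs")
  check_that(0 < low && low < high && high < fs / 2,
             "band edges must satisfy 0 < low < high < fs/2")
  check_finite(x, "x")
  sos <- butter_sos(2, c(low, high), "band", fs)
  sosfiltfilt(sos, as.numeric(x))
}

# smallest 2-3-5-smooth length >= n; R's mixed-radix FFT degrades to O(n^2)
# on large prime factors
fast_fft_len <- function(n) stats::nextn(n, c(2, 3, 5))

# FFT analytic signal: x + i H(x). Computed at a 2-3-5-smooth padded length
# (mirror-extended tail) and truncated; edge effects stay confined to the
# signal ends.
hilbert_analytic <- function(x) {
  n <- length(x)
  m <- fast_fft_len(n)
  xp <- if (m > n) c(x, rev(x)[seq_len(m - n)]) else x
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[1] <- 1; h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  (fft(fft(xp) * h, inverse = TRUE) / m)[seq_len(n)]
}
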