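# Adaptive stream bank: 3 axes x 7 center frequencies of the phase tracker
# run in parallel, with 10-s moving averages driving periodic self-tuning:
# the dominant axis is the one with the largest mean |amplitude| (mu_axis),
# and within it the center frequency with the smallest mean |error|
# (mu_error) wins. Selection happens at a programmable cadence (20 s by
# default, once per stimulation block) and the locked stream is never
# changed between selection instants.

#' Exact rectangular-window moving average
#'
#' Running mean of the last `window` samples; before `window` samples have
#' been seen, the mean of all available samples is used (partial window).
#'
#' @param x Numeric vector.
#' @param window Window length in samples (default `round(10 * 208.03)`,
#'   the 10-s window at the accelerometer rate).
#' @return Numeric vector of running means, same length as `x`.
#' @export
moving_average <- function(x, window = round(10 * 208.03)) {
  check_finite(x, "x")
  check_that(is.numeric(window) && length(window) == 1 && window >= 1 &&
               window == round(window),
             "`window` must be a positive integer number of samples")
  cpp_moving_average(as.numeric(x), as.integer(window))
}

#' Create an adaptive stream bank
#'
#' The bank holds one tracker per (axis, center frequency) pair -- 21
#' streams with the default 2-8 Hz grid -- all stepped every sample, plus
#' the moving averages `mu_axis` (per axis, of |filtered amplitude|) and
#' `mu_error` (per stream, of |prediction error|) used for self-tuning.
#' Before the first selection the locked stream defaults to the y axis
#' (the wrist-worn placement biases tremor sideways) at 5 Hz.
#'
#' The returned object is stateful; drive it with [bank_step()] and
#' [select_stream()], or process a whole record with [track_record()].
#'
#' @param fs Sampling rate in Hz.
#' @param grid Center-frequency grid in Hz (default `2:8`).
#' @param G Tracker gain in (0, 1).
#' @param interval_s Selection cadence in seconds (default 20).
#' @param ma_window_s Moving-average window in seconds (default 10).
#' @param init_axis,init_fc Locked stream before the first selection.
#' @return An object of class `stream_bank`.
#' @export
stream_bank <- function(fs = 208.03, grid = 2:8, G = 0.25, interval_s = 20,
                        ma_window_s = 10, init_axis = "y", init_fc = 5) {
  check_scalar_pos(fs, "fs")
  check_that(length(grid) >= 1 && all(grid > 0) && all(grid < fs / 2),
             "`grid` frequencies must lie in (0, fs/2)")
  check_that(init_axis %in% c("x", "y", "z"), "`init_axis` must be x, y or z")
  check_that(init_fc %in% grid, "`init_fc` must be on the frequency grid")
  check_scalar_pos(interval_s, "interval_s")
  check_scalar_pos(ma_window_s, "ma_window_s")
  grid <- as.numeric(grid)
  nf <- length(grid)
  W <- as.integer(round(ma_window_s * fs))

  env <- new.env(parent = emptyenv())
  env$fs <- fs
  env$grid <- grid
  env$G <- G
  env$interval_samples <- as.integer(round(interval_s * fs))
  env$interval_s <- interval_s
  env$W <- W
  env$theta <- 2 * pi * grid / fs
  env$a <- matrix(0, 3, nf)        # phasor real part, axes x rows
  env$b <- matrix(0, 3, nf)
  env$mu_axis_buf <- matrix(0, W, 3)
  env$mu_axis_sum <- numeric(3)
  env$mu_err_buf <- array(0, c(W, 3, nf))
  env$mu_err_sum <- matrix(0, 3, nf)
  env$count <- 0L
  env$sel_axis <- match(init_axis, c("x", "y", "z"))
  env$sel_fc <- match(init_fc, grid)
  env$selection_log <- list()
  class(env) <- "stream_bank"
  env
}

#' @export
print.stream_bank <- function(x, ...) {
  cat(sprintf("<stream_bank> %d streams (3 axes x %d frequencies: %s Hz), G = %g\n",
              3 * length(x$grid), length(x$grid),
              paste(range(x$grid), collapse = "-"), x$G))
  cat(sprintf("  locked: axis %s, fc %g Hz; selection every %g s; %d samples seen\n",
              c("x", "y", "z")[x$sel_axis], x$grid[x$sel_fc],
              x$interval_s, x$count))
  invisible(x)
}

mu_axis_values <- function(bank) {
  m <- min(bank$count, bank$W)
  if (m == 0) return(numeric(3))
  bank$mu_axis_sum / m
}

mu_error_values <- function(bank) {
  m <- min(bank$count, bank$W)
  if (m == 0) return(matrix(0, 3, length(bank$grid)))
  bank$mu_err_sum / m
}

#' Step all streams of a bank by one triaxial sample
#'
#' Every tracker is stepped with its axis's (already offset-removed)
#' sample; `mu_axis` is updated with the absolute sample per axis and
#' `mu_error` with each stream's absolute prediction error. Selection is
#' not performed here -- call [select_stream()] at selection instants, or
#' use [track_record()] which handles the cadence.
#'
#' @param bank A [stream_bank()].
#' @param sample Length-3 numeric `(x, y, z)` in g, high-pass filtered.
#' @return A list with `streams` (tibble of 21 rows: `axis`, `fc_hz`,
#'   `phi_deg`, `M`, `e`) and `locked` (one-row tibble for the locked
#'   stream).
#' @export
bank_step <- function(bank, sample) {
  check_that(length(sample) == 3, "`sample` must be length 3 (x, y, z)")
  check_finite(sample, "sample")
  nf <- length(bank$grid)
  e <- sweep(-bank$a, 1, as.numeric(sample), "+")        # x_in - a per stream
  astar <- bank$a + bank$G * e
  phi <- wrap_deg(atan2(bank$b, astar) * 180 / pi)
  M <- sqrt(astar^2 + bank$b^2)

  pos <- (bank$count %% bank$W) + 1L
  full <- bank$count >= bank$W
  if (full) bank$mu_axis_sum <- bank$mu_axis_sum - bank$mu_axis_buf[pos, ]
  bank$mu_axis_buf[pos, ] <- abs(as.numeric(sample))
  bank$mu_axis_sum <- bank$mu_axis_sum + bank$mu_axis_buf[pos, ]
  if (full) bank$mu_err_sum <- bank$mu_err_sum - bank$mu_err_buf[pos, , ]
  bank$mu_err_buf[pos, , ] <- abs(e)
  bank$mu_err_sum <- bank$mu_err_sum + abs(e)
  bank$count <- bank$count + 1L

  cth <- cos(bank$theta); sth <- sin(bank$theta)
  a_new <- sweep(astar, 2, cth, "*") - sweep(bank$b, 2, sth, "*")
  b_new <- sweep(astar, 2, sth, "*") + sweep(bank$b, 2, cth, "*")
  bank$a <- a_new
  bank$b <- b_new

  streams <- tibble(
    axis = rep(c("x", "y", "z"), times = nf),
    fc_hz = rep(bank$grid, each = 3),
    phi_deg = as.numeric(phi), M = as.numeric(M), e = as.numeric(e)
  )
  locked <- streams[streams$axis == c("x", "y", "z")[bank$sel_axis] &
                      streams$fc_hz == bank$grid[bank$sel_fc], ]
  list(streams = streams, locked = locked)
}

#' Select the dominant axis and center frequency
#'
#' The self-tuning rule, intended to run at selection instants (every
#' `interval_s`): the dominant axis is the one with the largest `mu_axis`;
#' on that axis, the center frequency of the stream with the smallest
#' `mu_error` wins. Exact ties keep the incumbent selection (avoiding
#' phase-reference churn); otherwise the first candidate in x, y, z /
#' ascending-frequency order is taken. Called before any samples have been
#' seen, the default selection is returned with a warning.
#'
#' @param bank A [stream_bank()].
#' @return A one-row tibble `axis`, `fc_hz` (the new locked selection; the
#'   bank is updated in place).
#' @export
select_stream <- function(bank) {
  if (bank$count == 0L) {
    warn("select_stream() called before any samples; keeping the default selection")
    return(tibble(axis = c("x", "y", "z")[bank$sel_axis],
                  fc_hz = bank$grid[bank$sel_fc]))
  }
  mu_ax <- mu_axis_values(bank)
  best <- max(mu_ax)
  new_axis <- if (mu_ax[bank$sel_axis] == best) bank$sel_axis else which(mu_ax == best)[1]
  mu_err <- mu_error_values(bank)[new_axis, ]
  best_err <- min(mu_err)
  new_fc <- if (new_axis == bank$sel_axis && mu_err[bank$sel_fc] == best_err)
    bank$sel_fc else which(mu_err == best_err)[1]
  bank$sel_axis <- new_axis
  bank$sel_fc <- new_fc
  tibble(axis = c("x", "y", "z")[new_axis], fc_hz = bank$grid[new_fc])
}

#' Track a triaxial record with the full adaptive pipeline
#'
#' The production path: each axis is high-pass filtered for offset removal
#' (streaming, causal), all 21 streams are stepped every sample, and the
#' locked stream is re-selected at the stated cadence. Runs in compiled
#' code; [bank_step()]/[select_stream()] give the identical sample-level
#' semantics in R.
#'
#' @param record A `tremor_record` (or any data frame with `ax_g`, `ay_g`,
#'   `az_g`), with sampling rate in `attr(, "fs")` unless `fs` is given.
#' @param fs Sampling rate in Hz (overrides the record attribute).
#' @param grid,G,interval_s,ma_window_s,init_axis,init_fc See
#'   [stream_bank()].
#' @param highpass_cutoff Offset-removal cutoff in Hz (default 0.1).
#' @return A `tremor_track` object: list with `samples` (tibble `time_s`,
#'   `phi_deg`, `M`, `e`, `axis`, `fc_hz`) and `selections` (one row per
#'   selection instant: `time_s`, `axis`, `fc_hz`, `mu_axis_x/y/z`,
#'   `mu_error_<fc>` for the chosen axis).
#' @examples
#' rec <- gen_tremor_record(tremor_scenario(duration_s = 30, freq = 4))
#' trk <- track_record(rec)
#' glance(trk)
#' @export
track_record <- function(record, fs = NULL, grid = 2:8, G = 0.25,
                         interval_s = 20, ma_window_s = 10,
                         init_axis = "y", init_fc = 5,
                         highpass_cutoff = 0.1) {
  check_that(all(c("ax_g", "ay_g", "az_g") %in% names(record)),
             "`record` must have columns ax_g, ay_g, az_g")
  fs <- fs %||% attr(record, "fs")
  check_that(!is.null(fs), "`fs` missing: give it or use a tremor_record")
  check_that(init_fc %in% grid, "`init_fc` must be on the frequency grid")
  grid <- as.numeric(grid)

  X <- vapply(c("ax_g", "ay_g", "az_g"), function(col) {
    filter_apply(make_highpass(fs, highpass_cutoff), record[[col]])
  }, numeric(nrow(record)))

  res <- cpp_bank_run(X, fs, grid, G,
                      as.integer(round(interval_s * fs)),
                      as.integer(round(ma_window_s * fs)),
                      match(init_axis, c("x", "y", "z")),
                      match(init_fc, grid))

  samples <- tibble(
    time_s = (seq_len(nrow(record)) - 1) / fs,
    phi_deg = res$phi, M = res$M, e = res$e,
    axis = c("x", "y", "z")[res$axis], fc_hz = res$fc
  )
  sel <- res$selection_log
  colnames(sel) <- c("time_s", "axis_idx", "fc_hz",
                     "mu_axis_x", "mu_axis_y", "mu_axis_z",
                     paste0("mu_error_", grid))
  selections <- as_tibble(sel) %>%
    mutate(axis = c("x", "y", "z")[.data$axis_idx], .after = "time_s") %>%
    select(-"axis_idx")

  structure(list(samples = samples, selections = selections,
                 fs = fs, grid = grid, G = G, interval_s = interval_s,
                 ma_window_s = ma_window_s, highpass_cutoff = highpass_cutoff),
            class = "tremor_track")
}

#' @export
print.tremor_track <- function(x, ...) {
  cat(sprintf("<tremor_track> %d samples at %g Hz (%.4g s), G = %g\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs, x$G))
  cat(sprintf("  %d selection instants (every %g s); final lock: axis %s, fc %g Hz\n",
              nrow(x$selections), x$interval_s,
              tail(x$samples$axis, 1), tail(x$samples$fc_hz, 1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
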