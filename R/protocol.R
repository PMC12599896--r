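# Phase-locked trigger logic and the two-stage in-clinic protocol:
# a 10-min baseline, a ~27-min random search over eight stimulation states
# (six phases at 60-degree resolution, open-loop high-frequency, sham) in
# ten shuffled blocks of 10 s on / 10 s off, then a 1-min baseline and 10
# minutes of continuous stimulation at the state scored most suppressive by
# the on-board envelope.

#' Phase-trigger error budget
#'
#' The tolerance around the target phase within which triggering is
#' permitted, equal to the theoretical phase resolution of one sample:
#' `fc / fs * 360` degrees. At fs = 208.03 Hz this spans about 3.5 degrees
#' at 2 Hz up to about 13.8 degrees at 8 Hz.
#'
#' @param fc Locked center frequency in Hz; `0 < fc < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return Budget in degrees.
#' @examples
#' error_budget(8, 208.03)
#' @export
error_budget <- function(fc, fs = 208.03) {
  check_scalar_pos(fc, "fc")
  check_scalar_pos(fs, "fs")
  check_that(fc < fs / 2, "`fc` must be below the Nyquist frequency fs/2")
  fc / fs * 360
}

#' Trigger configuration for one locked stream
#'
#' @param target_phase_deg Target stimulation phase in degrees \[0, 360).
#' @param fc Locked center frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum time between triggers; defaults to half a
#'   tremor period (`0.5 / fc`), preventing re-triggering within one cycle.
#'   Must exceed the 5-pulse burst duration (`8 / fs` s).
#' @param pulses_per_burst Pulses per burst (default 5, at fs/2 Hz).
#' @return A `trigger_config` list including the derived `budget_deg`.
#' @export
trigger_config <- function(target_phase_deg, fc, fs = 208.03,
                           refractory_s = 0.5 / fc, pulses_per_burst = 5) {
  check_that(is.numeric(target_phase_deg) && length(target_phase_deg) == 1 &&
               target_phase_deg >= 0 && target_phase_deg < 360,
             "`target_phase_deg` must be in [0, 360)")
  budget <- error_budget(fc, fs)
  burst_s <- 2 * (pulses_per_burst - 1) / fs
  check_that(refractory_s > burst_s,
             "`refractory_s` must exceed the burst duration (pulses at fs/2)")
  structure(list(target_phase_deg = target_phase_deg, fc = fc, fs = fs,
                 budget_deg = budget, refractory_s = refractory_s,
                 refractory_samples = as.integer(round(refractory_s * fs)),
                 pulses_per_burst = as.integer(pulses_per_burst),
                 burst_rate_hz = fs / 2),
            class = "trigger_config")
}

#' Should stimulation trigger at this sample?
#'
#' Triggering is permitted when the refractory interval has elapsed and the
#' current -- or, to avoid missed crossings, the previous -- phase estimate
#' lies within the error budget of the target phase (circular distance).
#'
#' @param phi_now,phi_prev Current and previous phase estimates in degrees.
#' @param cfg A [trigger_config()].
#' @param samples_since_last_trigger Samples since the last trigger
#'   (`Inf` if none yet).
#' @return Logical.
#' @export
should_trigger <- function(phi_now, phi_prev, cfg,
                           samples_since_last_trigger = Inf) {
  check_that(inherits(cfg, "trigger_config"), "`cfg` must be a trigger_config")
  samples_since_last_trigger >= cfg$refractory_samples &&
    (circ_dist(phi_now, cfg$target_phase_deg) <= cfg$budget_deg ||
       circ_dist(phi_prev, cfg$target_phase_deg) <= cfg$budget_deg)
}

#' Pulse times of one stimulation burst
#'
#' Five pulses at half the sampling rate: every second sample starting at
#' the trigger, spanning `8 / fs` s (about 38.5 ms at 208.03 Hz).
#'
#' @param trigger_index 0-based sample index of the trigger.
#' @param fs Sampling rate in Hz.
#' @param pulses Number of pulses (default 5).
#' @return Integer vector of pulse sample indices.
#' @export
emit_burst <- function(trigger_index, fs = 208.03, pulses = 5) {
  check_that(is.numeric(trigger_index) && length(trigger_index) == 1 &&
               trigger_index >= 0 && trigger_index == round(trigger_index),
             "`trigger_index` must be a non-negative sample index")
  as.integer(trigger_index + 2 * (seq_len(pulses) - 1))
}

protocol_states <- function() {
  c(paste0("phase_", seq(0, 300, by = 60)), "open_loop", "sham")
}

#' Build the two-stage protocol schedule
#'
#' Stage 1: 10-minute baseline, then ten random-search blocks. Each block
#' presents the eight stimulation states -- phasic at 0, 60, ..., 300
#' degrees, open-loop high-frequency, and sham -- in a fresh random order
#' without repetition; every state lasts 10 s followed by 10 s off. Stage
#' 2: 1-minute baseline, then 10 minutes of continuous stimulation at the
#' chosen state. Total 2860 s, about 48 minutes.
#'
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param baseline1_s,baseline2_s,continuous_s,blocks,trial_on_s,trial_off_s
#'   Stage durations (defaults per the in-clinic protocol).
#' @return A `protocol_schedule`: list with a `trials` tibble (`block`,
#'   `slot`, `state`, `on_start_s`, `on_end_s`, `off_end_s`) and stage
#'   timing.
#' @examples
#' sch <- build_schedule(seed = 7)
#' sch$total_s / 60  # ~47.7 minutes
#' @export
build_schedule <- function(seed = 1L, baseline1_s = 600, baseline2_s = 60,
                           continuous_s = 600, blocks = 10,
                           trial_on_s = 10, trial_off_s = 10) {
  states <- protocol_states()
  ns <- length(states)
  order_mat <- with_seed(seed, {
    vapply(seq_len(blocks), function(b) sample(ns), integer(ns))
  })
  trial_len <- trial_on_s + trial_off_s
  trials <- purrr::map_dfr(seq_len(blocks), function(b) {
    tibble(block = b, slot = seq_len(ns), state = states[order_mat[, b]])
  }) %>%
    mutate(
      on_start_s = baseline1_s + (((.data$block - 1) * ns + (.data$slot - 1)) * trial_len),
      on_end_s = .data$on_start_s + trial_on_s,
      off_end_s = .data$on_start_s + trial_len
    )
  search_s <- blocks * ns * trial_len
  structure(list(
    trials = trials, states = states, seed = as.integer(seed),
    baseline1_s = baseline1_s, search_s = search_s,
    baseline2_s = baseline2_s, continuous_s = continuous_s,
    trial_on_s = trial_on_s, trial_off_s = trial_off_s,
    continuous_start_s = baseline1_s + search_s + baseline2_s,
    total_s = baseline1_s + search_s + baseline2_s + continuous_s
  ), class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> seed %d: %g s baseline + %g s random search (%d blocks x %d states) + %g s baseline + %g s continuous = %g s (%.1f min)\n",
              x$seed, x$baseline1_s, x$search_s,
              max(x$trials$block), length(x$states),
              x$baseline2_s, x$continuous_s, x$total_s, x$total_s / 60))
  invisible(x)
}

# greedy refractory-respecting trigger scan over one trial's locked phases;
# returns 0-based global sample indices of triggers
scan_triggers <- function(idx, phi, cfg) {
  within <- circ_dist(phi, cfg$target_phase_deg) <= cfg$budget_deg
  prev_within <- c(FALSE, within[-length(within)])
  cand <- which(within | prev_within)
  trig <- integer(0)
  last <- -Inf
  for (k in cand) {
    if (idx[k] - last >= cfg$refractory_samples) {
      trig <- c(trig, idx[k])
      last <- idx[k]
    }
  }
  trig
}

#' Run the full in-clinic protocol on a record
#'
#' Runs the adaptive bank over the record (selection every
#' `trial_on_s + trial_off_s` seconds, so a fresh lock precedes every
#' trial), then walks the schedule: phasic states trigger bursts through
#' [should_trigger()] at their target phase, the open-loop state emits
#' bursts continuously without phase gating, and sham emits nothing.
#' Per-trial severity change is the percentage change of the median
#' on-board envelope (the locked stream's magnitude M) in the 10-s
#' stimulation window relative to the immediately preceding 10-s
#' no-stimulation window. The state with the lowest median change across
#' its trials is chosen for the continuous stage.
#'
#' Stimulation does not feed back on the signal (the package cannot know
#' the physiological response); an optional `response_model(state,
#' target_phase_deg)` returning a multiplicative envelope gain can emulate
#' a phase-dependent effect on the scored envelope for experimentation.
#'
#' @param record A `tremor_record` covering the schedule (shorter records
#'   yield a truncated run, flagged in the result).
#' @param schedule A [build_schedule()].
#' @param fs Sampling rate in Hz (defaults to the record's).
#' @param grid,G,init_axis,init_fc,highpass_cutoff Passed to
#'   [track_record()].
#' @param response_model Optional function; see above.
#' @return A `protocol_result`: list with `events` (tibble: `sample_index`,
#'   `time_s`, `kind`, `state`, `block`, `target_phase_deg`,
#'   `est_phase_deg`, `axis`, `fc_hz`), `trials` (tibble: `block`, `state`,
#'   `change_percent`), `best_state`, `continuous` (one-row tibble),
#'   `track`, `schedule`, and `truncated`.
#' @export
run_protocol <- function(record, schedule = build_schedule(),
                         fs = NULL, grid = 2:8, G = 0.25,
                         init_axis = "y", init_fc = 5,
                         highpass_cutoff = 0.1,
                         response_model = NULL) {
  check_that(inherits(schedule, "protocol_schedule"),
             "`schedule` must come from build_schedule()")
  fs <- fs %||% attr(record, "fs")
  check_that(!is.null(fs), "`fs` missing: give it or use a tremor_record")
  n <- nrow(record)
  duration_s <- n / fs
  truncated <- duration_s < schedule$total_s

  interval_s <- schedule$trial_on_s + schedule$trial_off_s
  trk <- track_record(record, fs = fs, grid = grid, G = G,
                      interval_s = interval_s, init_axis = init_axis,
                      init_fc = init_fc, highpass_cutoff = highpass_cutoff)
  samp <- trk$samples

  target_of <- function(state) {
    if (startsWith(state, "phase_")) as.numeric(sub("phase_", "", state)) else NA_real_
  }
  win_idx <- function(from_s, to_s) {
    lo <- ceiling(from_s * fs - 1e-9)
    hi <- ceiling(to_s * fs - 1e-9) - 1
    if (hi >= n) hi <- n - 1
    if (lo > hi) return(integer(0))
    seq.int(lo, hi) + 1L   # 1-based rows
  }

  events <- list()
  trial_rows <- list()
  add_event <- function(sample_index, kind, state, block, target, rows1) {
    tibble(sample_index = as.integer(sample_index),
           time_s = sample_index / fs, kind = kind, state = state,
           block = as.integer(block), target_phase_deg = target,
           est_phase_deg = samp$phi_deg[rows1],
           axis = samp$axis[rows1], fc_hz = samp$fc_hz[rows1])
  }

  run_state_window <- function(state, block, on_rows, target) {
    if (length(on_rows) == 0 || state == "sham") return(NULL)
    i0 <- on_rows[1] - 1L                                  # 0-based window start
    fc_lock <- samp$fc_hz[on_rows[1]]
    if (state == "open_loop") {
      # back-to-back bursts, no phase gating: one burst every 10 samples
      trig <- i0 + seq.int(0, length(on_rows) - 1, by = 10)
    } else {
      cfg <- trigger_config(target, fc_lock, fs)
      trig <- scan_triggers(i0 + seq_along(on_rows) - 1L, samp$phi_deg[on_rows], cfg)
    }
    if (length(trig) == 0) return(NULL)
    ev_t <- add_event(trig, "trigger", state, block, target, trig + 1L)
    pulses <- as.integer(outer(2 * (0:4), trig, "+"))
    pulses <- pulses[pulses < n]
    ev_p <- add_event(pulses, "pulse", state, block, target,
                      pulses + 1L)
    bind_rows(ev_t, ev_p)
  }

  tr <- schedule$trials
  for (r in seq_len(nrow(tr))) {
    on_rows <- win_idx(tr$on_start_s[r], tr$on_end_s[r])
    if (length(on_rows) < round(schedule$trial_on_s * fs) - 1) next  # truncated
    base_rows <- win_idx(tr$on_start_s[r] - schedule$trial_off_s, tr$on_start_s[r])
    state <- tr$state[r]
    target <- target_of(state)
    events[[length(events) + 1]] <- bind_rows(
      add_event(on_rows[1] - 1L, "state_start", state, tr$block[r], target, on_rows[1]),
      run_state_window(state, tr$block[r], on_rows, target),
      add_event(on_rows[length(on_rows)], "state_end", state, tr$block[r],
                target, on_rows[length(on_rows)])
    )
    env_on <- samp$M[on_rows]
    if (!is.null(response_model) && state != "sham")
      env_on <- env_on * response_model(state, target)
    ch <- trial_change(c(samp$M[base_rows], env_on),
                       stim_window = length(base_rows) + seq_along(env_on),
                       baseline_window = seq_along(base_rows))
    trial_rows[[length(trial_rows) + 1]] <-
      tibble(block = tr$block[r], state = state,
             change_percent = ch$change_percent, undefined = ch$undefined)
  }

  trials <- if (length(trial_rows)) bind_rows(trial_rows) else
    tibble(block = integer(), state = character(),
           change_percent = numeric(), undefined = logical())
  per_state <- trials %>%
    filter(!.data$undefined) %>%
    group_by(.data$state) %>%
    summarise(median_change = median(.data$change_percent), n_trials = n(),
              .groups = "drop")
  best_state <- if (nrow(per_state) > 0)
    per_state$state[which.min(per_state$median_change)] else NA_character_

  continuous <- NULL
  cont_rows <- win_idx(schedule$continuous_start_s,
                       schedule$continuous_start_s + schedule$continuous_s)
  if (!is.na(best_state) &&
      length(cont_rows) >= round(schedule$continuous_s * fs) - 1) {
    target <- target_of(best_state)
    events[[length(events) + 1]] <- bind_rows(
      add_event(cont_rows[1] - 1L, "state_start", best_state, NA, target, cont_rows[1]),
      run_state_window(best_state, NA, cont_rows, target),
      add_event(cont_rows[length(cont_rows)], "state_end", best_state, NA,
                target, cont_rows[length(cont_rows)])
    )
    base2 <- win_idx(schedule$continuous_start_s - schedule$baseline2_s,
                     schedule$continuous_start_s)
    env_on <- samp$M[cont_rows]
    if (!is.null(response_model) && best_state != "sham")
      env_on <- env_on * response_model(best_state, target)
    ch <- trial_change(c(samp$M[base2], env_on),
                       stim_window = length(base2) + seq_along(env_on),
                       baseline_window = seq_along(base2))
    continuous <- tibble(state = best_state, change_percent = ch$change_percent,
                         undefined = ch$undefined)
  }

  events <- if (length(events)) bind_rows(events) %>% arrange(.data$sample_index)
            else tibble(sample_index = integer(), time_s = numeric(),
                        kind = character(), state = character(),
                        block = integer(), target_phase_deg = numeric(),
                        est_phase_deg = numeric(), axis = character(),
                        fc_hz = numeric())
  structure(list(events = events, trials = trials, per_state = per_state,
                 best_state = best_state, continuous = continuous,
                 track = trk, schedule = schedule, fs = fs,
                 truncated = truncated),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %d trials scored, %d trigger events%s\n",
              nrow(x$trials), sum(x$events$kind == "trigger"),
              if (x$truncated) " [TRUNCATED: record shorter than schedule]" else ""))
  cat(sprintf("  best state: %s", x$best_state))
  if (!is.null(x$continuous))
    cat(sprintf(" (continuous stage change: %+.1f%%)", x$continuous$change_percent))
  cat("\n")
  invisible(x)
}
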