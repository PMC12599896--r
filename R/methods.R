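# broom-style accessors and ggplot2 visualizations for the result objects.

#' @exportS3Method generics::tidy
tidy.tremor_track <- function(x, ...) x$samples

#' @exportS3Method generics::glance
glance.tremor_track <- function(x, ...) {
  tibble(n_samples = nrow(x$samples), fs_hz = x$fs,
         duration_s = nrow(x$samples) / x$fs,
         n_streams = 3 * length(x$grid), G = x$G,
         n_selections = nrow(x$selections),
         final_axis = tail(x$samples$axis, 1),
         final_fc_hz = tail(x$samples$fc_hz, 1),
         mean_envelope_g = mean(x$samples$M))
}

#' @exportS3Method generics::tidy
tidy.protocol_result <- function(x, ...) x$trials

#' @exportS3Method generics::glance
glance.protocol_result <- function(x, ...) {
  tibble(n_trials = nrow(x$trials),
         n_triggers = sum(x$events$kind == "trigger"),
         n_pulses = sum(x$events$kind == "pulse"),
         best_state = x$best_state,
         continuous_change_percent = if (is.null(x$continuous)) NA_real_
                                     else x$continuous$change_percent,
         truncated = x$truncated)
}

#' @exportS3Method generics::tidy
tidy.state_profile <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.state_profile <- function(x, ...) {
  tibble(n_states = nrow(x), n_significant = sum(x$significant, na.rm = TRUE),
         alpha = attr(x, "alpha"), n_comparisons = attr(x, "n_comparisons"))
}

#' Plot the locked phase, envelope and stream selection of a tracked record
#'
#' @param object A `tremor_track` from [track_record()].
#' @param ... Unused.
#' @return A ggplot (three stacked panels: locked selection trace, envelope
#'   M, estimated phase).
#' @exportS3Method ggplot2::autoplot
autoplot.tremor_track <- function(object, ...) {
  d <- object$samples %>%
    tidyr::pivot_longer(c("phi_deg", "M", "fc_hz"), names_to = "panel") %>%
    mutate(panel = factor(.data$panel, c("fc_hz", "M", "phi_deg"),
                          c("locked fc [Hz]", "envelope M [g]", "phase [deg]")))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value, color = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, color = "locked axis") +
    ggplot2::theme_minimal()
}

#' Plot a state-amplitude profile
#'
#' Median change in tremor severity per stimulation state with the
#' Bonferroni-corrected resampling limits (dotted); significant states in
#' red.
#'
#' @param object A `state_profile` from [profile_significance()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.state_profile <- function(object, ...) {
  d <- as_tibble(object) %>% filter(!.data$untestable)
  ggplot2::ggplot(d, ggplot2::aes(.data$state, .data$median_change,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           linetype = "dotted", width = 0.4) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               na.value = "grey85") +
    ggplot2::labs(x = "stimulation state", y = "median change in tremor severity [%]",
                  fill = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot trigger phase alignment
#'
#' Estimated phase at each trigger against its target phase across the
#' random search, with the 30-degree tolerance band -- the offline check
#' that phase-locked stimulation landed where intended.
#'
#' @param result A `protocol_result` from [run_protocol()].
#' @param tolerance_deg Tolerance band half-width (default 30).
#' @return A ggplot.
#' @export
plot_phase_alignment <- function(result, tolerance_deg = 30) {
  check_that(inherits(result, "protocol_result"), "`result` must be a protocol_result")
  d <- result$events %>%
    filter(.data$kind == "trigger", !is.na(.data$target_phase_deg)) %>%
    mutate(event = dplyr::row_number(),
           dev = (.data$est_phase_deg - .data$target_phase_deg + 180) %% 360 - 180)
  ggplot2::ggplot(d, ggplot2::aes(.data$event)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$target_phase_deg - tolerance_deg,
                                      ymax = .data$target_phase_deg + tolerance_deg),
                         fill = "darkseagreen", alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$target_phase_deg), color = "firebrick",
                        size = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$target_phase_deg + .data$dev),
                        color = "steelblue", size = 0.6) +
    ggplot2::labs(x = "trigger event", y = "phase [deg]") +
    ggplot2::theme_minimal()
}
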