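#' Canonical TEP component windows
#'
#' Default latency windows (ms) for the classic DLPFC TEP components:
#' P30 (25–35), N45 (40–50), P60 (50–70), N100 (80–120), P180 (160–200).
#'
#' @return named list of ms pairs.
#' @export
component_windows <- function() {
  list(P30 = c(25, 35), N45 = c(40, 50), P60 = c(50, 70),
       N100 = c(80, 120), P180 = c(160, 200))
}

#' Trial-average TEP waveform
#'
#' Pointwise arithmetic mean over all retained trials ("stacked averaging").
#'
#' @param ep an [epoched_eeg()] with at least one trial.
#' @return object of class `tep_waveform`: `data` (`channels x time`, µV),
#'   `times_ms`, `n_trials`, `channel_names`.
#' @export
average_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoched_eeg"))
  if (dim(ep$data)[3] < 1) stop("no trials to average")
  m <- apply(ep$data, c(1, 2), mean)
  rownames(m) <- ep$channel_names
  structure(list(data = m, times_ms = ep$times_ms,
                 n_trials = dim(ep$data)[3],
                 channel_names = ep$channel_names),
            class = "tep_waveform")
}

#' @export
print.tep_waveform <- function(x, ...) {
  cat("<tep_waveform>", nrow(x$data), "ch x", length(x$times_ms),
      "samples, mean of", x$n_trials, "trials\n")
  invisible(x)
}

#' Mean amplitude of a waveform in a latency window
#'
#' Arithmetic mean of the trial-average waveform over all samples with
#' `window[1] <= t <= window[2]` (both endpoints inclusive).
#'
#' @param tep a [average_epochs()] waveform.
#' @param channel channel label (default `"F3"`, over the stimulated left
#'   DLPFC).
#' @param window ms pair inside the epoch.
#' @return mean amplitude, µV.
#' @export
component_amplitude <- function(tep, channel = "F3", window) {
  stopifnot(inherits(tep, "tep_waveform"), length(window) == 2)
  if (!channel %in% tep$channel_names)
    stop("unknown channel: ", channel)
  if (window[1] < min(tep$times_ms) || window[2] > max(tep$times_ms))
    stop("window [", window[1], ", ", window[2], "] ms outside the epoch")
  sel <- tep$times_ms >= window[1] & tep$times_ms <= window[2]
  mean(tep$data[channel, sel])
}

#' Extract all TEP component amplitudes at one electrode
#'
#' @param tep a [average_epochs()] waveform.
#' @param channel analysis electrode label.
#' @param windows named list of ms pairs, as [component_windows()].
#' @param magnitude if `TRUE`, also report the absolute amplitude (used for
#'   "greater N100" comparisons where N components are negative).
#' @return tibble with columns `component`, `window_start_ms`,
#'   `window_end_ms`, `amplitude_uv` (and `magnitude_uv` if requested).
#' @export
extract_components <- function(tep, channel = "F3",
                               windows = component_windows(),
                               magnitude = FALSE) {
  if (!length(windows))
    return(tibble::tibble(component = character(), window_start_ms = double(),
                          window_end_ms = double(), amplitude_uv = double()))
  amps <- vapply(windows, function(w) component_amplitude(tep, channel, w),
                 0)
  out <- tibble::tibble(
    component = names(windows),
    window_start_ms = vapply(windows, `[`, 0, 1),
    window_end_ms = vapply(windows, `[`, 0, 2),
    amplitude_uv = unname(amps))
  if (magnitude) out$magnitude_uv <- abs(out$amplitude_uv)
  out
}

#' Butterfly plot of a TEP waveform
#'
#' All channels overlaid, with the analysis electrode highlighted.
#'
#' @param object a `tep_waveform`.
#' @param channel electrode to highlight.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tep_waveform <- function(object, channel = "F3", ...) {
  df <- tibble::as_tibble(t(object$data))
  df$time_ms <- object$times_ms
  long <- tidyr::pivot_longer(df, -"time_ms", names_to = "channel",
                              values_to = "uv")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$uv,
                                     group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = long[long$channel == channel, ],
                       colour = "firebrick", linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = expression(paste("amplitude (", mu,
                                                        "V)")),
                  title = paste("TEP butterfly,", object$n_trials,
                                "trials;", channel, "highlighted")) +
    ggplot2::theme_minimal()
}
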