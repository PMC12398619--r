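#' Preprocessing configuration
#'
#' Defaults follow the artifact-suppression chain for single-pulse TMS-EEG:
#' pulse-window excision from -10 to 25 ms, downsampling to 1 kHz, epochs of
#' ±2 s around each pulse, exponential decay regression, 1–100 Hz band-pass
#' and 48–52 Hz band-stop zero-phase filtering, ±3 SD trial rejection,
#' neighbour-based bad-channel interpolation, average referencing, and
#' baseline correction over -550 to -50 ms.
#'
#' @param pulse_window_ms excised window around each pulse, ms pair.
#' @param target_srate analysis sampling rate after decimation, Hz.
#' @param epoch_window_ms epoch limits around each pulse, ms pair.
#' @param bandpass_hz band-pass edges, Hz pair.
#' @param notch_hz band-stop edges, Hz pair.
#' @param reject_sd trial-rejection threshold in SDs of the per-trial peak
#'   amplitude.
#' @param baseline_window_ms baseline window, ms pair, ending before 0.
#' @param decay_model `"exponential"` to fit-and-subtract post-pulse decays,
#'   `"off"` to skip.
#' @param decay_floor_uv channels with fitted decay amplitude below this
#'   floor are left untouched.
#' @param bad_channel_ratio bad-channel criterion: median per-trial RMS above
#'   `bad_channel_ratio` times (or below `1/bad_channel_ratio^?`, see
#'   details) the montage median RMS.
#' @param n_neighbors neighbours used for bad-channel interpolation.
#' @details A channel is flagged bad when its median per-trial RMS exceeds
#'   `bad_channel_ratio` (default 5) times the montage median RMS, or falls
#'   below 0.2 times it (dead channel).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(pulse_window_ms = c(-10, 25),
                              target_srate = 1000,
                              epoch_window_ms = c(-2000, 2000),
                              bandpass_hz = c(1, 100),
                              notch_hz = c(48, 52),
                              reject_sd = 3,
                              baseline_window_ms = c(-550, -50),
                              decay_model = c("exponential", "off"),
                              decay_floor_uv = 5,
                              bad_channel_ratio = 5,
                              n_neighbors = 4) {
  decay_model <- match.arg(decay_model)
  stopifnot(pulse_window_ms[1] < pulse_window_ms[2],
            epoch_window_ms[1] < epoch_window_ms[2],
            pulse_window_ms[1] >= epoch_window_ms[1],
            pulse_window_ms[2] <= epoch_window_ms[2],
            baseline_window_ms[1] < baseline_window_ms[2],
            baseline_window_ms[2] <= 0,
            baseline_window_ms[1] >= epoch_window_ms[1],
            bandpass_hz[1] < bandpass_hz[2],
            bandpass_hz[2] < target_srate / 2,
            reject_sd > 0, target_srate > 0)
  structure(list(pulse_window_ms = pulse_window_ms,
                 target_srate = target_srate,
                 epoch_window_ms = epoch_window_ms,
                 bandpass_hz = bandpass_hz, notch_hz = notch_hz,
                 reject_sd = reject_sd,
                 baseline_window_ms = baseline_window_ms,
                 decay_model = decay_model,
                 decay_floor_uv = decay_floor_uv,
                 bad_channel_ratio = bad_channel_ratio,
                 n_neighbors = n_neighbors),
            class = "preprocess_config")
}

#' Epoched EEG container
#'
#' @param data numeric array `channels x time x trials`, µV.
#' @param times_ms pulse-locked time axis, ms.
#' @param srate sampling rate, Hz.
#' @param channel_names channel labels.
#' @param bad_channels labels of interpolated channels.
#' @param n_rejected_trials number of trials removed by amplitude rejection.
#' @return object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, times_ms, srate, channel_names,
                        bad_channels = character(0),
                        n_rejected_trials = 0L) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(times_ms),
            dim(data)[1] == length(channel_names), srate > 0)
  structure(list(data = data, times_ms = times_ms, srate = srate,
                 channel_names = channel_names, bad_channels = bad_channels,
                 n_rejected_trials = as.integer(n_rejected_trials)),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoched_eeg>", d[1], "ch x", d[2], "samples x", d[3], "trials @",
      x$srate, "Hz;", x$n_rejected_trials, "trials rejected;",
      length(x$bad_channels), "channels interpolated\n")
  invisible(x)
}

#' Excise and interpolate the pulse-artifact window
#'
#' Replaces samples inside the configured window around each pulse marker
#' with a least-squares cubic polynomial fitted to flanking samples; all
#' other samples are untouched. A least-squares (rather than interpolating)
#' cubic reproduces any locally polynomial signal up to degree three exactly
#' while avoiding the large overshoots an interpolating spline produces when
#' the flanks are noisy.
#'
#' @param rec a [continuous_recording()].
#' @param cfg a [preprocess_config()].
#' @param n_flank flanking samples used on each side of the window.
#' @return a [continuous_recording()].
#' @export
excise_pulse_window <- function(rec, cfg = preprocess_config(),
                                n_flank = 8) {
  stopifnot(inherits(rec, "continuous_recording"))
  w <- round(cfg$pulse_window_ms / 1000 * rec$srate)
  data <- rec$data
  n <- ncol(data)
  for (m in rec$pulse_samples) {
    lo <- m + w[1]; hi <- m + w[2]
    if (lo - n_flank < 1 || hi + n_flank > n)
      stop("pulse marker at sample ", m,
           " too close to the recording edge for excision")
    xs <- c((lo - n_flank):(lo - 1), (hi + 1):(hi + n_flank))
    inside <- lo:hi
    xc <- (xs - m) / rec$srate * 1000        # centred, in ms
    X <- cbind(1, xc, xc^2, xc^3)
    Xi <- cbind(1, (inside - m) / rec$srate * 1000,
                ((inside - m) / rec$srate * 1000)^2,
                ((inside - m) / rec$srate * 1000)^3)
    # one QR for all channels: fit Y(xs) and predict on the window
    beta <- qr.solve(X, t(data[, xs, drop = FALSE]))
    data[, inside] <- t(Xi %*% beta)
  }
  continuous_recording(data, rec$srate, rec$channel_names, rec$pulse_samples)
}

# profiled exponential fit: minimise over tau the RSS of the linear model
# y ~ b + A exp(-t/tau), with the 2x2 normal equations solved in closed
# form; returns list(b, A, tau)
fit_decay <- function(t_ms, y, tau_range = c(5, 1500)) {
  n <- length(y)
  sy <- sum(y); syy <- sum(y * y)
  coefs <- function(tau) {
    b <- exp(-t_ms / tau)
    s1 <- sum(b); s2 <- sum(b * b); sby <- sum(b * y)
    det <- n * s2 - s1 * s1
    if (det < 1e-12) return(c(mean(y), 0))
    c((sy * s2 - s1 * sby) / det, (n * sby - s1 * sy) / det)
  }
  rss <- function(tau) {
    cf <- coefs(tau)
    b <- exp(-t_ms / tau)
    syy - 2 * (cf[1] * sy + cf[2] * sum(b * y)) +
      sum((cf[1] + cf[2] * b)^2)
  }
  opt <- stats::optimize(rss, tau_range)
  cf <- coefs(opt$minimum)
  list(b = cf[1], A = cf[2], tau = opt$minimum)
}

#' Regress out post-pulse exponential decay artifacts
#'
#' Per channel and pulse, fits `b + A exp(-t/tau)` over 25–500 ms post-pulse
#' by profiled least squares (linear in `b`, `A`; golden-section search over
#' `tau`) and subtracts the fitted `A exp(-t/tau)` from pulse onset until the
#' decay has vanished or the next pulse begins. Channels whose fitted `|A|`
#' falls below `cfg$decay_floor_uv` are left untouched. A failed fit skips
#' the channel with a warning, never an error.
#'
#' @param rec a [continuous_recording()].
#' @param cfg a [preprocess_config()] with `decay_model = "exponential"`.
#' @param fit_window_ms post-pulse window used for the fit.
#' @return a [continuous_recording()].
#' @export
remove_decay <- function(rec, cfg = preprocess_config(),
                         fit_window_ms = c(25, 500)) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (cfg$decay_model != "exponential") return(rec)
  data <- rec$data
  n <- ncol(data)
  fs <- rec$srate
  i0 <- round(fit_window_ms[1] / 1000 * fs)
  i1 <- round(fit_window_ms[2] / 1000 * fs)
  markers <- rec$pulse_samples
  for (k in seq_along(markers)) {
    m <- markers[k]
    hi <- min(m + i1, n)
    if (hi - (m + i0) < 10) next
    t_fit <- ((m + i0):hi - m) / fs * 1000
    sub_end <- if (k < length(markers)) markers[k + 1] - 1L else n
    for (ch in seq_len(nrow(data))) {
      fit <- tryCatch(fit_decay(t_fit, data[ch, (m + i0):hi]),
                      error = function(e) {
                        warning("decay fit failed on channel ",
                                rec$channel_names[ch], " pulse ", k,
                                ": ", conditionMessage(e))
                        NULL
                      })
      if (is.null(fit) || abs(fit$A) < cfg$decay_floor_uv) next
      # subtract until the fitted decay is negligible
      len <- min(sub_end - m + 1L, ceiling(14 * fit$tau / 1000 * fs))
      t_sub <- (0:(len - 1)) / fs * 1000
      data[ch, m:(m + len - 1)] <- data[ch, m:(m + len - 1)] -
        fit$A * exp(-t_sub / fit$tau)
    }
  }
  continuous_recording(data, fs, rec$channel_names, markers)
}

# Zero-phase Butterworth filtering of a channels x samples matrix. The
# squared magnitude response of each filter (identical to a forward-backward
# application) is applied in the frequency domain across all channels at
# once; the signal is reflection-padded so recording edges see no wrap.
# `filts` is a single filter or a list applied as a cascade in one pass.
filtfilt_rows <- function(data, filts, pad = min(ncol(data) - 1L, 2048L)) {
  if (!is.null(filts$b)) filts <- list(filts)
  n <- ncol(data)
  left <- data[, pad:1, drop = FALSE]
  right <- data[, n:(n - pad + 1), drop = FALSE]
  x <- cbind(left, data, right)
  np <- ncol(x)
  n2 <- stats::nextn(np)
  if (n2 > np) x <- cbind(x, matrix(0, nrow(data), n2 - np))
  w <- 2 * pi * (0:(n2 - 1)) / n2
  H2 <- rep(1, n2)
  for (filt in filts) {
    ew <- exp(-1i * outer(w, 0:(length(filt$b) - 1)))
    H <- as.vector(ew %*% filt$b) /
      as.vector(ew[, seq_along(filt$a)] %*% filt$a)
    H2 <- H2 * Mod(H)^2
  }
  sp <- stats::mvfft(t(x)) * H2
  y <- Re(stats::mvfft(sp, inverse = TRUE)) / n2
  t(y)[, pad + seq_len(n), drop = FALSE]
}

#' Decimate, filter and epoch a continuous recording
#'
#' Anti-aliased decimation to `cfg$target_srate` (integer factor), zero-phase
#' Butterworth band-pass and band-stop filtering on the continuous signal,
#' then one epoch per pulse marker over `cfg$epoch_window_ms`. Epochs that
#' would exceed the recording bounds are dropped with a warning.
#'
#' @param rec a [continuous_recording()].
#' @param cfg a [preprocess_config()].
#' @return an [epoched_eeg()].
#' @export
filter_downsample_epoch <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "continuous_recording"))
  fs <- rec$srate
  if (cfg$target_srate > fs)
    stop("target_srate exceeds the recording sampling rate")
  k <- fs / cfg$target_srate
  if (abs(k - round(k)) > 1e-9)
    stop("decimation factor must be an integer (got ", k, ")")
  k <- as.integer(round(k))
  data <- rec$data
  markers <- rec$pulse_samples
  if (k > 1L) {
    aa <- signal::butter(8, 0.8 / k, type = "low")
    data <- filtfilt_rows(data, aa)
    idx <- seq(1L, ncol(data), by = k)
    data <- data[, idx, drop = FALSE]
    markers <- as.integer(round((markers - 1L) / k) + 1L)
  }
  fs <- cfg$target_srate
  nyq <- fs / 2
  filts <- list(signal::butter(4, cfg$bandpass_hz / nyq, type = "pass"))
  if (!is.null(cfg$notch_hz))
    filts <- c(filts, list(signal::butter(2, cfg$notch_hz / nyq,
                                          type = "stop")))
  data <- filtfilt_rows(data, filts)
  w <- round(cfg$epoch_window_ms / 1000 * fs)
  n_t <- w[2] - w[1] + 1L
  ok <- markers + w[1] >= 1 & markers + w[2] <= ncol(data)
  if (!all(ok))
    warning(sum(!ok), " trial(s) dropped: epoch window exceeds recording")
  markers <- markers[ok]
  if (!length(markers)) stop("no epochs remain")
  ep <- array(0, c(nrow(data), n_t, length(markers)))
  for (i in seq_along(markers))
    ep[, , i] <- data[, (markers[i] + w[1]):(markers[i] + w[2])]
  times_ms <- (w[1]:w[2]) / fs * 1000
  epoched_eeg(ep, times_ms, fs, rec$channel_names)
}

#' Trial rejection, channel interpolation, referencing and baseline
#'
#' In order: (1) removes trials whose peak absolute amplitude (across
#' channels and samples, excluding the excised pulse window) exceeds the
#' mean + `reject_sd` SD of per-trial peaks; (2) flags bad channels by a
#' robust RMS criterion and replaces them with the unweighted mean of their
#' `n_neighbors` nearest good channels in 3-D montage distance; (3) applies
#' the average reference; (4) subtracts the per-channel, per-trial mean over
#' the baseline window.
#'
#' @param ep an [epoched_eeg()].
#' @param cfg a [preprocess_config()].
#' @param montage a [sensor_montage()] matching the channels.
#' @return an [epoched_eeg()], average-referenced and baseline-corrected.
#' @export
reject_and_reference <- function(ep, cfg = preprocess_config(), montage) {
  stopifnot(inherits(ep, "epoched_eeg"), inherits(montage, "sensor_montage"))
  d <- dim(ep$data)
  if (d[3] < 2) stop("need at least 2 trials")
  keep_t <- ep$times_ms < cfg$pulse_window_ms[1] |
    ep$times_ms > cfg$pulse_window_ms[2]

  # (1) trial rejection on peak absolute amplitude
  peaks <- apply(abs(ep$data[, keep_t, , drop = FALSE]), 3, max)
  thr <- mean(peaks) + cfg$reject_sd * stats::sd(peaks)
  keep <- peaks <= thr
  if (!any(keep)) stop("all trials rejected")
  n_rej <- sum(!keep)
  data <- ep$data[, , keep, drop = FALSE]

  # (2) bad channels by median per-trial RMS against the montage median
  rms <- apply(data[, keep_t, , drop = FALSE], c(1, 3),
               function(v) sqrt(mean(v^2)))
  ch_rms <- apply(rms, 1, stats::median)
  med <- stats::median(ch_rms)
  dead_thr <- min(0.2, 1 / cfg$bad_channel_ratio)
  bad <- ch_rms > cfg$bad_channel_ratio * med | ch_rms < dead_thr * med
  if (all(bad)) stop("all channels flagged bad")
  if (sum(!bad) < 2) stop("fewer than 2 good channels remain")
  bad_names <- ep$channel_names[bad]
  if (any(bad)) {
    pos <- montage$positions[ep$channel_names, , drop = FALSE]
    good_idx <- which(!bad)
    for (b in which(bad)) {
      dist <- sqrt(rowSums(sweep(pos[good_idx, , drop = FALSE], 2,
                                 pos[b, ])^2))
      nb <- good_idx[order(dist)[seq_len(min(cfg$n_neighbors,
                                             length(good_idx)))]]
      data[b, , ] <- apply(data[nb, , , drop = FALSE], c(2, 3), mean)
    }
  }

  # (3) average reference
  data <- sweep(data, c(2, 3), apply(data, c(2, 3), mean))

  # (4) baseline correction
  bl <- ep$times_ms >= cfg$baseline_window_ms[1] &
    ep$times_ms <= cfg$baseline_window_ms[2]
  base <- apply(data[, bl, , drop = FALSE], c(1, 3), mean)
  data <- sweep(data, c(1, 3), base)
  epoched_eeg(data, ep$times_ms, ep$srate, ep$channel_names,
              bad_channels = bad_names,
              n_rejected_trials = ep$n_rejected_trials + n_rej)
}

#' Run the full preprocessing chain
#'
#' Pulse-window excision, decay regression (if configured), decimation +
#' filtering + epoching, then trial rejection, channel interpolation,
#' average referencing and baseline correction, in that order.
#'
#' @param rec a [continuous_recording()] or path to a `.vhdr` file.
#' @param cfg a [preprocess_config()].
#' @param montage a [sensor_montage()].
#' @return an [epoched_eeg()].
#' @export
preprocess <- function(rec, cfg = preprocess_config(), montage) {
  if (is.character(rec)) rec <- read_brainvision(rec)
  rec <- excise_pulse_window(rec, cfg)
  rec <- remove_decay(rec, cfg)
  ep <- filter_downsample_epoch(rec, cfg)
  reject_and_reference(ep, cfg, montage)
}
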