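#' Continuous multichannel EEG recording
#'
#' @param data numeric `channels x samples` matrix, microvolts.
#' @param srate sampling rate, Hz.
#' @param channel_names channel labels, one per row of `data`.
#' @param pulse_samples strictly increasing sample indices of TMS pulses.
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, srate, channel_names, pulse_samples) {
  data <- as.matrix(data)
  pulse_samples <- as.integer(pulse_samples)
  stopifnot(srate > 0, nrow(data) == length(channel_names))
  if (nrow(data) == 0) stop("recording must have at least one channel")
  if (length(pulse_samples) &&
      (any(diff(pulse_samples) <= 0) || min(pulse_samples) < 1 ||
       max(pulse_samples) > ncol(data)))
    stop("pulse markers must be strictly increasing and within the recording")
  rownames(data) <- channel_names
  structure(list(data = data, srate = srate, channel_names = channel_names,
                 pulse_samples = pulse_samples),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording>", nrow(x$data), "ch x", ncol(x$data),
      "samples @", x$srate, "Hz,", length(x$pulse_samples), "pulses\n")
  invisible(x)
}

#' Source circuit specification for the synthetic generator
#'
#' A circuit is a cortical dipole that responds to every TMS pulse with a
#' smooth burst of activity inside a fixed post-pulse latency window. The
#' per-group multiplicative `gain` encodes generative group differences in
#' effective connectivity: elevating a downstream circuit's gain in one group
#' produces larger stimulus-locked source activity in exactly that region.
#'
#' @param source_position MNI mm triplet, inside the brain shell.
#' @param orientation dipole orientation (3-vector, normalised internally).
#' @param latency_window post-pulse activity window, ms pair.
#' @param amplitude peak dipole moment (nA·m equivalent), `>= 0`.
#' @param gain named per-group multiplicative gains (`SI`, `NSI`, `HC`), all
#'   `>= 0`; groups absent from the map default to 1.
#' @param label optional circuit label.
#' @return object of class `circuit_spec`.
#' @export
circuit_spec <- function(source_position, orientation = NULL,
                         latency_window = c(80, 120), amplitude = 60,
                         gain = c(SI = 1, NSI = 1, HC = 1), label = "") {
  stopifnot(length(source_position) == 3, length(latency_window) == 2,
            latency_window[1] < latency_window[2], amplitude >= 0,
            all(gain >= 0))
  if (!is.null(orientation)) {
    nrm <- sqrt(sum(orientation^2))
    if (nrm == 0) stop("orientation must be a nonzero vector")
    orientation <- orientation / nrm
  }
  structure(list(source_position = as.numeric(source_position),
                 orientation = orientation,
                 latency_window = as.numeric(latency_window),
                 amplitude = amplitude, gain = gain, label = label),
            class = "circuit_spec")
}

#' Noise and artifact specification for the synthetic generator
#'
#' Models the contamination classes the preprocessing chain targets: 1/f
#' background activity, 50 Hz line noise, a slow exponential decay following
#' each pulse, and the sharp clipped pulse artifact itself. Optional
#' broadband bursts (ocular/muscle-like) are off by default.
#'
#' @param pink_noise_sd per-channel 1/f noise SD, µV.
#' @param line_noise_amp 50 Hz line component amplitude, µV.
#' @param decay_amp post-pulse exponential decay amplitude, µV.
#' @param decay_tau decay time constant, ms.
#' @param pulse_artifact_amp pulse artifact amplitude (clipped), µV.
#' @param pulse_artifact_width pulse artifact duration, ms.
#' @param burst_amp amplitude of optional broadband artifact bursts, µV
#'   (0 disables them).
#' @param burst_rate_hz expected burst rate when enabled.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(pink_noise_sd = 3, line_noise_amp = 1.5,
                       decay_amp = 25, decay_tau = 120,
                       pulse_artifact_amp = 800, pulse_artifact_width = 10,
                       burst_amp = 0, burst_rate_hz = 0.2) {
  vals <- c(pink_noise_sd, line_noise_amp, decay_amp, decay_tau,
            pulse_artifact_amp, pulse_artifact_width, burst_amp)
  if (any(vals < 0)) stop("noise parameters must be nonnegative")
  structure(list(pink_noise_sd = pink_noise_sd,
                 line_noise_amp = line_noise_amp,
                 decay_amp = decay_amp, decay_tau = decay_tau,
                 pulse_artifact_amp = pulse_artifact_amp,
                 pulse_artifact_width = pulse_artifact_width,
                 burst_amp = burst_amp, burst_rate_hz = burst_rate_hz),
            class = "noise_spec")
}

#' Cohort specification
#'
#' Sample sizes, stimulation protocol and per-group covariate distributions.
#' Defaults reproduce the study conditions: 100 single pulses at 5 s
#' inter-stimulus interval with ±0.1–0.2 s jitter, and group covariate
#' means/SDs matching the clinical cohort (SI n = 74, NSI n = 92,
#' HC n = 61; e.g. age 24.7 (11.0) in SI vs 34.3 (16.4) in NSI).
#'
#' @param n_per_group named counts for groups `SI`, `NSI`, `HC` (each >= 1).
#' @param pulses_per_subject single pulses per subject.
#' @param isi_s mean inter-stimulus interval, seconds.
#' @param isi_jitter_s absolute jitter bounds, seconds (`c(lo, hi)`); each
#'   pulse is shifted by a uniform draw from ±\[lo, hi\].
#' @param covariates per-group list with `age`, `hamd`, `duration_months`
#'   entries of `c(mean, sd)`, plus `suicide_history_prob` and a named
#'   `antidepressant` probability vector.
#' @param seed master seed; per-subject seeds are derived from it and the
#'   subject id, independent of insertion order.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(SI = 74, NSI = 92, HC = 61),
                        pulses_per_subject = 100,
                        isi_s = 5, isi_jitter_s = c(0.1, 0.2),
                        covariates = default_covariates(),
                        seed = 1L) {
  if (!length(n_per_group)) stop("empty group map")
  if (any(n_per_group < 1)) stop("group counts must be >= 1")
  stopifnot(pulses_per_subject >= 1, isi_s > 0,
            length(isi_jitter_s) == 2, all(isi_jitter_s >= 0),
            isi_jitter_s[1] <= isi_jitter_s[2])
  structure(list(n_per_group = n_per_group,
                 pulses_per_subject = as.integer(pulses_per_subject),
                 isi_s = isi_s, isi_jitter_s = isi_jitter_s,
                 covariates = covariates, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-group covariate distributions
#'
#' Group means and SDs of age, HAMD-24 score and illness duration, the
#' probability of a history of suicide attempts, and the antidepressant-type
#' distribution, matching the clinical cohort's demographic table.
#'
#' @return named list with one entry per group.
#' @export
default_covariates <- function() {
  ad <- c(Escitalopram = 60, Fluoxetine = 7, Sertraline = 16, Venlafaxine = 9)
  list(
    SI = list(age = c(24.7, 11.0), hamd = c(25.6, 5.7),
              duration_months = c(48.5, 66.8),
              suicide_history_prob = 34 / 74,
              antidepressant = c(Escitalopram = 48, Fluoxetine = 7,
                                 Sertraline = 12, Venlafaxine = 7)),
    NSI = list(age = c(34.3, 16.4), hamd = c(24.7, 4.6),
               duration_months = c(54.8, 64.0),
               suicide_history_prob = 13 / 92,
               antidepressant = ad),
    HC = list(age = c(30.1, 8.6), hamd = c(4.8, 2.1),
              duration_months = c(0, 0),
              suicide_history_prob = 0,
              antidepressant = c(none = 1)))
}

#' Default source circuits of the synthetic cohort
#'
#' One early local response at the stimulated left-DLPFC target, and
#' N100-window downstream circuits at the network nodes used in the SCS
#' analysis. The SI group's coupling gain is elevated (default 1.5x) for the
#' mPFC and ACC circuits only, encoding increased DLPFC→mPFC and DLPFC→ACC
#' effective connectivity; angular, PPC and the other nodes have identical
#' gains across groups and act as negative controls.
#'
#' @param gain_si SI-group gain for the mPFC and ACC circuits.
#' @param stim_target stimulated-site MNI coordinates.
#' @param amplitude downstream circuit peak dipole moment (nA·m equivalent).
#' @return list of [circuit_spec()] objects.
#' @export
default_circuits <- function(gain_si = 1.5,
                             stim_target = c(-44, 40, 29),
                             amplitude = 60) {
  rois <- roi_centroids()
  pos <- function(r) {
    sub <- rois[rois$roi == r, c("x_mm", "y_mm", "z_mm")]
    as.numeric(colMeans(sub))
  }
  up <- c(SI = gain_si, NSI = 1, HC = 1)
  flat <- c(SI = 1, NSI = 1, HC = 1)
  # radially outward dipoles give positive potentials over the source;
  # alternating the local response's polarity across windows reproduces the
  # canonical P30-N45-P60 sequence, and inward downstream dipoles give the
  # frontal N100 negativity
  out_ori <- NULL                        # default: radial outward
  inward <- function(p) -(p - head_model()$center) /
    sqrt(sum((p - head_model()$center)^2))
  tgt <- stim_target
  list(
    circuit_spec(tgt, latency_window = c(25, 35),
                 amplitude = 1.2 * amplitude, gain = flat,
                 label = "target_P30"),
    circuit_spec(tgt, orientation = inward(tgt), latency_window = c(40, 50),
                 amplitude = 0.8 * amplitude, gain = flat,
                 label = "target_N45"),
    circuit_spec(tgt, latency_window = c(50, 70),
                 amplitude = 0.8 * amplitude, gain = flat,
                 label = "target_P60"),
    circuit_spec(tgt, latency_window = c(160, 200),
                 amplitude = 0.6 * amplitude, gain = flat,
                 label = "target_P180"),
    circuit_spec(pos("mPFC"), orientation = inward(pos("mPFC")),
                 latency_window = c(80, 120),
                 amplitude = amplitude, gain = up, label = "mPFC"),
    circuit_spec(pos("ACC"), orientation = inward(pos("ACC")),
                 latency_window = c(80, 120),
                 amplitude = amplitude, gain = up, label = "ACC"),
    circuit_spec(pos("PCC"), orientation = inward(pos("PCC")),
                 latency_window = c(80, 120),
                 amplitude = 0.8 * amplitude, gain = flat, label = "PCC"),
    circuit_spec(pos("angular"), orientation = inward(pos("angular")),
                 latency_window = c(80, 120),
                 amplitude = 0.8 * amplitude, gain = flat, label = "angular"),
    circuit_spec(pos("PPC"), orientation = inward(pos("PPC")),
                 latency_window = c(80, 120),
                 amplitude = 0.8 * amplitude, gain = flat, label = "PPC"),
    circuit_spec(pos("insula"), orientation = inward(pos("insula")),
                 latency_window = c(80, 120),
                 amplitude = 0.8 * amplitude, gain = flat, label = "insula"))
}

# deterministic, insertion-order independent per-subject seed; the hash is
# carried in doubles (31 * 2^31 < 2^53, exact) and reduced mod a prime
subject_seed <- function(master_seed, subject_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (b in utf8ToInt(subject_id)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# half-cosine (Hann) burst over the latency window, sampled at times t_ms
burst_waveform <- function(t_ms, window) {
  w <- numeric(length(t_ms))
  inside <- t_ms >= window[1] & t_ms <= window[2]
  ph <- (t_ms[inside] - window[1]) / (window[2] - window[1])
  w[inside] <- sin(pi * ph)^2
  w
}

# 1/f-shaped Gaussian noise, one channel, SD-normalised; the FFT length is
# padded to a highly composite size to keep the transform O(n log n)
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  n2 <- stats::nextn(n)
  white <- stats::rnorm(n2)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n2 - 1))
  f <- pmin(f, n2 - f + 1)                # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE))[seq_len(n)] / n2
  x * sd / stats::sd(x)
}

#' Simulate one subject's continuous TMS-EEG recording
#'
#' Forward-models a pulse train: each pulse triggers every circuit's burst,
#' scaled by the subject's group gain, projected to the sensors through the
#' analytic spherical forward solution at the circuit's exact position; the
#' configured noise and artifact components are added on top. The function is
#' a pure function of its arguments — identical seeds give bit-identical
#' recordings.
#'
#' @param circuits list of [circuit_spec()].
#' @param noise a [noise_spec()].
#' @param montage a [sensor_montage()].
#' @param head a [head_model()] used for the generative forward solution
#'   (pass a perturbed model to avoid the inverse crime in recovery tests).
#' @param cohort a [cohort_spec()] (stimulation protocol).
#' @param subject one-row data frame / list with at least `group`.
#' @param seed integer seed.
#' @param srate simulation sampling rate, Hz.
#' @param pad_s padding before the first and after the last pulse, seconds.
#' @return a [continuous_recording()].
#' @export
simulate_subject <- function(circuits, noise, montage, head, cohort, subject,
                             seed, srate = 1000, pad_s = 2.5) {
  stopifnot(inherits(noise, "noise_spec"), inherits(cohort, "cohort_spec"),
            inherits(montage, "sensor_montage"), inherits(head, "head_model"))
  for (ci in circuits) {
    if (sqrt(sum((ci$source_position - head$center)^2)) >=
        head$shell_radii[1])
      stop("circuit source position [",
           paste(ci$source_position, collapse = ", "),
           "] lies outside the brain shell")
  }
  group <- as.character(subject$group)
  nch <- length(montage$channel_names)
  np <- cohort$pulses_per_subject
  local_rng(seed, {
    jit <- stats::runif(np, cohort$isi_jitter_s[1], cohort$isi_jitter_s[2]) *
      sample(c(-1, 1), np, replace = TRUE)
    pulse_t <- pad_s + (seq_len(np) - 1) * cohort$isi_s + jit
    n_samp <- ceiling((max(pulse_t) + pad_s) * srate)
    pulse_samples <- round(pulse_t * srate) + 1L
    data <- matrix(0, nch, n_samp)

    # evoked activity: per circuit, one sensor topography and one waveform
    for (ci in circuits) {
      g <- if (group %in% names(ci$gain)) ci$gain[[group]] else 1
      amp <- ci$amplitude * g
      if (amp == 0) next
      ori <- ci$orientation
      if (is.null(ori)) {                  # default: radial
        v <- ci$source_position - head$center
        ori <- v / sqrt(sum(v^2))
      }
      topo <- dipole_topography(head, montage, ci$source_position, ori * amp)
      w_len <- ceiling((ci$latency_window[2] + 5) * srate / 1000)
      t_ms <- (0:(w_len - 1)) / srate * 1000
      wf <- burst_waveform(t_ms, ci$latency_window)
      seg <- topo %o% wf                   # nch x w_len
      for (p in pulse_samples) {
        idx <- p:(p + w_len - 1)
        keep <- idx <= n_samp
        data[, idx[keep]] <- data[, idx[keep]] + seg[, keep, drop = FALSE]
      }
    }

    # background and artifacts
    if (noise$pink_noise_sd > 0)
      for (ch in seq_len(nch))
        data[ch, ] <- data[ch, ] + pink_noise(n_samp, noise$pink_noise_sd)
    if (noise$line_noise_amp > 0) {
      tt <- (seq_len(n_samp) - 1) / srate
      line <- sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      gains <- stats::runif(nch, 0.5, 1.5) * noise$line_noise_amp
      data <- data + gains %o% line
    }
    if (noise$decay_amp > 0) {
      d_len <- min(ceiling(6 * noise$decay_tau * srate / 1000), n_samp)
      d_t <- (0:(d_len - 1)) / srate * 1000
      d_shape <- exp(-d_t / noise$decay_tau)
      for (p in pulse_samples) {
        sgn <- sample(c(-1, 1), nch, replace = TRUE)
        amp_ch <- stats::runif(nch, 0.5, 1) * noise$decay_amp * sgn
        idx <- p:(p + d_len - 1)
        keep <- idx <= n_samp
        data[, idx[keep]] <- data[, idx[keep]] +
          amp_ch %o% d_shape[keep]
      }
    }
    if (noise$pulse_artifact_amp > 0) {
      a_pre <- ceiling(2 * srate / 1000)   # starts 2 ms before the pulse
      a_len <- ceiling(noise$pulse_artifact_width * srate / 1000)
      a_t <- (0:(a_len - 1)) / srate * 1000
      shape <- sin(2 * pi * a_t / noise$pulse_artifact_width) * 3
      shape <- pmin(pmax(shape, -1), 1)    # clipped biphasic spike
      for (p in pulse_samples) {
        idx <- (p - a_pre):(p - a_pre + a_len - 1)
        keep <- idx >= 1 & idx <= n_samp
        sc <- stats::runif(nch, 0.8, 1.2) * noise$pulse_artifact_amp
        data[, idx[keep]] <- data[, idx[keep]] +
          sc %o% shape[keep]
      }
    }
    if (noise$burst_amp > 0) {
      nb <- stats::rpois(1, noise$burst_rate_hz * n_samp / srate)
      b_len <- ceiling(0.2 * srate)
      for (i in seq_len(nb)) {
        st <- sample.int(n_samp - b_len, 1)
        ch <- sample.int(nch, 1)
        data[ch, st:(st + b_len - 1)] <- data[ch, st:(st + b_len - 1)] +
          stats::rnorm(b_len, 0, noise$burst_amp)
      }
    }
    continuous_recording(data, srate, montage$channel_names, pulse_samples)
  })
}

#' Draw subject covariates for a cohort
#'
#' Samples per-group covariates (age, HAMD, illness duration, suicide
#' history, antidepressant type) from the distributions in the cohort spec.
#' Gaussian covariates are truncated at zero; HAMD is clamped to the 0–76
#' scale range.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional override of `spec$seed`.
#' @return tibble with one row per subject (`subject_id`, `group`, `age`,
#'   `hamd`, `duration_months`, `suicide_history`, `antidepressant`).
#' @export
simulate_covariates <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  for (g in names(spec$n_per_group)) {
    n <- spec$n_per_group[[g]]
    cv <- spec$covariates[[g]]
    ids <- sprintf("%s_%03d", g, seq_len(n))
    draw <- function(id, what) {
      m <- cv[[what]][1]; s <- cv[[what]][2]
      local_rng(subject_seed(seed, paste0(id, ":", what)),
                stats::rnorm(1, m, s))
    }
    for (i in seq_len(n)) {
      id <- ids[i]
      age <- max(0, draw(id, "age"))
      hamd <- min(76, max(0, draw(id, "hamd")))
      dur <- max(0, draw(id, "duration_months"))
      hist <- local_rng(subject_seed(seed, paste0(id, ":hist")),
                        stats::runif(1)) < cv$suicide_history_prob
      ad <- local_rng(subject_seed(seed, paste0(id, ":ad")), {
        p <- cv$antidepressant / sum(cv$antidepressant)
        sample(names(p), 1, prob = p)
      })
      rows[[id]] <- tibble::tibble(
        subject_id = id, group = g, age = age, hamd = hamd,
        duration_months = dur, suicide_history = hist, antidepressant = ad)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a full cohort of recordings and covariates
#'
#' @inheritParams simulate_subject
#' @param spec a [cohort_spec()].
#' @param srate simulation sampling rate, Hz.
#' @return list with `recordings` (named list of
#'   [continuous_recording()]s) and `subjects` (covariate tibble).
#' @export
simulate_cohort <- function(spec, circuits, noise, montage, head,
                            srate = 1000) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- simulate_covariates(spec)
  recs <- vector("list", nrow(subjects))
  names(recs) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    recs[[i]] <- simulate_subject(
      circuits, noise, montage, head, spec, subjects[i, ],
      seed = subject_seed(spec$seed, subjects$subject_id[i]), srate = srate)
  }
  list(recordings = recs, subjects = subjects)
}

#' Simulate a null cohort (no post-stimulus sources)
#'
#' All circuit amplitudes are forced to zero, so pre- and post-stimulus
#' signal distributions are identical by construction. Used to estimate the
#' family-wise false-positive rate of the permutation masking procedure.
#'
#' @inheritParams simulate_cohort
#' @return as [simulate_cohort()].
#' @export
null_cohort <- function(spec, noise, montage, head, srate = 1000) {
  simulate_cohort(spec, list(), noise, montage, head, srate = srate)
}

# package-internal loader for the bundled ROI centroid table
roi_centroids <- function() {
  path <- system.file("extdata", "aal_roi_centroids.csv",
                      package = "tepscatter")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
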