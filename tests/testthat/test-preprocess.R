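make_rec <- function(data, srate = 1000, markers) {
  continuous_recording(data, srate,
                       paste0("ch", seq_len(nrow(data))), markers)
}

test_that("pulse-window excision restores polynomial signals exactly", {
  cfg <- preprocess_config()
  n <- 5000

  # zeros stay zeros
  z <- make_rec(matrix(0, 2, n), markers = 2500L)
  expect_identical(excise_pulse_window(z, cfg)$data, z$data)

  # a linear ramp with a spike inside -10..25 ms is restored exactly
  ramp <- matrix(rep(seq(0, 100, length.out = n), each = 2), 2)
  spiked <- ramp
  spiked[, 2492:2524] <- 5000             # inside the excision window
  out <- excise_pulse_window(make_rec(spiked, markers = 2500L), cfg)
  expect_equal(out$data, ramp, tolerance = 1e-9, ignore_attr = TRUE)

  # a spike outside the window is untouched
  spiked2 <- ramp
  spiked2[1, 2540] <- 5000                # +40 ms
  out2 <- excise_pulse_window(make_rec(spiked2, markers = 2500L), cfg)
  expect_equal(unname(out2$data[1, 2540]), 5000)

  # samples away from any window are bit-identical
  noise <- matrix(rnorm(2 * n), 2)
  out3 <- excise_pulse_window(make_rec(noise, markers = 2500L), cfg)
  untouched <- setdiff(seq_len(n), 2490:2525)
  expect_equal(out3$data[, untouched], noise[, untouched],
               ignore_attr = TRUE)

  expect_error(excise_pulse_window(make_rec(noise, markers = 5L), cfg),
               "edge")
})

test_that("decay regression removes known exponentials", {
  cfg <- preprocess_config()
  tt <- 0:3000

  # pure exponential: residual under 1% of the initial amplitude
  y <- 100 * exp(-tt / 150)
  out <- remove_decay(make_rec(matrix(y, 1), markers = 1L), cfg)
  expect_lt(max(abs(out$data[1, 26:3001])), 1)

  # white noise below the amplitude floor is untouched
  set.seed(8)
  w <- matrix(rnorm(3001, sd = 1), 1)
  cfg_hi <- preprocess_config(decay_floor_uv = 50)
  out2 <- remove_decay(make_rec(w, markers = 1L), cfg_hi)
  expect_equal(out2$data, w, ignore_attr = TRUE)

  # two pulses with different decays are fitted independently
  n <- 8000
  y2 <- numeric(n)
  y2[1000:3500] <- 80 * exp(-(0:2500) / 100)
  y2[4000:7990] <- 150 * exp(-(0:3990) / 300)
  out3 <- remove_decay(make_rec(matrix(y2, 1), markers = c(1000L, 4000L)),
                       cfg)
  expect_lt(max(abs(out3$data[1, 1026:3500])), 1.5)
  expect_lt(max(abs(out3$data[1, 4026:7990])), 2.5)

  # decay_model = "off" is a no-op
  cfg_off <- preprocess_config(decay_model = "off")
  out4 <- remove_decay(make_rec(matrix(y, 1), markers = 1L), cfg_off)
  expect_identical(out4$data[1, ], y)
})

test_that("filtering attenuates the notch band and passes the passband", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- make_rec(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t)), fs,
                  markers = 10000L)
  ep <- filter_downsample_epoch(rec, preprocess_config())
  mid <- abs(ep$times_ms) < 1500
  a50 <- max(abs(ep$data[1, mid, 1]))
  a10 <- max(abs(ep$data[2, mid, 1]))
  expect_lt(20 * log10(a50), -40)         # >= 40 dB down at 50 Hz
  expect_gt(20 * log10(a10), -1)          # < 1 dB loss at 10 Hz
})

test_that("decimation is anti-aliased and epochs are bookkept", {
  fs <- 4000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(3)
  markers <- as.integer(seq(10000, length(t) - 10000, length.out = 10))
  sig <- rbind(sin(2 * pi * 10 * t), rnorm(length(t)))
  rec <- make_rec(sig, fs, markers)
  ep <- filter_downsample_epoch(rec, preprocess_config())
  expect_equal(ep$srate, 1000)
  expect_equal(dim(ep$data)[3], 10)
  expect_equal(range(ep$times_ms), c(-2000, 2000))
  # a 10 Hz tone survives decimation intact
  mid <- abs(ep$times_ms) < 1500
  expect_gt(max(abs(ep$data[1, mid, 1])), 0.89)

  # epochs that do not fit are dropped with a warning
  rec2 <- make_rec(sig[, 1:20000], fs, c(3000L, 10000L))
  expect_warning(ep2 <- filter_downsample_epoch(rec2, preprocess_config()),
                 "dropped")
  expect_equal(dim(ep2$data)[3], 1)

  expect_error(filter_downsample_epoch(
    make_rec(sig, 1500, markers), preprocess_config()), "integer")
})

test_that("outlier trials are rejected and identities hold after referencing", {
  cfg <- preprocess_config(epoch_window_ms = c(-700, 700))
  set.seed(21)
  fs <- 500
  n <- fs * 40
  nch <- 16
  markers <- as.integer(seq(2 * fs, n - 2 * fs, by = 2.5 * fs))
  data <- matrix(rnorm(nch * n), nch)
  # trial 3 carries a 50x amplitude artifact
  data[, (markers[3] - 100):(markers[3] + 100)] <-
    data[, (markers[3] - 100):(markers[3] + 100)] * 50
  rec <- continuous_recording(data, fs, fix_montage16$channel_names, markers)
  ep0 <- filter_downsample_epoch(rec, preprocess_config(
    target_srate = 500, epoch_window_ms = c(-700, 700)))
  n_tr <- dim(ep0$data)[3]
  ep <- reject_and_reference(ep0, cfg, fix_montage16)
  expect_equal(ep$n_rejected_trials, 1L)
  expect_equal(dim(ep$data)[3], n_tr - 1)

  # average-reference identity: cross-channel mean is 0 everywhere
  expect_lt(max(abs(apply(ep$data, c(2, 3), mean))), 1e-10)
  # baseline identity: per channel x trial mean over -550..-50 ms is 0
  bl <- ep$times_ms >= -550 & ep$times_ms <= -50
  expect_lt(max(abs(apply(ep$data[, bl, , drop = FALSE], c(1, 3), mean))),
            1e-10)
  # re-referencing is idempotent
  again <- sweep(ep$data, c(2, 3), apply(ep$data, c(2, 3), mean))
  expect_equal(again, ep$data, tolerance = 1e-12)
})

test_that("bad channels are replaced by their neighbours", {
  cfg <- preprocess_config(epoch_window_ms = c(-700, 700))
  set.seed(22)
  fs <- 500
  n <- fs * 30
  nch <- 16
  markers <- as.integer(seq(2 * fs, n - 2 * fs, by = 2.5 * fs))
  data <- matrix(rnorm(nch * n), nch)
  data[5, ] <- data[5, ] * 30              # broken amplifier channel
  rec <- continuous_recording(data, fs, fix_montage16$channel_names, markers)
  ep0 <- filter_downsample_epoch(rec, preprocess_config(
    target_srate = 500, epoch_window_ms = c(-700, 700)))
  ep <- reject_and_reference(ep0, cfg, fix_montage16)
  expect_identical(ep$bad_channels, fix_montage16$channel_names[5])
  # the interpolated channel now sits at a typical amplitude
  rms <- apply(ep$data, 1, function(x) sqrt(mean(x^2)))
  expect_lt(rms[5], 2 * median(rms))
})

test_that("evoked SNR does not degrade through the pipeline", {
  cfg <- preprocess_config(target_srate = 500,
                           epoch_window_ms = c(-700, 700))
  circ <- list(circuit_spec(c(-44, 40, 29), latency_window = c(80, 120),
                            amplitude = 80))
  rec <- simulate_subject(circ, noise_spec(), fix_montage16, fix_head,
                          quiet_cohort(n_pulses = 20), list(group = "SI"),
                          seed = 3, srate = 500)
  snr_of <- function(mat, times) {
    n100 <- times >= 80 & times <= 120
    base <- times >= -550 & times <= -50
    sqrt(mean(mat[, n100]^2)) / sqrt(mean(mat[, base]^2))
  }
  # raw epochs, no artifact handling
  w <- round(c(-700, 700) / 1000 * 500)
  times <- (w[1]:w[2]) / 500 * 1000
  raw <- array(0, c(16, length(times), 20))
  for (i in seq_along(rec$pulse_samples)) {
    p <- rec$pulse_samples[i]
    raw[, , i] <- rec$data[, (p + w[1]):(p + w[2])]
  }
  snr_raw <- snr_of(apply(raw, c(1, 2), mean), times)
  ep <- preprocess(rec, cfg, fix_montage16)
  snr_clean <- snr_of(average_epochs(ep)$data, ep$times_ms)
  expect_gte(snr_clean, snr_raw)
})
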