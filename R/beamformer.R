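#' Beamformer configuration
#'
#' @param noise_cov_window_ms pre-stimulus window used for the noise
#'   covariance estimate, ms pair.
#' @param filter_window_ms window over which the data covariance for the
#'   LCMV filters is pooled (spanning pre- and post-stimulus), ms pair.
#' @param regularization diagonal loading as a fraction of the mean
#'   covariance eigenvalue (default 0.05).
#' @return object of class `beamformer_config`.
#' @export
beamformer_config <- function(noise_cov_window_ms = c(-500, 0),
                              filter_window_ms = c(-500, 500),
                              regularization = 0.05) {
  stopifnot(noise_cov_window_ms[1] < noise_cov_window_ms[2],
            filter_window_ms[1] < filter_window_ms[2],
            regularization >= 0)
  structure(list(noise_cov_window_ms = noise_cov_window_ms,
                 filter_window_ms = filter_window_ms,
                 regularization = regularization),
            class = "beamformer_config")
}

# pooled channel covariance over a time window, across trials
window_covariance <- function(ep, window_ms) {
  sel <- ep$times_ms >= window_ms[1] & ep$times_ms <= window_ms[2]
  d <- dim(ep$data)
  x <- matrix(ep$data[, sel, , drop = FALSE], nrow = d[1])
  x <- x - rowMeans(x)
  tcrossprod(x) / (ncol(x) - 1)
}

#' Compute LCMV beamformer spatial filters
#'
#' Vector (unpooled-orientation) linearly constrained minimum-variance
#' filters `W = (L' C^-1 L)^-1 L' C^-1` per voxel, with `C` the regularized
#' channel covariance pooled over trials in the filter window. The unit-gain
#' constraint `W L = I` holds by construction.
#'
#' @param ep an [epoched_eeg()] (average-referenced).
#' @param lf a [leadfield_sphere()] lead field on the analysis grid.
#' @param cfg a [beamformer_config()].
#' @return object of class `spatial_filter`: `w` array
#'   `(3, n_channels, n_voxels)`, plus grid and channel order.
#' @export
lcmv_filters <- function(ep, lf, cfg = beamformer_config()) {
  stopifnot(inherits(ep, "epoched_eeg"), inherits(lf, "lead_field"))
  if (!identical(ep$channel_names, lf$channel_names))
    stop("epochs and lead field have different montages")
  sel <- ep$times_ms >= cfg$filter_window_ms[1] &
    ep$times_ms <= cfg$filter_window_ms[2]
  d <- dim(ep$data)
  if (sum(sel) * d[3] < d[1])
    stop("too few samples in the filter window to estimate the covariance")
  C <- window_covariance(ep, cfg$filter_window_ms)
  nch <- d[1]
  if (cfg$regularization > 0) {
    C <- C + diag(cfg$regularization * sum(diag(C)) / nch, nch)
  }
  Ci <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("covariance is singular; increase `regularization` ",
         "(average-referenced data always need loading)", call. = FALSE))
  nv <- dim(lf$lf)[3]
  w <- array(0, c(3, nch, nv))
  for (v in seq_len(nv)) {
    L <- lf$lf[, , v]                     # nch x 3
    CiL <- Ci %*% L
    w[, , v] <- solve(crossprod(L, CiL), t(CiL))
  }
  structure(list(w = w, grid = lf$grid, channel_names = ep$channel_names,
                 cfg = cfg),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat("<spatial_filter>", dim(x$w)[3], "voxels x", dim(x$w)[2],
      "channels (vector LCMV)\n")
  invisible(x)
}

#' Project epochs into source space
#'
#' Applies the beamformer per trial: 3-D moment time series `m(t) = W v(t)`
#' per voxel, with nonnegative source strength `ss(x, t) = ||m(t)||`. Also
#' returns the trial-average activation (mean of per-trial strengths).
#'
#' By default each trial is re-centred on its whole-epoch mean (per
#' channel) before projection. This cancels the trial's baseline-window
#' offset exactly: after baseline correction a trial's samples inside the
#' baseline window are anti-correlated with the subtracted offset while
#' post-stimulus samples are not, which — with autocorrelated background
#' activity — gives post-stimulus strengths a systematic variance surplus
#' and breaks the pre/post exchangeability the permutation test relies on.
#' The whole-epoch mean is symmetric in time, so re-centring on it restores
#' exchangeability without touching the sensor-level pipeline.
#'
#' @param ep an [epoched_eeg()].
#' @param filters a [lcmv_filters()] result.
#' @param demean re-centre each trial and channel on its whole-epoch mean
#'   before projecting (default `TRUE`).
#' @return object of class `source_activation`: `strength` (voxel x time,
#'   trial-average), `trials` (voxel x time x trial array), `times_ms`,
#'   `grid`.
#' @export
project_sources <- function(ep, filters, demean = TRUE) {
  stopifnot(inherits(ep, "epoched_eeg"), inherits(filters, "spatial_filter"))
  if (!identical(ep$channel_names, filters$channel_names))
    stop("epochs and filters have different montages")
  d <- dim(ep$data)
  nv <- dim(filters$w)[3]
  wmat <- matrix(aperm(filters$w, c(1, 3, 2)), nrow = 3 * nv)  # (3nv) x nch
  dat <- ep$data
  if (demean) dat <- sweep(dat, c(1, 3), apply(dat, c(1, 3), mean))
  x <- matrix(dat, nrow = d[1])                                # nch x (nt*ntr)
  m <- wmat %*% x                                              # 3nv x ...
  ss <- sqrt(m[seq(1, 3 * nv, 3), , drop = FALSE]^2 +
               m[seq(2, 3 * nv, 3), , drop = FALSE]^2 +
               m[seq(3, 3 * nv, 3), , drop = FALSE]^2)
  trials <- array(ss, c(nv, d[2], d[3]))
  avg <- rowMeans(trials, dims = 2)
  structure(list(strength = avg, trials = trials, times_ms = ep$times_ms,
                 grid = filters$grid),
            class = "source_activation")
}

#' @export
print.source_activation <- function(x, ...) {
  cat("<source_activation>", nrow(x$strength), "voxels x",
      ncol(x$strength), "samples,", dim(x$trials)[3], "trials\n")
  invisible(x)
}
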