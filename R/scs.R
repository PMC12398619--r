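#' Permutation-test configuration
#'
#' @param n_permutations number of permutations (>= 100).
#' @param alpha family-wise significance level.
#' @param pre_window_ms pre-stimulus window, ms pair.
#' @param post_window_ms post-stimulus window, ms pair; must contain as many
#'   samples as the pre window.
#' @param exclude_window_ms window whose samples are excluded from the
#'   tested family (mask fixed to 0 there). Defaults to the pulse-excision
#'   window: those samples are interpolated, not measured, so testing them
#'   for "significant activation" is meaningless and their distorted
#'   variance would break the pre/post exchangeability the permutation null
#'   relies on. Set to `NULL` to test every sample.
#' @param correction multiple-comparison correction; only `"max_stat"`.
#' @return object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, alpha = 0.05,
                               pre_window_ms = c(-500, -5),
                               post_window_ms = c(5, 500),
                               exclude_window_ms = c(-10, 25),
                               correction = "max_stat") {
  stopifnot(0 < alpha, alpha <= 1,
            pre_window_ms[1] < pre_window_ms[2],
            post_window_ms[1] < post_window_ms[2],
            pre_window_ms[2] < post_window_ms[1])
  correction <- match.arg(correction)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 pre_window_ms = pre_window_ms,
                 post_window_ms = post_window_ms,
                 exclude_window_ms = exclude_window_ms,
                 correction = correction),
            class = "permutation_config")
}

#' Max-statistic permutation mask of significant sources
#'
#' Tests, per voxel and post-stimulus time point, whether source strength
#' exceeds its time-matched pre-stimulus counterpart. The observed statistic
#' is the trial-mean post-stimulus strength minus the trial-mean of the
#' reversed-index-matched pre-stimulus strength. The null distribution is
#' built by randomly swapping each trial's pre/post window assignment
#' (equivalently, flipping the sign of its paired difference) and recording
#' the maximum statistic over all voxels and times, which controls the
#' family-wise error over the whole voxel-by-time family. A voxel-time cell
#' is masked significant when its permutation p-value
#' `(1 + #[max_b >= obs]) / (B + 1)` is at most `alpha`.
#'
#' @param src a [project_sources()] result (per-trial strengths).
#' @param cfg a [permutation_config()].
#' @param seed integer seed for the permutation draws.
#' @return object of class `significance_mask`: binary `mask`
#'   (voxel x post-window time), `times_ms`, `threshold` (the alpha-level
#'   max-null quantile), `alpha`.
#' @export
permutation_mask <- function(src, cfg = permutation_config(), seed = 1L) {
  stopifnot(inherits(src, "source_activation"))
  if (cfg$n_permutations < 100)
    stop("n_permutations must be at least 100 for inference")
  ntr <- dim(src$trials)[3]
  if (ntr < 2) stop("need at least 2 trials")
  tms <- src$times_ms
  excl <- function(idx) {
    if (is.null(cfg$exclude_window_ms)) return(idx)
    idx[tms[idx] < cfg$exclude_window_ms[1] |
          tms[idx] > cfg$exclude_window_ms[2]]
  }
  post_all <- which(tms >= cfg$post_window_ms[1] &
                      tms <= cfg$post_window_ms[2])
  pre_idx <- excl(which(tms >= cfg$pre_window_ms[1] &
                          tms <= cfg$pre_window_ms[2]))
  post_idx <- excl(post_all)
  m <- length(post_idx)
  if (length(pre_idx) < m)
    stop("pre window has fewer samples (", length(pre_idx),
         ") than the post window (", m, ")")
  # reversed-index matching: the first post sample pairs with the last
  # pre sample, so both sit symmetrically around the pulse
  pre_idx <- rev(pre_idx)[seq_len(m)]
  nv <- dim(src$trials)[1]
  # per-trial paired differences, trials x (voxel*time)
  dmat <- t(matrix(src$trials[, post_idx, , drop = FALSE] -
                     src$trials[, pre_idx, , drop = FALSE],
                   nv * m, ntr))
  obs <- colMeans(dmat)
  B <- cfg$n_permutations
  max_null <- local_rng(seed, {
    signs <- matrix(sample(c(-1, 1), B * ntr, replace = TRUE), B, ntr)
    perm <- signs %*% dmat / ntr
    perm[cbind(seq_len(B), max.col(perm, ties.method = "first"))]
  })
  # #(max_null >= obs) = B - #(max_null < obs), via a sorted lookup
  sorted <- sort(max_null)
  exceed <- B - findInterval(obs, sorted, left.open = TRUE)
  pvals <- (1 + exceed) / (B + 1)
  mask <- matrix(0L, nv, length(post_all))
  mask[, match(post_idx, post_all)] <- as.integer(pvals <= cfg$alpha)
  thr <- stats::quantile(max_null, 1 - cfg$alpha, names = FALSE, type = 1)
  structure(list(mask = mask, times_ms = tms[post_all],
                 threshold = thr, alpha = cfg$alpha),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat("<significance_mask>", nrow(x$mask), "voxels x", ncol(x$mask),
      "samples;", sum(x$mask), "significant cells (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Stimulation target
#'
#' @param mni_mm MNI coordinates of the stimulated site (default the left
#'   DLPFC target `[-44, 40, 29]`).
#' @param label free-text label.
#' @return object of class `stimulation_target`.
#' @export
stimulation_target <- function(mni_mm = c(-44, 40, 29),
                               label = "left DLPFC") {
  stopifnot(length(mni_mm) == 3)
  structure(list(mni_mm = as.numeric(mni_mm), label = label),
            class = "stimulation_target")
}

#' Voxel-wise significant current scattering field
#'
#' `SCS(x, t) = ss(x, t) * mask(x, t) * ||pos(x) - x_stim||`, the
#' significance-masked source strength weighted by Euclidean distance (mm)
#' from the stimulation site. The stimulation site is snapped to its nearest
#' grid voxel before distances are computed, so the target voxel itself
#' contributes (approximately) zero: SCS scores propagation, not local
#' activation.
#'
#' @param src a [project_sources()] result (the trial-average strength is
#'   used).
#' @param mask a [permutation_mask()] result on the same grid and window.
#' @param grid the analysis [build_grid()].
#' @param stim a [stimulation_target()].
#' @return object of class `scs_field`: `scs` (voxel x time, strength·mm),
#'   `times_ms`, `grid`, `stim_voxel`.
#' @export
scs_voxel <- function(src, mask, grid, stim = stimulation_target()) {
  stopifnot(inherits(src, "source_activation"),
            inherits(mask, "significance_mask"),
            inherits(grid, "source_grid"),
            inherits(stim, "stimulation_target"))
  sel <- match(mask$times_ms, src$times_ms)
  if (anyNA(sel)) stop("mask times are not a subset of the activation times")
  ss <- src$strength[, sel, drop = FALSE]
  if (!identical(dim(ss), dim(mask$mask)))
    stop("activation and mask shapes disagree")
  if (nrow(grid$positions) != nrow(ss))
    stop("grid does not match the activation voxels")
  sv <- nearest_voxel(grid, stim$mni_mm)
  d <- sqrt(rowSums(sweep(grid$positions, 2, grid$positions[sv, ])^2))
  scs <- ss * mask$mask * d
  structure(list(scs = scs, times_ms = mask$times_ms, grid = grid,
                 stim_voxel = sv),
            class = "scs_field")
}

#' ROI atlas on a source grid
#'
#' Builds spherical ROI fixtures: each row of `roi_spec` contributes the
#' inside-grid voxels within `radius_mm` of its centre, and rows sharing a
#' `roi` name (e.g. left and right AAL labels of one node) are pooled.
#'
#' @param grid a [build_grid()].
#' @param roi_spec data frame with columns `roi`, `network`, `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm` (defaults to the bundled AAL centroid table for the
#'   DMN/ECN/SN node set).
#' @param min_radius_mm effective lower bound on the ROI radius. A sphere
#'   smaller than half the lattice diagonal (`spacing * sqrt(3)/2`) can fall
#'   between grid points and capture nothing; on coarse analysis grids the
#'   bound keeps every node represented. Set to 0 to use the literal radii.
#' @return object of class `roi_atlas`: named list `voxels` of integer
#'   vectors, and `network` (named character).
#' @export
build_atlas_fixture <- function(grid, roi_spec = roi_centroids(),
                                min_radius_mm = grid$spacing * sqrt(3) / 2) {
  stopifnot(inherits(grid, "source_grid"),
            all(c("roi", "x_mm", "y_mm", "z_mm", "radius_mm") %in%
                  names(roi_spec)))
  if (any(roi_spec$radius_mm <= 0)) stop("ROI radii must be positive")
  if (!"network" %in% names(roi_spec)) roi_spec$network <- NA_character_
  vox <- list()
  net <- character()
  for (r in unique(roi_spec$roi)) {
    rows <- roi_spec[roi_spec$roi == r, , drop = FALSE]
    members <- integer()
    for (i in seq_len(nrow(rows))) {
      ctr <- as.numeric(rows[i, c("x_mm", "y_mm", "z_mm")])
      d <- sqrt(rowSums(sweep(grid$positions, 2, ctr)^2))
      members <- union(members, which(d <= max(rows$radius_mm[i],
                                               min_radius_mm)))
    }
    if (!length(members))
      warning("ROI ", r, " captures no grid voxels")
    vox[[r]] <- sort(members)
    net[r] <- rows$network[1]
  }
  structure(list(voxels = vox, network = net, grid = grid),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("<roi_atlas>", length(x$voxels), "ROIs:",
      paste(sprintf("%s(%d)", names(x$voxels),
                    lengths(x$voxels)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-ROI significant current scattering
#'
#' Aggregates the SCS field over each ROI's member voxels and the samples of
#' the analysis window (default: sum, the accumulated scattering; `mean`
#' divides by the number of voxel-time cells, removing ROI-size dependence).
#'
#' @param field a [scs_voxel()] result.
#' @param atlas a [build_atlas_fixture()] atlas on the same grid.
#' @param window ms pair inside the post-stimulus window (default the N100
#'   window 80–120 ms).
#' @param aggregate `"sum"` or `"mean"`.
#' @return tibble with columns `roi`, `network`, `window_start_ms`,
#'   `window_end_ms`, `scs`.
#' @export
scs_roi <- function(field, atlas, window = c(80, 120), aggregate = "sum") {
  stopifnot(inherits(field, "scs_field"), inherits(atlas, "roi_atlas"))
  aggregate <- match.arg(aggregate, c("sum", "mean"))
  sel <- field$times_ms >= window[1] & field$times_ms <= window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      "] ms has no samples in the post-stimulus window")
  vals <- vapply(names(atlas$voxels), function(r) {
    v <- atlas$voxels[[r]]
    if (!length(v)) {
      warning("ROI ", r, " is empty; SCS reported as 0")
      return(0)
    }
    block <- field$scs[v, sel, drop = FALSE]
    if (aggregate == "sum") sum(block) else mean(block)
  }, 0)
  tibble::tibble(roi = names(atlas$voxels),
                 network = unname(atlas$network[names(atlas$voxels)]),
                 window_start_ms = window[1], window_end_ms = window[2],
                 scs = unname(vals))
}
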