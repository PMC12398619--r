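#' Sensor montage on a spherical scalp
#'
#' A montage holds channel labels and 3-D electrode positions (MNI mm) on the
#' scalp shell of a [head_model()]. Positions are stored as an
#' `n_channels x 3` matrix with row names equal to the labels.
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions numeric `n x 3` matrix of electrode positions (mm).
#' @return An object of class `sensor_montage`.
#' @seealso [standard_montage()] for the bundled 64-channel 10-10 cap.
#' @export
sensor_montage <- function(channel_names, positions) {
  positions <- as.matrix(positions)
  stopifnot(is.character(channel_names),
            nrow(positions) == length(channel_names),
            ncol(positions) == 3)
  if (anyDuplicated(channel_names))
    stop("duplicate channel labels in montage")
  if (anyDuplicated(positions))
    stop("electrode positions must be distinct")
  dimnames(positions) <- list(channel_names, c("x", "y", "z"))
  structure(list(channel_names = channel_names, positions = positions),
            class = "sensor_montage")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat("<sensor_montage> ", length(x$channel_names), " channels: ",
      paste(utils::head(x$channel_names, 6), collapse = ", "),
      if (length(x$channel_names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Bundled 64-channel 10-10 montage projected onto a spherical scalp
#'
#' Loads the standard 10-10 electrode direction table shipped with the package
#' and projects each electrode radially onto the scalp shell of `head`. Only
#' the angular position of each electrode is taken from the standard table;
#' the radius is that of the head model, so the montage always sits exactly on
#' the outermost shell.
#'
#' @param head a [head_model()]; defaults to the package default.
#' @param n_channels keep the first `n_channels` labels of the 64-channel cap
#'   (useful for small test problems).
#' @param jitter_mm optional tangential jitter (mm) applied to each electrode,
#'   used by inverse-crime guards that analyse with a montage deliberately
#'   mismatched to the generating one. Requires `seed`.
#' @param seed integer seed for the jitter.
#' @return a `sensor_montage`.
#' @export
standard_montage <- function(head = head_model(), n_channels = 64,
                             jitter_mm = 0, seed = NULL) {
  path <- system.file("extdata", "montage_1010_64.csv", package = "tepscatter")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[seq_len(min(n_channels, nrow(tab))), ]
  xyz <- as.matrix(tab[, c("x_mm", "y_mm", "z_mm")])
  # the shipped table is in a head frame centred near the sphere centre;
  # keep directions, impose the model's scalp radius
  ctr_fit <- colMeans(xyz)
  dirs <- sweep(xyz, 2, ctr_fit)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  if (jitter_mm > 0) {
    if (is.null(seed)) stop("electrode jitter requires a seed")
    dirs <- dirs + local_rng(seed, stats::rnorm(length(dirs))) *
      (jitter_mm / max(head$shell_radii))
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  pos <- sweep(dirs * max(head$shell_radii), 2, head$center, "+")
  sensor_montage(tab$label, pos)
}

# evaluate expr with a private RNG stream, restoring global state
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
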