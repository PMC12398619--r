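#' Analytic three-shell spherical head model
#'
#' Concentric-sphere volume conductor with brain, skull and scalp shells.
#' Used both to generate synthetic sensor data (forward model) and to build
#' the lead field for source analysis. Radii must be strictly increasing and
#' conductivities positive. The default conductivities follow the common
#' 0.33 / 0.0042 / 0.33 S/m brain/skull/scalp convention.
#'
#' The model lives in MNI mm coordinates; `center` places the sphere so that
#' cortical and subcortical ROI centroids fall inside the innermost shell.
#'
#' @param shell_radii numeric length-3, inner to outer (brain, skull, scalp)
#'   radii in mm.
#' @param conductivities numeric length-3 conductivities (S/m), same order.
#' @param center sphere centre in MNI mm.
#' @return object of class `head_model`.
#' @export
head_model <- function(shell_radii = c(80, 85, 92),
                       conductivities = c(0.33, 0.0042, 0.33),
                       center = c(0, -18, 15)) {
  stopifnot(length(shell_radii) == 3, length(conductivities) == 3,
            all(diff(shell_radii) > 0), all(conductivities > 0),
            length(center) == 3)
  structure(list(shell_radii = as.numeric(shell_radii),
                 conductivities = as.numeric(conductivities),
                 center = as.numeric(center)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> radii", paste(x$shell_radii, collapse = "/"),
      "mm, conductivities", paste(x$conductivities, collapse = "/"),
      "S/m, centre [", paste(x$center, collapse = ", "), "] mm\n")
  invisible(x)
}

#' Perturbed copy of a head model
#'
#' Scales all shell radii by `radius_scale`. Used by parameter-recovery tests
#' that must not commit the inverse crime: data are generated under a head
#' model slightly different from the one used for analysis.
#'
#' @param head a `head_model`.
#' @param radius_scale multiplicative factor on all radii (e.g. 1.02).
#' @return a `head_model`.
#' @export
perturb_head <- function(head, radius_scale = 1.02) {
  head_model(head$shell_radii * radius_scale, head$conductivities, head$center)
}

#' Regular source grid clipped to the brain shell
#'
#' Axis-aligned cubic lattice with the given spacing, centred on the sphere
#' centre; voxels strictly inside the innermost shell form the source space.
#'
#' @param head a [head_model()].
#' @param spacing lattice spacing in mm (default 8).
#' @return object of class `source_grid` with `positions` (`n x 3` MNI mm),
#'   `spacing`, and the generating head model.
#' @export
build_grid <- function(head, spacing = 8) {
  stopifnot(inherits(head, "head_model"), spacing > 0)
  r <- head$shell_radii[1]
  if (spacing > 2 * r) stop("grid spacing exceeds the head diameter")
  ax <- seq(-r, r, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside <- rowSums(g^2) < r^2
  pos <- sweep(g[inside, , drop = FALSE], 2, head$center, "+")
  rownames(pos) <- NULL
  structure(list(positions = pos, spacing = spacing, head = head),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat("<source_grid>", nrow(x$positions), "voxels,", x$spacing, "mm spacing\n")
  invisible(x)
}

#' Nearest grid voxel to an MNI position
#' @param grid a `source_grid`.
#' @param pos MNI mm triplet.
#' @return integer voxel index.
#' @export
nearest_voxel <- function(grid, pos) {
  d2 <- rowSums(sweep(grid$positions, 2, pos)^2)
  which.min(d2)
}

# ---- multishell sphere potential ------------------------------------------
#
# Potential on the outer surface of an N-shell concentric sphere from a
# current dipole in the innermost shell, by Legendre expansion. Per harmonic
# order n the radial part in each layer is  A r^n + B r^-(n+1); boundary
# conditions (continuity of V and of sigma dV/dr at interfaces, zero normal
# current at the scalp) give a small linear system whose solution yields the
# surface gain for that order. Radii are normalised by the scalp radius for
# conditioning.

# per-order surface gains G_n for a unit source coefficient r^-(n+1) in
# layer 1 (normalised radii); returns numeric vector length n_terms
shell_gains <- function(radii, cond, n_terms) {
  r1 <- radii[1] / radii[3]; r2 <- radii[2] / radii[3]; r3 <- 1
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    # unknowns: A1, A2, B2, A3, B3; source term r^-(n+1) lives in layer 1
    # rows: V cont r1; J cont r1; V cont r2; J cont r2; J = 0 at r3
    m <- matrix(0, 5, 5)
    b <- numeric(5)
    pr <- function(r) r^n
    qr <- function(r) r^-(n + 1)
    dpr <- function(r) n * r^(n - 1)
    dqr <- function(r) -(n + 1) * r^-(n + 2)
    m[1, ] <- c(pr(r1), -pr(r1), -qr(r1), 0, 0);            b[1] <- -qr(r1)
    m[2, ] <- c(s1 * dpr(r1), -s2 * dpr(r1), -s2 * dqr(r1), 0, 0)
    b[2] <- -s1 * dqr(r1)
    m[3, ] <- c(0, pr(r2), qr(r2), -pr(r2), -qr(r2));       b[3] <- 0
    m[4, ] <- c(0, s2 * dpr(r2), s2 * dqr(r2), -s3 * dpr(r2), -s3 * dqr(r2))
    m[5, ] <- c(0, 0, 0, dpr(r3), dqr(r3))
    # column equilibration: raw powers of the radii span a huge dynamic
    # range at high order
    cs <- apply(abs(m), 2, max)
    sol <- solve(sweep(m, 2, cs, "/"), b) / cs
    g[n] <- sol[4] * pr(r3) + sol[5] * qr(r3)
  }
  g
}

# Legendre P_n(c) and derivative P_n'(c) for n = 1..n_terms, vectorised
# over c; the derivative uses P'_{n+1} = P'_{n-1} + (2n+1) P_n, which is
# stable at the poles c = +/-1
legendre_terms <- function(c_ang, n_terms) {
  ne <- length(c_ang)
  p_nm1 <- rep(1, ne)              # P_0
  p_n <- c_ang                     # P_1
  d_nm1 <- rep(0, ne)              # P_0'
  d_n <- rep(1, ne)                # P_1'
  P <- matrix(0, n_terms, ne)
  Pd <- matrix(0, n_terms, ne)
  for (n in seq_len(n_terms)) {
    P[n, ] <- p_n
    Pd[n, ] <- d_n
    p_np1 <- ((2 * n + 1) * c_ang * p_n - n * p_nm1) / (n + 1)
    d_np1 <- d_nm1 + (2 * n + 1) * p_n
    p_nm1 <- p_n; p_n <- p_np1
    d_nm1 <- d_n; d_n <- d_np1
  }
  list(P = P, Pd = Pd)
}

# surface potential (uV per nA*m) at electrodes for unit dipoles along x/y/z
# at a single source position; returns n_channels x 3 matrix (not referenced)
dipole_potential <- function(head, src_mni, elec_mni, n_terms = 80) {
  ctr <- head$center
  radii <- head$shell_radii
  src <- src_mni - ctr
  f <- sqrt(sum(src^2))
  if (f >= radii[1]) stop("dipole at or outside the inner shell")
  R <- radii[3]
  E <- sweep(elec_mni, 2, ctr)
  Ehat <- E / sqrt(rowSums(E^2))
  gains <- shell_gains(radii, head$conductivities, n_terms)
  # unit scale: nA*m dipole, mm distances, S/m conductivity -> microvolts
  unit <- 1e3 / (4 * pi * head$conductivities[1])
  if (f < 1e-9) {                      # central dipole: bhat undefined
    bhat <- c(0, 0, 1)
  } else bhat <- src / f
  c_ang <- as.vector(Ehat %*% bhat)
  lt <- legendre_terms(c_ang, n_terms)
  n_seq <- seq_len(n_terms)
  # radial factor per order: gains hold the surface value for a unit source
  # coefficient; the dipole's n-th source coefficient is f^(n-1)/R^(n+1),
  # i.e. rho^(n-1)/R^2 with rho = f/R after radius normalisation
  rho <- f / R
  rad <- gains * rho^(n_seq - 1) / R^2
  # per-electrode radial and tangential series sums
  sum_rad <- as.vector(crossprod(lt$P, rad * n_seq))   # sum_n n rad_n P_n
  sum_tan <- as.vector(crossprod(lt$Pd, rad))          # sum_n rad_n P_n'
  # q_r = q.bhat; tangential term = (q.(ehat - c bhat)) * P_n'(c): the
  # 1/sin factors of the unit tangent and of P_n^1 cancel exactly
  tan_num <- Ehat - outer(c_ang, bhat)
  V <- matrix(0, nrow(elec_mni), 3)
  for (k in 1:3) {
    V[, k] <- bhat[k] * sum_rad + tan_num[, k] * sum_tan
  }
  V * unit
}

#' Lead field of a source grid in a spherical head model
#'
#' Computes the average-referenced sensor potential of unit dipoles along
#' x, y and z at every grid voxel, using the analytic Legendre-series
#' solution for the three-shell concentric sphere. Units are microvolts per
#' nA·m of dipole moment.
#'
#' @param head a [head_model()].
#' @param grid a [build_grid()] source grid.
#' @param montage a [sensor_montage()] on the scalp shell.
#' @param n_terms number of series terms (>= 20); the series converges like
#'   `(f/R)^n`, so the default 80 is ample for 8 mm-deep sources.
#' @return object of class `lead_field`: array `lf` of dim
#'   `(n_channels, 3, n_voxels)`, plus `grid`, `channel_names`.
#' @export
leadfield_sphere <- function(head, grid, montage, n_terms = 80) {
  stopifnot(inherits(head, "head_model"), inherits(grid, "source_grid"),
            inherits(montage, "sensor_montage"), n_terms >= 20)
  pos <- grid$positions
  nch <- length(montage$channel_names)
  lf <- array(0, c(nch, 3, nrow(pos)))
  for (v in seq_len(nrow(pos))) {
    V <- dipole_potential(head, pos[v, ], montage$positions, n_terms)
    lf[, , v] <- V - rep(colMeans(V), each = nch)   # average reference
  }
  structure(list(lf = lf, grid = grid, channel_names = montage$channel_names),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat("<lead_field>", dim(x$lf)[3], "voxels x", dim(x$lf)[1], "channels\n")
  invisible(x)
}

# sensor topography (average-referenced, uV) of one dipole with moment
# q (nA*m, 3-vector) at an arbitrary position, exact (not grid-snapped)
dipole_topography <- function(head, montage, pos_mni, q, n_terms = 80) {
  V <- dipole_potential(head, pos_mni, montage$positions, n_terms)
  v <- as.vector(V %*% q)
  v - mean(v)
}
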