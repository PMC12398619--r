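# Shared small fixtures, built once per test run.

fix_head <- head_model()
fix_montage16 <- standard_montage(fix_head, n_channels = 16)
fix_montage <- standard_montage(fix_head)
fix_grid24 <- build_grid(fix_head, 24)
fix_lf24_16 <- leadfield_sphere(fix_head, fix_grid24, fix_montage16)

quiet_cohort <- function(n_pulses = 3, seed = 1) {
  cohort_spec(n_per_group = c(SI = 1), pulses_per_subject = n_pulses,
              isi_s = 2.5, seed = seed)
}

no_noise <- noise_spec(pink_noise_sd = 0, line_noise_amp = 0, decay_amp = 0,
                       pulse_artifact_amp = 0)

# Independent oracle for the homogeneous bounded sphere: the infinite-medium
# multipole expansion with each order scaled by (2n+1)/n, the factor that
# follows directly from the insulating outer boundary. Written with its own
# Legendre recursions, independent of the package's multishell solver.
oracle_homog_sphere <- function(sigma, R, src, q, elec, n_terms = 150) {
  f <- sqrt(sum(src^2))
  bhat <- if (f > 0) src / f else c(0, 0, 1)
  out <- numeric(nrow(elec))
  for (e in seq_len(nrow(elec))) {
    ehat <- elec[e, ] / sqrt(sum(elec[e, ]^2))
    cc <- sum(ehat * bhat)
    qr_ <- sum(q * bhat)
    tanv <- ehat - cc * bhat
    qt_ <- sum(q * tanv)
    p0 <- 1; p1 <- cc       # P_0, P_1
    d0 <- 0; d1 <- 1        # derivatives
    acc <- 0
    for (n in seq_len(n_terms)) {
      term <- (2 * n + 1) / n * f^(n - 1) / R^(n + 1) *
        (n * qr_ * p1 + qt_ * d1)
      acc <- acc + term
      p2 <- ((2 * n + 1) * cc * p1 - n * p0) / (n + 1)
      d2 <- d0 + (2 * n + 1) * p1
      p0 <- p1; p1 <- p2; d0 <- d1; d1 <- d2
    }
    out[e] <- acc * 1e3 / (4 * pi * sigma)
  }
  out
}
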