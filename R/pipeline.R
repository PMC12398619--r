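#' Pipeline run configuration
#'
#' Bundles every stage's configuration with a master seed. Defaults give a
#' desk-scale demonstration (3 subjects per group, 20 mm grid, 40 pulses) of
#' the full chain; study-scale values are the stage defaults themselves.
#'
#' @param cohort a [cohort_spec()].
#' @param circuits list of [circuit_spec()]s.
#' @param noise a [noise_spec()].
#' @param head analysis [head_model()].
#' @param generator_head head model used for simulation (defaults to `head`;
#'   pass a perturbed model to exercise the inverse-crime guard).
#' @param montage a [sensor_montage()].
#' @param generator_montage montage used for simulation.
#' @param preprocess a [preprocess_config()].
#' @param beamformer a [beamformer_config()].
#' @param permutation a [permutation_config()].
#' @param grid_spacing analysis grid spacing, mm.
#' @param stim a [stimulation_target()].
#' @param scs_window ms pair for ROI aggregation (N100 window).
#' @param tep_channel sensor-level analysis electrode.
#' @param srate simulation sampling rate, Hz.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(n_per_group = c(SI = 3, NSI = 3,
                                                            HC = 3),
                                            pulses_per_subject = 40),
                       circuits = default_circuits(),
                       noise = noise_spec(),
                       head = head_model(),
                       generator_head = head,
                       montage = standard_montage(head),
                       generator_montage = montage,
                       preprocess = preprocess_config(),
                       beamformer = beamformer_config(),
                       permutation = permutation_config(n_permutations = 200),
                       grid_spacing = 20,
                       stim = stimulation_target(),
                       scs_window = c(80, 120),
                       tep_channel = "F3",
                       srate = 1000,
                       seed = 1L) {
  structure(list(cohort = cohort, circuits = circuits, noise = noise,
                 head = head, generator_head = generator_head,
                 montage = montage, generator_montage = generator_montage,
                 preprocess = preprocess, beamformer = beamformer,
                 permutation = permutation, grid_spacing = grid_spacing,
                 stim = stim, scs_window = scs_window,
                 tep_channel = tep_channel, srate = srate,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulate → preprocess → TEP components → beamformer source projection →
#' permutation mask → SCS per ROI → group statistics, with all randomness
#' derived from the master seed. Rerunning with an identical configuration
#' reproduces every output.
#'
#' @param config a [run_config()].
#' @param windows component windows for sensor-level and window-specificity
#'   analyses.
#' @param progress print per-subject progress.
#' @return list with `subjects` (covariates), `tep` (component tibble),
#'   `scs` (per subject × ROI × window tibble joined with covariates),
#'   `stats` (per-ROI N100-window group comparisons), `config`.
#' @export
run_pipeline <- function(config = run_config(),
                         windows = component_windows(),
                         progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  cohort$seed <- config$seed
  subjects <- simulate_covariates(cohort)
  grid <- build_grid(config$head, config$grid_spacing)
  lf <- leadfield_sphere(config$head, grid, config$montage)
  atlas <- build_atlas_fixture(grid)
  tep_rows <- list()
  scs_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    if (progress) message("subject ", sid)
    rec <- simulate_subject(config$circuits, config$noise,
                            config$generator_montage, config$generator_head,
                            cohort, subjects[i, ],
                            seed = subject_seed(config$seed, sid),
                            srate = config$srate)
    ep <- preprocess(rec, config$preprocess, config$montage)
    tw <- average_epochs(ep)
    comp <- extract_components(tw, config$tep_channel, windows)
    comp$subject_id <- sid
    tep_rows[[sid]] <- comp
    filt <- lcmv_filters(ep, lf, config$beamformer)
    src <- project_sources(ep, filt)
    mask <- permutation_mask(src, config$permutation,
                             seed = subject_seed(config$seed,
                                                 paste0(sid, ":perm")))
    field <- scs_voxel(src, mask, grid, config$stim)
    per_win <- lapply(names(windows), function(wn) {
      out <- scs_roi(field, atlas, windows[[wn]])
      out$component <- wn
      out
    })
    sc <- dplyr::bind_rows(per_win)
    sc$subject_id <- sid
    scs_rows[[sid]] <- sc
  }
  tep_tbl <- dplyr::left_join(dplyr::bind_rows(tep_rows), subjects,
                              by = "subject_id")
  scs_tbl <- dplyr::left_join(dplyr::bind_rows(scs_rows), subjects,
                              by = "subject_id")
  n100 <- scs_tbl[scs_tbl$window_start_ms == config$scs_window[1] &
                    scs_tbl$window_end_ms == config$scs_window[2], ]
  stats_tbl <- scs_group_stats(n100)
  list(subjects = subjects, tep = tep_tbl, scs = scs_tbl,
       stats = stats_tbl, config = config)
}

#' Per-ROI group comparison of SCS values
#'
#' One-way ANOVA (with automatic Welch fallback and Tukey HSD post hocs)
#' across groups, per ROI.
#'
#' @param scs_tbl tibble as produced by [run_pipeline()] (`roi`, `scs`,
#'   `group` columns).
#' @return tibble with one row per ROI (omnibus F/p and SI-vs-NSI Tukey p).
#' @export
scs_group_stats <- function(scs_tbl) {
  rois <- unique(scs_tbl$roi)
  rows <- lapply(rois, function(r) {
    sub <- scs_tbl[scs_tbl$roi == r, ]
    if (stats::sd(sub$scs) == 0) {
      return(tibble::tibble(roi = r, statistic = 0, p_value = 1,
                            p_si_nsi = 1, variant = "degenerate"))
    }
    res <- oneway_anova_auto(sub, scs, group)
    pair <- res$pairwise
    si_nsi <- pair$p_tukey[grepl("SI", pair$contrast) &
                             grepl("NSI", pair$contrast) &
                             !grepl("HC", pair$contrast)]
    tibble::tibble(roi = r, statistic = res$omnibus$statistic,
                   p_value = res$omnibus$p_value,
                   p_si_nsi = if (length(si_nsi)) si_nsi[1] else NA_real_,
                   variant = res$variant)
  })
  dplyr::bind_rows(rows)
}

#' Family-wise type-I error of the permutation mask on null subjects
#'
#' Simulates subjects with no post-stimulus source activity (noise only),
#' runs each through preprocessing, beamforming and the max-statistic
#' permutation mask, and reports the fraction of subjects whose mask
#' contains any significant voxel — the empirical family-wise false-positive
#' rate, to be compared against `alpha`.
#'
#' @param n_subjects number of simulated null subjects.
#' @param n_trials pulses per subject.
#' @param grid_spacing analysis grid spacing, mm (20 mm gives ~270 voxels).
#' @param n_permutations permutations per subject.
#' @param alpha significance level.
#' @param srate analysis sampling rate, Hz.
#' @param seed master seed.
#' @param progress print progress every 20 subjects.
#' @return list: `fwer` (fraction), `any_sig` (logical per subject),
#'   `n_subjects`, `alpha`.
#' @export
fwer_null_experiment <- function(n_subjects = 200, n_trials = 40,
                                 grid_spacing = 20, n_permutations = 200,
                                 alpha = 0.05, srate = 250, seed = 1L,
                                 progress = FALSE) {
  head <- head_model()
  montage <- standard_montage(head)
  grid <- build_grid(head, grid_spacing)
  lf <- leadfield_sphere(head, grid, montage)
  cohort <- cohort_spec(n_per_group = c(HC = 1), pulses_per_subject = n_trials,
                        isi_s = 2.5, seed = seed)
  pcfg <- preprocess_config(target_srate = srate,
                            epoch_window_ms = c(-700, 700))
  bcfg <- beamformer_config()
  mcfg <- permutation_config(n_permutations = n_permutations, alpha = alpha)
  noise <- noise_spec()
  any_sig <- logical(n_subjects)
  for (s in seq_len(n_subjects)) {
    rec <- simulate_subject(list(), noise, montage, head, cohort,
                            list(group = "HC"),
                            seed = seed + 7919L * s, srate = srate)
    ep <- preprocess(rec, pcfg, montage)
    filt <- lcmv_filters(ep, lf, bcfg)
    src <- project_sources(ep, filt)
    mask <- permutation_mask(src, mcfg, seed = seed + 104729L * s)
    any_sig[s] <- any(mask$mask > 0)
    if (progress && s %% 20 == 0)
      message(s, "/", n_subjects, " subjects, running FWER = ",
              signif(mean(any_sig[1:s]), 3))
  }
  list(fwer = mean(any_sig), any_sig = any_sig, n_subjects = n_subjects,
       alpha = alpha)
}

#' Beamformer localization accuracy under model mismatch
#'
#' Places a single dipole at a random deep-enough grid-interior location,
#' simulates noiseless evoked epochs under a perturbed head model (shell
#' radii scaled, electrodes jittered) and localizes the peak projected power
#' with the unperturbed analysis model. Reports the fraction of placements
#' localized within `tolerance_steps` grid steps of the true position.
#'
#' @param n_placements number of random dipole placements.
#' @param grid_spacing analysis grid spacing, mm.
#' @param radius_scale generator head radii scale factor (inverse-crime
#'   guard).
#' @param electrode_jitter_mm generator electrode jitter, mm.
#' @param tolerance_steps allowed localization error in grid steps.
#' @param seed master seed.
#' @return list: `hit_rate`, `errors_mm` per placement, `tolerance_mm`.
#' @export
localization_experiment <- function(n_placements = 50, grid_spacing = 12,
                                    radius_scale = 1.02,
                                    electrode_jitter_mm = 2,
                                    tolerance_steps = 2, seed = 1L) {
  head <- head_model()
  montage <- standard_montage(head)
  grid <- build_grid(head, grid_spacing)
  lf <- leadfield_sphere(head, grid, montage)
  gen_head <- perturb_head(head, radius_scale)
  gen_montage <- standard_montage(gen_head, jitter_mm = electrode_jitter_mm,
                                  seed = seed)
  cohort <- cohort_spec(n_per_group = c(HC = 1), pulses_per_subject = 10,
                        isi_s = 2.5, seed = seed)
  pcfg <- preprocess_config(target_srate = 250,
                            epoch_window_ms = c(-700, 700),
                            decay_model = "off",
                            bad_channel_ratio = Inf)
  bcfg <- beamformer_config()
  no_noise <- noise_spec(pink_noise_sd = 0, line_noise_amp = 0,
                         decay_amp = 0, pulse_artifact_amp = 0)
  # candidate true positions: grid voxels comfortably inside the brain shell
  # and away from the centre (where all lead fields vanish radially)
  ctr <- head$center
  depth <- sqrt(rowSums(sweep(grid$positions, 2, ctr)^2))
  candidates <- which(depth < 0.85 * head$shell_radii[1] & depth > 20)
  errs <- numeric(n_placements)
  for (k in seq_len(n_placements)) {
    v_true <- local_rng(seed + 17L * k, sample(candidates, 1))
    circ <- circuit_spec(grid$positions[v_true, ],
                         latency_window = c(80, 120), amplitude = 80)
    rec <- simulate_subject(list(circ), no_noise, gen_montage, gen_head,
                            cohort, list(group = "HC"),
                            seed = seed + 31L * k, srate = 250)
    ep <- preprocess(rec, pcfg, montage)
    filt <- lcmv_filters(ep, lf, bcfg)
    src <- project_sources(ep, filt)
    post <- src$times_ms >= 80 & src$times_ms <= 120
    pow <- rowMeans(src$strength[, post, drop = FALSE]^2)
    v_hat <- which.max(pow)
    errs[k] <- sqrt(sum((grid$positions[v_hat, ] -
                           grid$positions[v_true, ])^2))
  }
  tol <- tolerance_steps * grid_spacing
  list(hit_rate = mean(errs <= tol + 1e-9), errors_mm = errs,
       tolerance_mm = tol)
}

#' Cohort-level SCS parameter-recovery experiment
#'
#' Simulates an SI/NSI/HC cohort in which only the mPFC and ACC circuit
#' gains are elevated in the SI group, runs the full pipeline under the
#' inverse-crime guard (perturbed generator head model and electrode
#' positions), and returns the SCS table over all component windows together
#' with the sensor-level TEP components.
#'
#' @param n_per_group subjects per group.
#' @param gain_si SI-group gain for mPFC/ACC circuits.
#' @param n_trials pulses per subject.
#' @param grid_spacing analysis grid spacing, mm.
#' @param srate analysis and simulation sampling rate, Hz.
#' @param n_permutations permutations per subject.
#' @param seed master seed.
#' @param progress print per-subject progress.
#' @return as [run_pipeline()].
#' @export
cohort_recovery_experiment <- function(n_per_group = 20, gain_si = 1.5,
                                       n_trials = 40, grid_spacing = 20,
                                       srate = 250, n_permutations = 200,
                                       seed = 1L, progress = FALSE) {
  head <- head_model()
  cfg <- run_config(
    cohort = cohort_spec(n_per_group = c(SI = n_per_group, NSI = n_per_group,
                                         HC = n_per_group),
                         pulses_per_subject = n_trials, isi_s = 2.5,
                         seed = seed),
    circuits = default_circuits(gain_si = gain_si),
    head = head,
    generator_head = perturb_head(head, 1.02),
    montage = standard_montage(head),
    generator_montage = standard_montage(perturb_head(head, 1.02),
                                         jitter_mm = 2, seed = seed),
    preprocess = preprocess_config(target_srate = srate,
                                   epoch_window_ms = c(-700, 700)),
    permutation = permutation_config(n_permutations = n_permutations),
    grid_spacing = grid_spacing,
    srate = srate,
    seed = seed)
  run_pipeline(cfg, progress = progress)
}
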