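# synthetic source_activation built directly from arrays
make_src <- function(trials, times) {
  structure(list(strength = rowMeans(trials, dims = 2), trials = trials,
                 times_ms = times, grid = NULL),
            class = "source_activation")
}

test_that("permutation mask hits a constructed deterministic effect", {
  set.seed(6)
  nv <- 30; ntr <- 20
  times <- seq(-500, 500, by = 5)
  trials <- array(abs(rnorm(nv * length(times) * ntr)),
                  c(nv, length(times), ntr))
  post <- times >= 80 & times <= 120
  trials[7, post, ] <- trials[7, post, ] + 10   # 10-SD deterministic shift
  src <- make_src(trials, times)
  mask <- permutation_mask(src, permutation_config(n_permutations = 200),
                           seed = 1)
  hit <- mask$times_ms >= 80 & mask$times_ms <= 120
  expect_true(all(mask$mask[7, hit] == 1))
  expect_lt(mean(mask$mask[-7, ]), 0.01)
})

test_that("alpha limits give all-ones and all-zeros masks", {
  set.seed(7)
  nv <- 10; ntr <- 12
  times <- seq(-500, 500, by = 10)
  trials <- array(abs(rnorm(nv * length(times) * ntr)),
                  c(nv, length(times), ntr))
  src <- make_src(trials, times)
  m1 <- permutation_mask(src, permutation_config(
    n_permutations = 100, alpha = 1, exclude_window_ms = NULL), seed = 1)
  expect_true(all(m1$mask == 1))
  m0 <- permutation_mask(src, permutation_config(
    n_permutations = 100, alpha = 0.001), seed = 1)
  expect_true(all(m0$mask == 0))
})

test_that("permutation preconditions are enforced", {
  times <- seq(-500, 500, by = 10)
  trials <- array(1, c(3, length(times), 5))
  src <- make_src(trials, times)
  expect_error(permutation_mask(src, permutation_config(n_permutations = 50)),
               "at least 100")
  short <- make_src(array(1, c(3, 30, 5)), seq(-90, 500, length.out = 30))
  expect_error(permutation_mask(short, permutation_config()),
               "fewer samples")
  one_tr <- make_src(array(1, c(3, length(times), 1)), times)
  expect_error(permutation_mask(one_tr, permutation_config()), "2 trials")
})

test_that("masks are reproducible under a fixed seed", {
  set.seed(9)
  trials <- array(abs(rnorm(20 * 101 * 10)), c(20, 101, 10))
  times <- seq(-500, 500, by = 10)
  src <- make_src(trials, times)
  m1 <- permutation_mask(src, permutation_config(n_permutations = 150),
                         seed = 3)
  m2 <- permutation_mask(src, permutation_config(n_permutations = 150),
                         seed = 3)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$threshold, m2$threshold)
})

test_that("scs_voxel matches a triple-loop brute force", {
  grid <- build_grid(fix_head, 28)
  nv <- nrow(grid$positions)
  stim <- stimulation_target()
  for (s in 1:10) {
    set.seed(s)
    nt <- 20
    times <- seq(30, 30 + 5 * (nt - 1), by = 5)
    use_v <- seq_len(min(50, nv))
    ss <- matrix(abs(rnorm(length(use_v) * nt)), length(use_v), nt)
    msk <- matrix(rbinom(length(use_v) * nt, 1, 0.3), length(use_v), nt)
    sub_grid <- structure(list(
      positions = grid$positions[use_v, , drop = FALSE],
      spacing = grid$spacing, head = grid$head), class = "source_grid")
    src <- structure(list(strength = ss, trials = NULL, times_ms = times,
                          grid = sub_grid), class = "source_activation")
    mask <- structure(list(mask = msk, times_ms = times, threshold = 0,
                           alpha = 0.05), class = "significance_mask")
    field <- scs_voxel(src, mask, sub_grid, stim)

    sv <- nearest_voxel(sub_grid, stim$mni_mm)
    brute <- matrix(0, length(use_v), nt)
    for (x in seq_along(use_v)) {
      for (tt in seq_len(nt)) {
        dd <- sqrt(sum((sub_grid$positions[x, ] -
                          sub_grid$positions[sv, ])^2))
        brute[x, tt] <- ss[x, tt] * msk[x, tt] * dd
      }
    }
    expect_equal(field$scs, brute, tolerance = 1e-12)

    # ROI sums: random disjoint partition adds up to the whole-brain sum
    labels <- sample(rep_len(c("A", "B", "C"), length(use_v)))
    atlas <- structure(list(
      voxels = split(seq_along(use_v), labels),
      network = c(A = "x", B = "y", C = "z"), grid = sub_grid),
      class = "roi_atlas")
    roi <- scs_roi(field, atlas, window = range(times))
    expect_equal(sum(roi$scs), sum(brute), tolerance = 1e-9)

    # brute-force one ROI over a sub-window
    wsel <- times >= 50 & times <= 80
    roi2 <- scs_roi(field, atlas, window = c(50, 80))
    expect_equal(roi2$scs[roi2$roi == "B"],
                 sum(brute[atlas$voxels$B, wsel]), tolerance = 1e-9)
  }
})

test_that("SCS vanishes with an empty mask and at the stimulation voxel", {
  grid <- build_grid(fix_head, 28)
  nv <- nrow(grid$positions)
  times <- seq(30, 120, by = 10)
  ss <- matrix(1, nv, length(times))
  src <- structure(list(strength = ss, times_ms = times, grid = grid),
                   class = "source_activation")
  zero <- structure(list(mask = ss * 0, times_ms = times, threshold = 0,
                         alpha = 0.05), class = "significance_mask")
  expect_true(all(scs_voxel(src, zero, grid)$scs == 0))

  ones <- structure(list(mask = ss * 0 + 1, times_ms = times, threshold = 0,
                         alpha = 0.05), class = "significance_mask")
  field <- scs_voxel(src, ones, grid)
  expect_equal(field$scs[field$stim_voxel, ], rep(0, length(times)))
  # monotone in ss and in mask inclusion
  src2 <- src; src2$strength <- ss * 2
  expect_true(all(scs_voxel(src2, ones, grid)$scs >= field$scs))
})

test_that("atlas fixtures capture the right voxels", {
  grid <- build_grid(fix_head, 12)
  # a tiny radius captures at most the single nearest voxel
  spec1 <- data.frame(roi = "tiny", network = "t",
                      x_mm = grid$positions[40, 1] + 1,
                      y_mm = grid$positions[40, 2],
                      z_mm = grid$positions[40, 3], radius_mm = 1.5)
  at <- build_atlas_fixture(grid, spec1, min_radius_mm = 0)
  expect_lte(length(at$voxels$tiny), 1)

  # identical rows give identical voxel sets
  spec2 <- data.frame(roi = c("a", "b"), network = "n",
                      x_mm = -10, y_mm = 0, z_mm = 30, radius_mm = 15)
  at2 <- build_atlas_fixture(grid, spec2)
  expect_identical(at2$voxels$a, at2$voxels$b)

  # voxel count of an interior sphere ~ volume / spacing^3 (+/- 30%)
  spec3 <- data.frame(roi = "ball", network = "n",
                      x_mm = 0, y_mm = -18, z_mm = 15, radius_mm = 30)
  at3 <- build_atlas_fixture(grid, spec3)
  expected <- 4 / 3 * pi * 30^3 / 12^3
  expect_gt(length(at3$voxels$ball), expected * 0.7)
  expect_lt(length(at3$voxels$ball), expected * 1.3)

  # an ROI outside the head captures nothing, with a warning
  spec4 <- data.frame(roi = "out", network = "n",
                      x_mm = 500, y_mm = 0, z_mm = 0, radius_mm = 5)
  expect_warning(at4 <- build_atlas_fixture(grid, spec4, min_radius_mm = 0),
                 "no grid voxels")
  times <- seq(30, 120, by = 10)
  ss <- matrix(1, nrow(grid$positions), length(times))
  src <- structure(list(strength = ss, times_ms = times, grid = grid),
                   class = "source_activation")
  ones <- structure(list(mask = ss * 0 + 1, times_ms = times, threshold = 0,
                         alpha = 0.05), class = "significance_mask")
  field <- scs_voxel(src, ones, grid)
  expect_warning(roi_out <- scs_roi(field, at4, c(30, 120)), "empty")
  expect_equal(roi_out$scs, 0)

  # the bundled node table pools left and right labels into 8 nodes
  at5 <- build_atlas_fixture(build_grid(fix_head, 16))
  expect_setequal(names(at5$voxels),
                  c("mPFC", "PCC", "angular", "DLPFC", "PPC", "ACC",
                    "insula", "amygdala"))
})
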