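# Synthetic phantom generator: size mixture, rendering, perturbation,
# cohort determinism.

test_that("sampled diameters follow the stratum mixture within a binomial 99% CI", {
  cfg <- phantom_config(shape = 96, n_lesions = 1, d_max = 12,
                        size_mixture = c(0.2573, 0.4092, 0.3335))
  set.seed(123)
  diams <- replicate(1000, sample_lesions(cfg)[[1]]$target_diameter)
  counts <- c(small = sum(diams < 3), medium = sum(diams >= 3 & diams <= 6),
              large = sum(diams > 6))
  probs <- c(0.2573, 0.4092, 0.3335)
  for (k in 1:3) {
    ci <- qbinom(c(0.005, 0.995), 1000, probs[k])
    expect_gte(counts[k], ci[1])
    expect_lte(counts[k], ci[2])
  }
})

test_that("degenerate mixtures put every lesion in the chosen stratum", {
  cfg <- phantom_config(shape = 64, n_lesions = 3, size_mixture = c(1, 0, 0))
  set.seed(1)
  specs <- sample_lesions(cfg)
  expect_true(all(vapply(specs, `[[`, numeric(1), "target_diameter") < 3))
  cfg2 <- phantom_config(shape = 64, n_lesions = 3, size_mixture = c(0, 0, 1))
  set.seed(1)
  specs2 <- sample_lesions(cfg2)
  expect_true(all(vapply(specs2, `[[`, numeric(1), "target_diameter") > 6))
})

test_that("lesion sampling is deterministic given the seed and lesions stay inside", {
  cfg <- phantom_config(shape = 48, n_lesions = 5, d_max = 10)
  s1 <- sample_lesions(cfg, seed = 42)
  s2 <- sample_lesions(cfg, seed = 42)
  expect_identical(s1, s2)
  for (sp in s1) {
    expect_true(all(sp$semi_axes > 0))
    expect_equal(2 * max(sp$semi_axes), sp$target_diameter, tolerance = 1e-9)
    expect_true(all(sp$center - max(sp$semi_axes) >= 0))
    expect_true(all(sp$center + max(sp$semi_axes) <= 48))
  }
})

test_that("placement failure in an overfull volume signals an error", {
  cfg <- phantom_config(shape = 16, n_lesions = 40, d_max = 8,
                        size_mixture = c(0, 0, 1))
  set.seed(3)
  expect_error(sample_lesions(cfg), "volume too small")
})

test_that("rendering: empty spec list gives an all-zero mask, noiseless background is flat", {
  cfg <- phantom_config(shape = 24, noise_sd = 0)
  ph <- render_phantom(list(), cfg)
  expect_true(all(ph$mask == 0))
  expect_true(all(ph$image == cfg$bg_level))
  # with lesions, voxels outside the mask keep the background level
  set.seed(4)
  cfg2 <- phantom_config(shape = 24, noise_sd = 0, n_lesions = 2, d_max = 8)
  specs <- sample_lesions(cfg2)
  ph2 <- render_phantom(specs, cfg2)
  expect_true(all(ph2$image[ph2$mask == 0] == cfg2$bg_level))
  expect_true(all(ph2$image[ph2$mask == 1] > cfg2$bg_level))
})

test_that("a 4 mm sphere voxelizes into the medium stratum as measured by the evaluation oracle", {
  cfg <- phantom_config(shape = 24, noise_sd = 0)
  spec <- list(center = c(12, 12, 12), semi_axes = c(2, 2, 2),
               rotation = diag(3), contrast = 0.5, target_diameter = 4,
               stratum = "medium")
  ph <- render_phantom(list(spec), cfg)
  comps <- extract_components(ph$mask, cfg$spacing)
  expect_length(comps, 1)
  expect_true(comps[[1]]$longest_axis_mm >= 3 && comps[[1]]$longest_axis_mm <= 6)
  expect_equal(as.character(size_stratum(comps[[1]]$longest_axis_mm)), "medium")
})

test_that("rendered lesions land in their spec's stratum when at least 2 voxels across", {
  cfg <- phantom_config(shape = 48, n_lesions = 3, d_max = 10, noise_sd = 0)
  set.seed(6)
  specs <- sample_lesions(cfg)
  ph <- render_phantom(specs, cfg)
  comps <- extract_components(ph$mask, cfg$spacing)
  want <- vapply(specs, `[[`, character(1), "stratum")
  # match rendered components to specs by center proximity
  for (ci in comps) {
    ctr <- colMeans(ci$voxels) - 0.5
    di <- which.min(vapply(specs, function(s) sum((s$center - ctr)^2), numeric(1)))
    if (specs[[di]]$target_diameter >= 2)
      expect_equal(as.character(size_stratum(ci$longest_axis_mm)), want[di])
  }
})

test_that("perturbation realizes requested coverage fractions and drops/spurious counts", {
  gt <- array(0, c(24, 24, 24))
  gt[3:6, 3:6, 3:6] <- 1       # 64 voxels
  gt[15:16, 15:16, 15:16] <- 1 # 8 voxels
  # keep all -> identical
  expect_identical(perturb_prediction(gt, list(actions = c("keep", "keep"))), gt)
  # drop the second lesion
  p2 <- perturb_prediction(gt, list(actions = c("keep", "drop")))
  expect_equal(sum(p2[15:16, 15:16, 15:16]), 0)
  expect_equal(sum(p2), 64)
  # erode the 64-voxel lesion to coverage 0.5: 32 +/- 1 overlapping voxels
  p3 <- perturb_prediction(gt, list(actions = list(list(action = "erode", coverage = 0.5),
                                                   "drop")))
  expect_lte(abs(sum(p3 * gt) - 32), 1)
  # spurious blobs are disjoint from GT
  p4 <- perturb_prediction(gt, list(actions = c("keep", "keep"), n_spurious = 2),
                           seed = 9)
  expect_true(all(gt[p4 != gt] == 0))
  expect_length(extract_components(p4), 4)
  # unreachable coverage errors
  expect_error(perturb_prediction(gt, list(actions = list("keep",
                                  list(action = "erode", coverage = 0.01)))),
               "unreachable coverage")
})

test_that("cohort generation round-trips through NIfTI and is reproducible", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  cfg <- phantom_config(shape = 24, n_lesions = 2, d_max = 8, seed = 5)
  m1 <- generate_cohort(cfg, 2, dir1)
  m2 <- generate_cohort(cfg, 2, dir2)
  expect_length(m1$patients, 2)
  c1 <- load_cohort(m1); c2 <- load_cohort(m2)
  for (i in 1:2) {
    expect_identical(c1[[i]]$mask, c2[[i]]$mask)
    expect_equal(c1[[i]]$image, c2[[i]]$image, tolerance = 1e-6)
    expect_equal(c1[[i]]$spacing, c(1, 1, 1))
  }
  # manifest file loads too
  c3 <- load_cohort(file.path(dir1, "manifest.json"))
  expect_identical(c3[[1]]$mask, c1[[1]]$mask)
  unlink(c(dir1, dir2), recursive = TRUE)
})
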