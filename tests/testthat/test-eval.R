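# Lesion-wise evaluation protocol: closing, components, diameters,
# coverage matching and the metric reports.

test_that("closing fills a 1-voxel gap, leaves solids unchanged, and is idempotent", {
  m <- array(0, c(12, 12, 12))
  m[4, 4, 4] <- 1; m[6, 4, 4] <- 1  # gap at x = 5
  cl <- close_mask(m, c(1, 1, 1), radius_mm = 1)
  expect_length(extract_components(cl), 1)
  expect_equal(cl[5, 4, 4], 1)
  expect_identical(close_mask(cl, c(1, 1, 1)), cl)
  cube <- box_mask(12, c(4, 4, 4), c(8, 8, 8))
  expect_identical(close_mask(cube, c(1, 1, 1)), cube)
  zero <- array(0, c(6, 6, 6))
  expect_identical(close_mask(zero, c(1, 1, 1)), zero)
})

test_that("anisotropic spacing scales the closing kernel per axis", {
  m <- array(0, c(12, 12, 12))
  m[4, 4, 4] <- 1; m[4, 4, 6] <- 1
  # 2 mm slices: a 1 mm kernel still uses the minimum 1-voxel radius
  cl <- close_mask(m, c(1, 1, 2), radius_mm = 1)
  expect_length(extract_components(cl), 1)
})

test_that("corner-touching voxels form one 26-connected component but two 6-connected ones", {
  m <- array(0, c(8, 8, 8))
  m[3, 3, 3] <- 1; m[4, 4, 4] <- 1
  expect_length(extract_components(m, connectivity = 26), 1)
  expect_length(extract_components(m, connectivity = 6), 2)
  expect_length(extract_components(array(0, c(8, 8, 8))), 0)
})

test_that("longest axis is the max pairwise voxel-center distance in mm", {
  m <- array(0, c(8, 8, 8)); m[2, 2, 2] <- 1
  comp <- extract_components(m)[[1]]
  expect_equal(comp$longest_axis_mm, 0)
  expect_equal(as.character(size_stratum(0)), "small")
  m2 <- array(0, c(8, 8, 8)); m2[2, 2, 2:6] <- 1
  comp2 <- extract_components(m2)[[1]]
  expect_equal(comp2$longest_axis_mm, 4)
  expect_equal(as.character(size_stratum(4)), "medium")
  # axis permutation invariance on an isotropic grid
  m3 <- array(0, c(8, 8, 8)); m3[2:6, 2, 2] <- 1
  expect_equal(extract_components(m3)[[1]]$longest_axis_mm, 4)
  # surface-voxel shortcut agrees with the full set on a big component
  big <- box_mask(16, c(2, 2, 2), c(13, 13, 13))
  expect_equal(extract_components(big)[[1]]$longest_axis_mm, sqrt(3) * 11,
               tolerance = 1e-9)
})

test_that("stratum boundaries are [0,3), [3,6], (6, inf)", {
  expect_equal(as.character(size_stratum(c(0, 2.99, 3, 4.5, 6, 6.01, 10))),
               c("small", "small", "medium", "medium", "medium", "large", "large"))
})

test_that("coverage is the covered fraction of the GT component", {
  a <- box_mask(12, c(2, 2, 2), c(3, 3, 3))       # 8 voxels
  b <- box_mask(12, c(2, 2, 2), c(3, 3, 2))       # covers 4 of them
  ca <- extract_components(a)[[1]]
  cb <- extract_components(b)[[1]]
  expect_equal(coverage(ca, ca), 1)
  expect_equal(coverage(cb, ca), 0.5)
  disj <- extract_components(box_mask(12, c(8, 8, 8), c(9, 9, 9)))[[1]]
  expect_equal(coverage(disj, ca), 0)
})

test_that("the hand-built 5-lesion fixture yields TP=3 FN=2 FP=2, sensitivity = precision = 0.6", {
  gt <- array(0, c(32, 32, 32))
  centers <- list(c(3, 3, 3), c(3, 3, 20), c(3, 20, 3), c(20, 3, 3), c(20, 20, 20))
  for (ct in centers)
    gt[ct[1]:(ct[1] + 1), ct[2]:(ct[2] + 1), ct[3]:(ct[3] + 1)] <- 1  # 8 voxels each
  plan <- list(actions = list("keep",                                   # CV 1.0
                              list(action = "erode", coverage = 0.625), # CV 0.625
                              list(action = "erode", coverage = 0.5),   # CV 0.5
                              "drop", "drop"),
               n_spurious = 2)
  pred <- perturb_prediction(gt, plan, seed = 11)
  rec <- evaluate_masks(pred, gt, close = FALSE)
  m <- rec$match
  expect_equal(m$tp, 3); expect_equal(m$fn, 2); expect_equal(m$fp, 2)
  expect_equal(sort(round(m$pairs$cv, 3)), c(0.5, 0.625, 1))
  expect_equal(m$tp / (m$tp + m$fn), 0.6)
  expect_equal(m$tp / (m$tp + m$fp), 0.6)
})

test_that("CV exactly at 0.5 is a TP while 0.49 becomes FP plus FN", {
  gt <- array(0, c(16, 16, 16))
  gt[3:7, 3:6, 3:7] <- 1  # 100 voxels
  pred <- array(0, c(16, 16, 16))
  pred[3:7, 3:6, 3:4] <- 1; pred[3:7, 3:4, 5] <- 1  # 50 overlapping voxels
  m1 <- match_lesions(extract_components(pred), extract_components(gt))
  expect_equal(m1$tp, 1); expect_equal(m1$fp, 0); expect_equal(m1$fn, 0)
  expect_equal(m1$pairs$cv, 0.5)
  pred[3, 3, 5] <- 0  # 49 overlapping voxels
  m2 <- match_lesions(extract_components(pred), extract_components(gt))
  expect_equal(m2$tp, 0); expect_equal(m2$fp, 1); expect_equal(m2$fn, 1)
})

test_that("greedy matching agrees with exhaustive optimal assignment on small instances", {
  set.seed(13)
  for (rep in 1:25) {
    np <- sample(1:4, 1); ng <- sample(1:4, 1)
    # random coverage matrix with plausible structure
    cv <- matrix(0, np, ng)
    for (i in seq_len(np)) {
      j <- sample(ng, 1)
      cv[i, j] <- runif(1, 0.3, 1)
      if (runif(1) < 0.3) cv[i, sample(ng, 1)] <- runif(1, 0.3, 0.9)
    }
    # synthesize component lists whose coverage() reproduces cv:
    # give each GT 100 private voxel slots; predictions overlap them
    gt_comps <- lapply(seq_len(ng), function(j)
      list(id = j, lin_idx = (j - 1) * 1000 + 1:100,
           voxels = cbind(1:100, j, 1), longest_axis_mm = 5))
    pred_comps <- lapply(seq_len(np), function(i) {
      lin <- unlist(lapply(seq_len(ng), function(j) {
        k <- round(cv[i, j] * 100)
        if (k > 0) (j - 1) * 1000 + 1:k else integer(0)
      }))
      if (!length(lin)) lin <- 1e6 + i
      list(id = i, lin_idx = lin, voxels = cbind(seq_along(lin), i, 2),
           longest_axis_mm = 5)
    })
    m <- match_lesions(pred_comps, gt_comps)
    # recompute the coverage matrix the matcher saw (overlaps interact)
    cvm <- matrix(0, np, ng)
    for (i in seq_len(np)) for (j in seq_len(ng))
      cvm[i, j] <- coverage(pred_comps[[i]], gt_comps[[j]])
    opt <- match_bruteforce(cvm, 0.5)
    expect_equal(m$tp, opt$n)
  }
})

test_that("per-lesion Dice excludes small GT lesions and matches arithmetic", {
  gt <- array(0, c(24, 24, 24))
  gt[2:6, 2:5, 2] <- 1      # 20 voxels, 5 mm long -> included
  gt[14:15, 14, 14] <- 1    # 2 voxels, 1 mm -> excluded (< 3 mm)
  pred <- array(0, c(24, 24, 24))
  pred[2:6, 2:5, 2] <- 1; pred[2:6, 2:3, 3] <- 1  # A = 30, overlap = 20
  pred[14:15, 14, 14] <- 1
  pc <- extract_components(pred); gc_ <- extract_components(gt)
  m <- match_lesions(pc, gc_)
  expect_equal(m$tp, 2)
  dcs <- dice_per_lesion(m, pc, gc_)
  expect_equal(nrow(dcs), 1)  # the 2-voxel lesion is excluded
  expect_equal(dcs$dice, 2 * 20 / (30 + 20))
  # identical pair scores 1
  mm <- match_lesions(gc_, gc_)
  expect_true(all(dice_per_lesion(mm, gc_, gc_)$dice == 1))
})

test_that("counts are conserved and spurious additions never help precision", {
  set.seed(14)
  cfg <- phantom_config(shape = 32, n_lesions = 3, d_max = 8, seed = 2)
  specs <- sample_lesions(cfg, seed = 21)
  gt <- render_phantom(specs, cfg)$mask
  pred <- perturb_prediction(gt, list(actions = c("keep", "drop", "keep")), seed = 3)
  rec <- evaluate_masks(pred, gt, close = FALSE)
  expect_equal(rec$match$tp + rec$match$fn, length(rec$gt_comps))
  expect_equal(rec$match$tp + rec$match$fp, length(rec$pred_comps))
  pred2 <- perturb_prediction(gt, list(actions = c("keep", "drop", "keep"),
                                       n_spurious = 2), seed = 3)
  rec2 <- evaluate_masks(pred2, gt, close = FALSE)
  r1 <- lesion_level_report(list(rec)); r2 <- lesion_level_report(list(rec2))
  expect_lte(r2$precision, r1$precision)
  expect_equal(r2$sensitivity, r1$sensitivity)
})

test_that("reports pool correctly and leave empty strata undefined", {
  gt <- array(0, c(32, 32, 32))
  gt[4:8, 4:5, 4:5] <- 1       # longest axis sqrt(16+1+1) = 4.24 mm: medium
  gt[20, 20, 20] <- 1          # single-voxel small lesion
  pred <- perturb_prediction(gt, list(actions = c("keep", "drop")))
  rec <- evaluate_masks(pred, gt, close = FALSE)
  rep_l <- lesion_level_report(list(rec))
  expect_equal(unname(rep_l$sensitivity_by_stratum["medium"]), 1)
  expect_equal(unname(rep_l$sensitivity_by_stratum["small"]), 0)
  expect_true(is.na(rep_l$sensitivity_by_stratum["large"]))  # no large lesions
  expect_equal(rep_l$sensitivity, 0.5)
  expect_equal(rep_l$precision, 1)
  rep_p <- patient_level_report(list(rec, rec))
  expect_equal(unname(rep_p$sensitivity["mean"]), 0.5)
  expect_equal(unname(rep_p$sensitivity["sd"]), 0)
  expect_equal(rep_p$n_patients, 2)
})
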