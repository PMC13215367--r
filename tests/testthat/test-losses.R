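# Dice / cross-entropy / patch-focal losses against closed forms and
# loop oracles.

test_that("dice loss matches direct arithmetic and its fixed points", {
  gt <- box_mask(8, c(1, 1, 1), c(2, 2, 2))
  expect_equal(dice_loss(gt, gt), 0, tolerance = 1e-6)
  disj <- box_mask(8, c(5, 5, 5), c(6, 6, 6))
  expect_equal(dice_loss(disj, gt), 1 - 1e-5 / (16 + 1e-5), tolerance = 1e-12)
  # uniform 0.5 prediction over a 4^3 volume with 8 GT voxels
  pred <- array(0.5, c(4, 4, 4))
  gt2 <- box_mask(4, c(1, 1, 1), c(2, 2, 2))
  eps <- 1e-5
  expected <- 1 - (2 * sum(pred * gt2) + eps) / (sum(pred) + sum(gt2) + eps)
  expect_equal(dice_loss(pred, gt2, eps), expected, tolerance = 1e-12)
  expect_error(dice_loss(array(0.5, c(4, 4, 4)), box_mask(8, c(1, 1, 1), c(1, 1, 1))),
               "shape mismatch")
})

test_that("cross-entropy equals -mean log p(correct), ln 2 at p = 0.5, 0 at p = 1", {
  gt <- box_mask(4, c(1, 1, 1), c(2, 2, 2))
  perfect <- gt
  expect_equal(ce_loss(perfect, gt), 0, tolerance = 1e-5)
  half <- array(0.5, c(4, 4, 4))
  expect_equal(ce_loss(half, gt), log(2), tolerance = 1e-9)
  # permutation invariance
  set.seed(1)
  p <- array(runif(64), c(4, 4, 4))
  perm <- sample(64)
  p2 <- array(as.numeric(p)[perm], c(4, 4, 4))
  g2 <- array(as.numeric(gt)[perm], c(4, 4, 4))
  expect_equal(ce_loss(p, gt), ce_loss(p2, g2), tolerance = 1e-12)
  # 4D class-probability input agrees with the foreground-only form
  p4 <- array(c(1 - p, p), c(4, 4, 4, 2))
  expect_equal(ce_loss(p4, gt), ce_loss(p, gt), tolerance = 1e-12)
})

test_that("patch labels flag any patch containing a lesion voxel", {
  m <- array(0, c(16, 16, 16))
  m[1, 1, 1] <- 1
  y <- patch_labels(m, 8)
  expect_equal(as.numeric(y), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(patch_labels(array(0, c(16, 16, 16)), 8)), rep(0, 8))
  expect_equal(as.numeric(patch_labels(array(1, c(16, 16, 16)), 8)), rep(1, 8))
  expect_error(patch_labels(array(0, c(12, 12, 12)), 8), "does not divide")
})

test_that("patch probabilities aggregate by max and are monotone", {
  p <- array(0.3, c(16, 16, 16))
  expect_equal(as.numeric(patch_probs(p, 8)), rep(0.3, 8))
  p2 <- array(0, c(16, 16, 16)); p2[3, 3, 3] <- 0.9
  q2 <- patch_probs(p2, 8)
  expect_equal(as.numeric(q2), c(0.9, rep(0, 7)))
  # raising any voxel never lowers any patch probability
  set.seed(2)
  pr <- array(runif(16^3), c(16, 16, 16))
  q0 <- patch_probs(pr, 8)
  for (i in sample(16^3, 5)) {
    pr2 <- pr; pr2[i] <- min(1, pr2[i] + 0.3)
    expect_true(all(patch_probs(pr2, 8) >= q0 - 1e-12))
  }
})

test_that("focal loss matches direct scalar evaluation on single patches", {
  # y = 1, q = 0.5, gamma = 0.5: (1 - 0.5)^0.5 * (-log 0.5)
  y <- array(1, c(1, 1, 1)); q <- array(0.5, c(1, 1, 1))
  expect_equal(lrp_loss(y, q, gamma = 0.5), sqrt(0.5) * log(2), tolerance = 1e-9)
  expect_equal(lrp_loss(y, q, gamma = 0.5), 0.4901, tolerance = 1e-4)
  # y = 0, q = 0.2: 0.2^0.5 * (-log 0.8)
  y0 <- array(0, c(1, 1, 1)); q0 <- array(0.2, c(1, 1, 1))
  expect_equal(lrp_loss(y0, q0, gamma = 0.5), sqrt(0.2) * (-log(0.8)), tolerance = 1e-9)
  expect_equal(lrp_loss(y0, q0, gamma = 0.5), 0.0998, tolerance = 1e-4)
  # perfect predictions give zero loss (up to the probability clamp)
  expect_equal(lrp_loss(y, array(1, c(1, 1, 1)), 0.5), 0, tolerance = 1e-3)
  # the one-sided printed form ignores negative patches entirely
  expect_equal(lrp_loss(y0, q0, gamma = 0.5, two_sided = FALSE), 0, tolerance = 1e-12)
  expect_error(lrp_loss(y, q, gamma = -1), "gamma")
})

test_that("focal loss strictly decreases in q for positive patches", {
  y <- array(1, c(1, 1, 1))
  qs <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(qs, function(q) lrp_loss(y, array(q, c(1, 1, 1)), 0.5), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("vectorized focal loss equals the naive per-patch loop on random volumes", {
  set.seed(7)
  for (rep in 1:20) {
    pred <- array(runif(16^3), c(16, 16, 16))
    gt <- array(rbinom(16^3, 1, 0.1), c(16, 16, 16))
    y <- patch_labels(gt, 8)
    q <- patch_probs(pred, 8)
    expect_equal(lrp_loss(y, q, 0.5), lrp_bruteforce(y, q, 0.5), tolerance = 1e-6)
    expect_equal(lrp_loss(y, q, 2, two_sided = FALSE),
                 lrp_bruteforce(y, q, 2, two_sided = FALSE), tolerance = 1e-6)
  }
})

test_that("composite loss hits its endpoints and is affine in w", {
  set.seed(8)
  pred <- array(runif(16^3, 0.01, 0.99), c(16, 16, 16))
  gt <- array(0, c(16, 16, 16)); gt[4:6, 4:6, 4:6] <- 1
  l0 <- composite_loss(pred, gt, loss_config(w = 0))
  expect_equal(l0, dice_loss(pred, gt) + ce_loss(pred, gt), tolerance = 1e-12)
  l1 <- composite_loss(pred, gt, loss_config(w = 1))
  y <- patch_labels(gt, 8); q <- patch_probs(pred, 8)
  expect_equal(l1, dice_loss(pred, gt) + lrp_loss(y, q, 0.5), tolerance = 1e-12)
  lm <- composite_loss(pred, gt, loss_config(w = 0.5))
  expect_equal(lm, (l0 + l1) / 2, tolerance = 1e-10)
})

test_that("composite loss gradient matches finite differences at single voxels", {
  set.seed(9)
  pred <- array(runif(16^3, 0.05, 0.95), c(16, 16, 16))
  gt <- array(0, c(16, 16, 16)); gt[2:4, 2:4, 2:4] <- 1
  cfg <- loss_config(w = 0.4)
  pn <- ag_var(pred)
  ag_backward(composite_loss(pn, gt, cfg))
  f <- function(p) composite_loss(p, gt, cfg)
  for (i in c(which(gt == 1)[1], which(gt == 0)[5], 2000)) {
    fd <- fdiff(f, pred, i)
    expect_equal(ag_grad(pn)[i], fd, tolerance = 1e-3 * max(1, abs(fd)))
  }
})

test_that("all loss terms are non-negative after clamping", {
  set.seed(10)
  for (rep in 1:5) {
    pred <- array(runif(8^3), c(8, 8, 8))
    gt <- array(rbinom(8^3, 1, 0.2), c(8, 8, 8))
    expect_gte(dice_loss(pred, gt), 0)
    expect_gte(ce_loss(pred, gt), 0)
    expect_gte(lrp_loss(patch_labels(gt, 4), patch_probs(pred, 4), 0.5), 0)
  }
})
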