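# Contrastive latent pretraining: mask subsampling, the InfoNCE loss
# against the literal triple-loop oracle, separation score, t-SNE.

test_that("mask subsampling is max-pooling onto the 512-cell token grid", {
  expect_equal(subsample_mask(array(0, c(16, 16, 16))), rep(0, 512))
  m <- array(0, c(16, 16, 16))
  m[3, 3, 3] <- 1  # cell (2,2,2) -> index 1 + 1 + 8 + 64
  s <- subsample_mask(m)
  expect_equal(length(s), 512)
  expect_equal(which(s == 1), 1 + 1 + 8 + 64)
  # any single voxel in a cell flags that cell
  m2 <- array(0, c(64, 64, 64))
  m2[64, 64, 64] <- 1
  expect_equal(which(subsample_mask(m2) == 1), 512)
  expect_error(subsample_mask(array(0, c(12, 12, 12))), "not divisible")
})

test_that("single positive pair gives zero attraction; equal negatives give log(1/2) each", {
  # one anchor and one other positive: denominator has one element
  z <- matrix(0, 2, 3)
  z[, 1] <- c(1, 0); z[, 2] <- c(1, 0); z[, 3] <- c(0, 1)
  m <- c(1, 1, 0)
  cfg <- clp_config(max_anchors = 512, max_negatives = 512)
  # attraction terms are exactly 0 (ratio 1); repulsion has one negative
  # per anchor: log(exp(s)/exp(s)) = 0, so the whole loss is 0
  expect_equal(clp_loss(z, m, cfg), 0, tolerance = 1e-9)
  # one anchor, two orthogonal negatives with equal similarity:
  # each repulsion term is log(1/2)
  z2 <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m2 <- c(1, 0, 0)
  expect_equal(clp_loss(z2, m2, cfg), 2 * log(0.5), tolerance = 1e-9)
})

test_that("stabilized loss equals the literal triple-loop oracle on random latent fields", {
  set.seed(31)
  cfg <- clp_config(max_anchors = 512, max_negatives = 512)
  for (case in list(c(d = 4, L = 27), c(d = 8, L = 64))) {
    for (rep in 1:3) {
      z <- matrix(rnorm(case["d"] * case["L"]), case["d"], case["L"])
      m <- rbinom(case["L"], 1, 0.3)
      if (sum(m) < 2 || sum(m) == case["L"]) m[1:2] <- c(1, 0)
      expect_equal(clp_loss(z, m, cfg), clp_bruteforce(z, m), tolerance = 1e-5)
      # unnormalized-similarity variant (clamped only far outside this range)
      cfg_raw <- clp_config(max_anchors = 512, max_negatives = 512,
                            normalize_tokens = FALSE)
      expect_equal(clp_loss(z * 0.3, m, cfg_raw),
                   clp_bruteforce(z * 0.3, m, normalize = FALSE), tolerance = 1e-4)
    }
  }
})

test_that("loss is invariant to permuting tokens together with the mask", {
  set.seed(32)
  z <- matrix(rnorm(4 * 30), 4, 30)
  m <- c(rep(1, 6), rep(0, 24))
  cfg <- clp_config(max_anchors = 512, max_negatives = 512)
  l0 <- clp_loss(z, m, cfg)
  for (rep in 1:3) {
    pm <- sample(30)
    expect_equal(clp_loss(z[, pm], m[pm], cfg), l0, tolerance = 1e-9)
  }
})

test_that("volumes with a single class contribute no loss and errors are raised on bad input", {
  cfg <- clp_config()
  expect_true(is.na(clp_loss(matrix(rnorm(40), 4, 10), rep(0, 10), cfg)))
  expect_true(is.na(clp_loss(matrix(rnorm(40), 4, 10), rep(1, 10), cfg)))
  zbad <- matrix(rnorm(40), 4, 10); zbad[2, 2] <- NaN
  expect_error(clp_loss(zbad, c(1, rep(0, 9)), cfg), "non-finite")
})

test_that("separation score is 0 for identical clouds and ~10 for 10-SD-shifted Gaussians", {
  set.seed(33)
  base <- matrix(rnorm(8 * 400), 8, 400)
  m <- rep(c(1, 0), each = 200)
  expect_lt(separation_score(base, m), 0.5)
  shifted <- base
  shifted[1, m == 1] <- shifted[1, m == 1] + 10  # 10 SDs along one dim
  expect_equal(separation_score(shifted, m), 10, tolerance = 1.5)
  # invariant to a common affine rescaling
  expect_equal(separation_score(3 * shifted + 2, m),
               separation_score(shifted, m), tolerance = 1e-9)
  expect_error(separation_score(base, rep(1, 400)), "both classes")
})

test_that("pretraining decreases the contrastive loss and widens the similarity gap", {
  net <- tiny_net(seed = 6)
  cohort <- tiny_cohort(n = 3, seed = 9)
  gap <- function(net) {
    gaps <- vapply(cohort, function(p) {
      z <- extract_latent(net, p$image)
      m <- subsample_mask(p$mask)
      if (sum(m) == 0) return(NA_real_)
      tk <- t(z) / sqrt(colSums(z^2))
      s <- tk %*% t(tk)
      mean(s[m == 1, m == 1]) - mean(s[m == 1, m == 0])
    }, numeric(1))
    mean(gaps, na.rm = TRUE)
  }
  g0 <- gap(net)
  tc <- train_config(lr0 = 0.02, seed = 2)
  pretrain(net, cohort, clp_config(epochs = 8, lr = 0.02), tc)
  tr <- net$traces$pretrain
  expect_true(all(is.finite(tr$loss)))
  expect_lt(tr$loss[nrow(tr)], tr$loss[1])
  expect_gt(gap(net), g0)
  # determinism: same seed, same cohort, same final loss
  net2 <- tiny_net(seed = 6)
  set.seed(2); pretrain(net2, cohort, clp_config(epochs = 2, lr = 0.02), tc)
  net3 <- tiny_net(seed = 6)
  set.seed(2); pretrain(net3, cohort, clp_config(epochs = 2, lr = 0.02), tc)
  expect_identical(net2$traces$pretrain, net3$traces$pretrain)
  expect_identical(net2$params, net3$params)
})

test_that("pretraining on an unlesioned cohort errors", {
  net <- tiny_net()
  blank <- list(list(image = array(rnorm(16^3), c(16, 16, 16)),
                     mask = array(0, c(16, 16, 16)), spacing = c(1, 1, 1)))
  expect_error(pretrain(net, blank, clp_config(epochs = 1)), "no lesioned volume")
})

test_that("t-SNE embeds tokens in 2D deterministically with labels attached", {
  set.seed(34)
  z <- cbind(matrix(rnorm(5 * 30), 5, 30), matrix(rnorm(5 * 30, mean = 6), 5, 30))
  m <- rep(c(0, 1), each = 30)
  e1 <- tsne_embed(z, m, seed = 3, n_iter = 120)
  e2 <- tsne_embed(z, m, seed = 3, n_iter = 120)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 60)
  expect_equal(e1$label, m)
  # well-separated clusters stay separated in the embedding
  d01 <- sqrt(sum((colMeans(e1[e1$label == 1, 1:2]) -
                   colMeans(e1[e1$label == 0, 1:2]))^2))
  within <- mean(c(sd(e1$x[e1$label == 0]), sd(e1$x[e1$label == 1])))
  expect_gt(d01, within)
  expect_error(tsne_embed(matrix(1, 4, 20), rep(0:1, 10), seed = 1), "degenerate")
  expect_error(tsne_embed(matrix(rnorm(8), 2, 4), c(1, 0, 1, 0), seed = 1), "at least 10")
})
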