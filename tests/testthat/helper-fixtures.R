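# Shared fixtures: all tiny, generated in code.

# smallest legal network input: 16^3 -> one stride-2 stage -> 8^3 tokens
tiny_net_config <- function(...) {
  net_config(input_shape = 16L, base_channels = 2L, vit_layers = 1L,
             vit_dim = 4L, vit_heads = 2L, ...)
}

tiny_net <- function(seed = 1L, ...) build_network(tiny_net_config(...), seed = seed)

# a 16^3 phantom cohort with one small bright lesion each
tiny_cohort <- function(n = 3L, seed = 1L, shape = 16L, n_lesions = 1L) {
  cfg <- phantom_config(shape = shape, n_lesions = n_lesions, d_max = 6,
                        size_mixture = c(0.5, 0.5, 0),
                        noise_sd = 2, seed = seed)
  lapply(seq_len(n), function(i) {
    set.seed(seed + i)
    specs <- sample_lesions(cfg)
    ph <- render_phantom(specs, cfg)
    list(id = i, image = ph$image, mask = ph$mask, spacing = cfg$spacing)
  })
}

# place a solid axis-aligned box of 1s in a zero mask
box_mask <- function(shape, from, to) {
  m <- array(0, dim = rep(shape, length.out = 3))
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1
  m
}

# central finite difference of f at arr[i]
fdiff <- function(f, arr, i, h = 1e-5) {
  a1 <- arr; a1[i] <- a1[i] + h
  a2 <- arr; a2[i] <- a2[i] - h
  (f(a1) - f(a2)) / (2 * h)
}

# literal triple-loop contrastive loss, the pseudo-code oracle:
# for every anchor i (positive), attraction -log(exp(s_ij)/sum_{j'!=i}
# exp(s_ij')) over positives j != i, repulsion +log(exp(s_ik)/sum_k'
# exp(s_ik')) over negatives k.  Plain exp/log arithmetic, no
# stabilization, no sampling.
clp_bruteforce <- function(z, m, normalize = TRUE, temperature = 1) {
  tk <- t(z)  # tokens as rows
  if (normalize) tk <- tk / sqrt(rowSums(tk^2))
  s <- tk %*% t(tk) / temperature
  pos <- which(m == 1); neg <- which(m == 0)
  total <- 0
  for (i in pos) {
    others <- setdiff(pos, i)
    if (length(others)) {
      den <- sum(exp(s[i, others]))
      for (j in others) total <- total - log(exp(s[i, j]) / den)
    }
    if (length(neg)) {
      den <- sum(exp(s[i, neg]))
      for (k in neg) total <- total + log(exp(s[i, k]) / den)
    }
  }
  total
}

# naive per-patch focal loss, the loop oracle for lrp_loss
lrp_bruteforce <- function(y, q, gamma, two_sided = TRUE) {
  qc <- pmin(pmax(q, 1e-7), 1 - 1e-7)
  tot <- 0
  for (i in seq_along(y)) {
    t1 <- y[i] * (1 - qc[i])^gamma * log(qc[i])
    t2 <- if (two_sided) (1 - y[i]) * qc[i]^gamma * log(1 - qc[i]) else 0
    tot <- tot - (t1 + t2)
  }
  tot / length(y)
}

# exhaustive optimal one-to-one matching oracle: maximizes the number of
# matched pairs (all with CV >= threshold), then total coverage
match_bruteforce <- function(cv, threshold = 0.5) {
  np <- nrow(cv); ng <- ncol(cv)
  best <- list(n = -1, cov = -Inf)
  # enumerate assignments pred -> gt-or-unmatched recursively
  rec <- function(i, used, pairs) {
    if (i > np) {
      n <- nrow(pairs)
      cov <- if (n) sum(pairs$cv) else 0
      if (n > best$n || (n == best$n && cov > best$cov))
        best <<- list(n = n, cov = cov, pairs = pairs)
      return(invisible())
    }
    rec(i + 1, used, pairs)  # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (used[j] || cv[i, j] < threshold) next
      used[j] <- TRUE
      rec(i + 1, used, rbind(pairs, data.frame(pred_id = i, gt_id = j, cv = cv[i, j])))
      used[j] <- FALSE
    }
  }
  rec(1, logical(ng), data.frame(pred_id = integer(), gt_id = integer(), cv = numeric()))
  best
}
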