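# Supervised contrastive latent pretraining (CLP).
#
# The encoder + ViT are pretrained so that bottleneck tokens inside
# lesions attract each other and repel background tokens, via an
# InfoNCE-style objective over the 512 latent tokens.  The lesion mask
# is max-pool subsampled onto the 8x8x8 token grid; tokens in cells
# containing any lesion voxel are positives, the rest negatives.
#
# The loss follows the literal pseudo-code form: for each anchor i
# (positive), the attraction term is -log(exp(s_ij) / sum_{j' != i}
# exp(s_ij')) summed over positives j, with the denominator running
# over positives only; the repulsion term is +log(exp(s_ik) /
# sum_{k'} exp(s_ik')) summed over negatives k.  A standard
# supervised-contrastive denominator (positives + negatives) is
# available as a variant.

#' CLP configuration
#'
#' @param max_anchors,max_negatives Per-volume sampling caps on anchor
#'   and negative tokens; the full quadratic pair loop over 512 tokens
#'   is kept for testing but capped sampling is used in training.
#' @param normalize_tokens Unit-normalize tokens before similarities
#'   (default `TRUE`); with raw tokens the exponentials of inner
#'   products are clamped to avoid overflow.
#' @param temperature Similarity scale divisor (default 1, matching the
#'   unscaled `exp(z' z)` similarity).
#' @param denominator `"literal"` (attraction denominator over
#'   positives only) or `"supcon"` (positives + negatives).
#' @param epochs Pretraining epochs (default 30).
#' @param lr Initial learning rate of the poly schedule (default 0.001).
#' @return A list of class `"clp_config"`.
#' @export
clp_config <- function(max_anchors = 16L, max_negatives = 64L,
                       normalize_tokens = TRUE, temperature = 1,
                       denominator = c("literal", "supcon"),
                       epochs = 30L, lr = 0.001) {
  denominator <- match.arg(denominator)
  stopifnot(max_anchors >= 1, max_negatives >= 1, temperature > 0)
  structure(list(max_anchors = as.integer(max_anchors),
                 max_negatives = as.integer(max_negatives),
                 normalize_tokens = normalize_tokens,
                 temperature = temperature, denominator = denominator,
                 epochs = as.integer(epochs), lr = lr),
            class = "clp_config")
}

#' Subsample a lesion mask onto the token grid
#'
#' Max-pool subsampling: grid cell `l` is 1 iff its block of the
#' partitioned mask contains at least one lesion voxel (mean or nearest
#' subsampling would erase small lesions entirely). The raster order
#' (x fastest) matches the token order of [extract_latent()].
#'
#' @param gt Binary 3D mask; each axis must be divisible by the
#'   corresponding `grid_shape` entry.
#' @param grid_shape Token grid, default `c(8, 8, 8)`.
#' @return Binary vector of length `prod(grid_shape)` (512).
#' @export
subsample_mask <- function(gt, grid_shape = c(8L, 8L, 8L)) {
  d <- dim(gt)
  if (any(d %% grid_shape != 0))
    stop("mask shape ", paste(d, collapse = "x"),
         " not divisible by grid ", paste(grid_shape, collapse = "x"))
  cell <- d %/% grid_shape
  lin <- which(gt > 0)
  m <- numeric(prod(grid_shape))
  if (length(lin)) {
    co <- arrayInd(lin, d)
    cx <- (co[, 1] - 1L) %/% cell[1]
    cy <- (co[, 2] - 1L) %/% cell[2]
    cz <- (co[, 3] - 1L) %/% cell[3]
    m[unique(cx + grid_shape[1] * (cy + grid_shape[2] * cz)) + 1L] <- 1
  }
  m
}

# Core token-space loss. tokens: L x d matrix or node (rows = tokens).
# Returns NULL when there is no positive or no negative token.
.clp_loss_tokens <- function(tokens, m, config) {
  L <- nrow(vof(tokens))
  stopifnot(length(m) == L)
  pos <- which(m == 1)
  neg <- which(m == 0)
  if (!length(pos) || !length(neg)) return(NULL)
  anchors <- if (length(pos) > config$max_anchors)
    sort(sample(pos, config$max_anchors)) else pos
  negs <- if (length(neg) > config$max_negatives)
    sort(sample(neg, config$max_negatives)) else neg
  tk <- if (config$normalize_tokens) ag_rownorm(tokens) else tokens
  A <- ag_rows(tk, anchors)
  P <- ag_rows(tk, pos)
  N <- ag_rows(tk, negs)
  Sp <- ag_mul(ag_matmul(A, ag_t(P)), 1 / config$temperature)
  Sn <- ag_mul(ag_matmul(A, ag_t(N)), 1 / config$temperature)
  if (!config$normalize_tokens) {
    Sp <- ag_clamp(Sp, -30, 30)
    Sn <- ag_clamp(Sn, -30, 30)
  }
  # mask excluding each anchor's own column among the positives
  excl <- matrix(1, length(anchors), length(pos))
  own <- match(anchors, pos)
  for (r in seq_along(anchors)) excl[r, own[r]] <- 0
  np_eff <- length(pos) - 1L
  total <- NULL
  if (np_eff >= 1L) {
    lse_p <- if (config$denominator == "literal") ag_lse_rows(Sp, excl)
             else {
               # supcon: denominator over positives (j != i) and negatives
               both <- ag_cat_cols(list(Sp, Sn))
               ag_lse_rows(both, cbind(excl, matrix(1, length(anchors), length(negs))))
             }
    attr_term <- ag_sub(ag_mul(ag_sum(lse_p), np_eff),
                        ag_sum(ag_mul(Sp, excl)))
    total <- attr_term
  }
  lse_n <- ag_lse_rows(Sn)
  rep_term <- ag_sub(ag_sum(Sn), ag_mul(ag_sum(lse_n), length(negs)))
  total <- if (is.null(total)) rep_term else ag_add(total, rep_term)
  total
}

#' Contrastive (InfoNCE) latent loss
#'
#' Computes the supervised contrastive loss over a latent token field
#' and its subsampled mask, with log-sum-exp stabilization. Equals the
#' literal triple-loop pseudo-code evaluation on the same inputs.
#'
#' @param z Latent tokens: a `d x L` matrix (one token per column, as
#'   returned by [extract_latent()]).
#' @param m Binary vector of length `L` from [subsample_mask()].
#' @param config A [clp_config()]; set the caps `>= L` for the exact
#'   (unsampled) loss.
#' @return Scalar loss, or `NA` when the volume has no positive (or no
#'   negative) token, in which case the volume contributes no loss.
#' @export
clp_loss <- function(z, m, config = clp_config()) {
  if (any(!is.finite(z))) stop("non-finite latent entries")
  out <- .clp_loss_tokens(t(z), m, config)
  if (is.null(out)) return(NA_real_)
  vof(out)
}

#' Pretrain encoder + ViT with the contrastive loss
#'
#' Stage-1 training: optimizes the contrastive latent loss with
#' SGD/Nesterov momentum under a polynomial learning-rate schedule.
#' Decoder parameters are untouched (bitwise). Volumes whose token grid
#' contains no lesion cell are skipped and counted.
#'
#' @param net A [build_network()] network; will be put in stage
#'   `"pretrain"`.
#' @param cohort List of patients (`list(image, mask, ...)`) from
#'   [load_cohort()], or a manifest accepted by it.
#' @param config A [clp_config()].
#' @param train A [train_config()]; its optimizer settings are used
#'   (`epochs` and `lr` come from `config`).
#' @param verbose Print per-epoch losses.
#' @return The network, invisibly, with a `pretrain_trace` data frame
#'   (epoch, mean loss, volumes skipped) attached to `net$traces`.
#' @export
pretrain <- function(net, cohort, config = clp_config(),
                     train = train_config(), verbose = FALSE) {
  if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
    cohort <- load_cohort(cohort)
  set_stage(net, "pretrain")
  n_pos <- sum(vapply(cohort, function(p) sum(p$mask) > 0, logical(1)))
  if (n_pos == 0L) stop("cohort contains no lesioned volume")
  opt <- .sgd_state(net, c("encoder", "vit"))
  trace <- data.frame(epoch = integer(), loss = numeric(), skipped = integer())
  for (ep in seq_len(config$epochs)) {
    lr <- poly_lr(ep - 1L, config$epochs, config$lr, train$poly_power)
    losses <- c(); skipped <- 0L
    for (pat in cohort[sample(length(cohort))]) {
      m <- subsample_mask(pat$mask)
      if (sum(m) == 0 || sum(m) == length(m)) { skipped <- skipped + 1L; next }
      fw <- .net_forward(net, pat$image, "latent")
      loss <- .clp_loss_tokens(fw$latent, m, config)
      if (is.null(loss)) { skipped <- skipped + 1L; next }
      ag_backward(loss)
      .sgd_step(net, opt, fw$pnodes, lr, train)
      losses <- c(losses, vof(loss))
    }
    trace <- rbind(trace, data.frame(epoch = ep,
                                     loss = if (length(losses)) mean(losses) else NA_real_,
                                     skipped = skipped))
    if (verbose) message(sprintf("pretrain epoch %d: loss %.4f", ep,
                                 trace$loss[nrow(trace)]))
  }
  net$traces$pretrain <- trace
  invisible(net)
}

#' Latent class-separation score
#'
#' After normalizing every latent dimension by the mean and SD of the
#' non-lesion tokens, returns the distance between the lesion and
#' non-lesion centroids divided by the mean within-class RMS spread.
#' Higher means better-separated classes; the score is invariant to a
#' common affine rescaling of all tokens.
#'
#' @param z `d x L` latent matrix.
#' @param m Binary vector of length `L` (1 = lesion cell).
#' @param normalize_by_negatives Normalize by non-lesion statistics
#'   first (default `TRUE`).
#' @return Non-negative scalar.
#' @export
separation_score <- function(z, m, normalize_by_negatives = TRUE) {
  stopifnot(ncol(z) == length(m))
  if (length(unique(m)) < 2L) stop("both classes must be present")
  if (normalize_by_negatives) {
    zn <- z[, m == 0, drop = FALSE]
    mu <- rowMeans(zn)
    s <- apply(zn, 1, sd)
    s[s < 1e-12] <- 1e-12
    z <- (z - mu) / s
  }
  zp <- z[, m == 1, drop = FALSE]
  zn <- z[, m == 0, drop = FALSE]
  cdist <- sqrt(sum((rowMeans(zp) - rowMeans(zn))^2))
  spread <- function(x) sqrt(mean(apply(x, 1, stats::var)))
  sp <- mean(c(spread(zp), spread(zn)))
  if (sp < 1e-12) return(if (cdist < 1e-12) 0 else Inf)
  cdist / sp
}

#' t-SNE embedding of latent tokens
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding of the
#' latent tokens into 2D for visualizing lesion / non-lesion
#' separation. Seeded and deterministic.
#'
#' @param z `d x L` latent matrix (`L >= 10`).
#' @param m Binary class labels of length `L`.
#' @param seed RNG seed.
#' @param perplexity Target perplexity (default 10).
#' @param n_iter Gradient-descent iterations (default 300).
#' @return Data frame with `x`, `y`, `label`.
#' @export
tsne_embed <- function(z, m, seed = 1L, perplexity = 10, n_iter = 300L) {
  X <- t(z)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 tokens")
  if (max(dist(X)) < 1e-12) stop("degenerate input: all tokens identical")
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  # per-point bandwidths by bisection on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    mult <- if (it < 100) 4 else 1  # early exaggeration
    W <- (mult * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
    inc <- (if (it < 20) 0.5 else 0.8) * inc - 200 * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  data.frame(x = Y[, 1], y = Y[, 2], label = m)
}
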