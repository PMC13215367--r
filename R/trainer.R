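# Two-stage optimization schedule.
#
# Stage 1 pretrains encoder + ViT with the contrastive latent loss
# (decoder frozen); stage 2 fine-tunes the decoder with the composite
# Dice + CE + patch-focal loss (encoder + ViT frozen).  Both stages use
# SGD with Nesterov momentum 0.99 and a polynomial learning-rate decay
# from 0.001, the optimizer settings of full-scale training; epoch
# counts default to desk scale (30 + 30) and are fully configurable.

#' Training configuration
#'
#' @param epochs_pretrain,epochs_finetune Stage epoch counts (desk
#'   defaults 30 + 30; full-scale training uses 4000 + 4000 with 201
#'   batch iterations per epoch).
#' @param lr0 Initial learning rate (default 0.001).
#' @param momentum Nesterov momentum (default 0.99).
#' @param poly_power Polynomial decay exponent (default 0.9).
#' @param batch_size Volumes per optimizer step (default 2; whole
#'   volumes, no patch sampling).
#' @param clip_norm Global gradient-norm clip (default 5).
#' @param seed RNG seed for shuffling and sampling.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs_pretrain = 30L, epochs_finetune = 30L,
                         lr0 = 0.001, momentum = 0.99, poly_power = 0.9,
                         batch_size = 2L, clip_norm = 5, seed = 1L) {
  stopifnot(epochs_pretrain >= 1, epochs_finetune >= 1, lr0 > 0,
            momentum >= 0, momentum < 1, batch_size >= 1)
  structure(list(epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 lr0 = lr0, momentum = momentum, poly_power = poly_power,
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Polynomial learning-rate schedule
#'
#' `lr0 * (1 - epoch / total_epochs)^power`: starts at `lr0` and decays
#' monotonically to 0 at the final epoch.
#'
#' @param epoch Current epoch, `0 <= epoch <= total_epochs`.
#' @param total_epochs Total number of epochs (`> 0`).
#' @param lr0 Initial rate (default 0.001).
#' @param power Decay exponent (default 0.9).
#' @return The learning rate.
#' @export
poly_lr <- function(epoch, total_epochs, lr0 = 0.001, power = 0.9) {
  if (total_epochs <= 0) stop("total_epochs must be positive")
  stopifnot(epoch >= 0, epoch <= total_epochs)
  lr0 * (1 - epoch / total_epochs)^power
}

# optimizer state: velocity per trainable parameter
.sgd_state <- function(net, groups) {
  nms <- names(net$params)[net$groups[names(net$params)] %in% groups]
  st <- new.env(parent = emptyenv())
  st$names <- nms
  st$vel <- lapply(net$params[nms], function(p) array(0, dim = dim(p) %||% length(p)))
  names(st$vel) <- nms
  st
}

# one SGD/Nesterov step from accumulated gradients on the param nodes
.sgd_step <- function(net, opt, pnodes, lr, train) {
  grads <- lapply(opt$names, function(nm) ag_grad(pnodes[[nm]]))
  names(grads) <- opt$names
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(train$clip_norm) && gn > train$clip_norm)
    grads <- lapply(grads, function(g) g * (train$clip_norm / gn))
  mu <- train$momentum
  for (nm in opt$names) {
    g <- grads[[nm]]
    v <- mu * opt$vel[[nm]] + g
    opt$vel[[nm]] <- v
    upd <- g + mu * v  # Nesterov
    dim(upd) <- dim(net$params[[nm]])
    net$params[[nm]] <- net$params[[nm]] - lr * upd
  }
  invisible(gn)
}

#' Fine-tune the decoder with the composite loss
#'
#' Stage-2 training: the decoder is optimized against
#' [composite_loss()] while encoder + ViT stay bitwise frozen. Batches
#' accumulate gradients over `batch_size` whole volumes.
#'
#' @param net A network (pretrained or fresh); moved to stage
#'   `"finetune"`.
#' @param cohort Patient list from [load_cohort()] or a manifest.
#' @param train A [train_config()].
#' @param loss A [loss_config()]; `loss$w` is the patch-focal mixing
#'   weight and can be swept.
#' @param verbose Print per-epoch losses.
#' @return The network, invisibly, with `net$traces$finetune` holding
#'   the per-epoch mean composite loss.
#' @export
finetune <- function(net, cohort, train = train_config(),
                     loss = loss_config(), verbose = FALSE) {
  if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
    cohort <- load_cohort(cohort)
  set_stage(net, "finetune")
  opt <- .sgd_state(net, "decoder")
  # Encoder + ViT are frozen in this stage, so their forward pass is
  # computed once per volume and cached as plain numeric features.
  cache <- lapply(cohort, function(p) .net_encode(net, p$image, net$params))
  trace <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(train$epochs_finetune)) {
    lr <- poly_lr(ep - 1L, train$epochs_finetune, train$lr0, train$poly_power)
    ord <- sample(length(cohort))
    losses <- c()
    i <- 0L
    while (i < length(ord)) {
      # accumulate mean gradients over one batch on a shared tape
      bsize <- min(train$batch_size, length(ord) - i)
      sel <- ord[(i + 1):(i + bsize)]
      i <- i + bsize
      pn1 <- NULL
      for (bi in seq_along(sel)) {
        pn <- .make_pnodes(net)
        en <- cache[[sel[bi]]]
        probs <- .net_decode(net, en$latent, en$skips, pn)
        l <- composite_loss(probs, cohort[[sel[bi]]]$mask, loss)
        losses <- c(losses, vof(l))
        ag_backward(ag_mul(l, 1 / bsize))
        if (bi == 1L) pn1 <- pn else {
          for (nm in opt$names) {
            g <- pn[[nm]]$grad
            if (!is.null(g))
              pn1[[nm]]$grad <- (pn1[[nm]]$grad %||% 0) + g
          }
        }
      }
      .sgd_step(net, opt, pn1, lr, train)
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = mean(losses)))
    if (verbose) message(sprintf("finetune epoch %d: loss %.4f", ep,
                                 trace$loss[nrow(trace)]))
  }
  net$traces$finetune <- trace
  invisible(net)
}

#' Sweep the patch-focal mixing weight
#'
#' Trains one stage-1 (contrastive) encoder per seed, then fine-tunes a
#' fresh decoder from the shared encoder once per `w` value at equal
#' epochs, and evaluates lesion-wise metrics on the cohort. This is the
#' scaled analog of the LRP-weight sensitivity experiment: it isolates
#' the effect of `w` on detection (notably small-lesion sensitivity)
#' under a paired comparison.
#'
#' @param cohort Patient list or manifest.
#' @param w_values Mixing weights to compare (e.g. `c(0, 0.4)`).
#' @param net A [net_config()].
#' @param train A [train_config()].
#' @param clp A [clp_config()].
#' @param loss A [loss_config()] supplying the non-`w` loss settings.
#' @param seed Seed for this replicate.
#' @return A data frame with one row per `w`: lesion-level sensitivity
#'   and precision (pooled and small-stratum), mean Dice and counts.
#' @export
sweep_w <- function(cohort, w_values = c(0, 0.4), net = NULL,
                    train = train_config(), clp = clp_config(),
                    loss = loss_config(), seed = 1L) {
  if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
    cohort <- load_cohort(cohort)
  if (is.null(net))
    net <- net_config(input_shape = dim(cohort[[1]]$image)[1])
  base <- build_network(net, seed = seed)
  clp$epochs <- train$epochs_pretrain
  clp$lr <- train$lr0
  set.seed(seed)
  pretrain(base, cohort, clp, train)
  enc_params <- base$params
  out <- NULL
  for (w in w_values) {
    netw <- build_network(net, seed = seed)
    netw$params <- enc_params  # shared pretrained encoder + fresh decoder seeding
    lw <- loss
    lw$w <- w
    set.seed(seed + 1L)
    finetune(netw, cohort, train, lw)
    recs <- lapply(cohort, function(p)
      evaluate_masks(predict_mask(netw, p$image), p$mask, p$spacing %||% c(1, 1, 1)))
    rl <- lesion_level_report(recs)
    out <- rbind(out, data.frame(
      w = w,
      sensitivity = rl$sensitivity,
      precision = rl$precision,
      sensitivity_small = unname(rl$sensitivity_by_stratum["small"]),
      precision_small = unname(rl$precision_by_stratum["small"]),
      mean_dice = rl$mean_dice,
      tp = rl$tp, fp = rl$fp, fn = rl$fn))
  }
  out
}

#' Run the full two-stage schedule
#'
#' Stage 1: contrastive pretraining of encoder + ViT (decoder frozen).
#' Stage 2: decoder fine-tuning with the composite loss (encoder + ViT
#' frozen). Returns per-stage loss traces and parameter checkpoints.
#'
#' @param net A freshly built network.
#' @param cohort Patient list or manifest.
#' @param train A [train_config()].
#' @param loss A [loss_config()].
#' @param clp A [clp_config()]; its `epochs` default is overridden by
#'   `train$epochs_pretrain`.
#' @param verbose Print progress.
#' @return A list with the trained `net`, `traces` (pretrain/finetune)
#'   and `checkpoints` (parameter lists after each stage).
#' @export
run_two_stage <- function(net, cohort, train = train_config(),
                          loss = loss_config(), clp = clp_config(),
                          verbose = FALSE) {
  if (!is.list(cohort[[1]]) || is.null(cohort[[1]]$mask))
    cohort <- load_cohort(cohort)
  clp$epochs <- train$epochs_pretrain
  clp$lr <- train$lr0
  set.seed(train$seed)
  pretrain(net, cohort, clp, train, verbose = verbose)
  ckpt1 <- net$params
  finetune(net, cohort, train, loss, verbose = verbose)
  list(net = net,
       traces = net$traces,
       checkpoints = list(after_pretrain = ckpt1, after_finetune = net$params))
}
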