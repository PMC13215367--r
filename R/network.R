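# Hybrid encoder-transformer-decoder segmentation network.
#
# A U-Net style convolutional encoder downsamples the input volume to
# an 8x8x8 bottleneck grid (L = 512 token positions), a small vision
# transformer models global context over the bottleneck tokens, and a
# decoder with skip connections upsamples back to per-voxel class
# probabilities (background / lesion).  Parameters are grouped into
# encoder, vit and decoder; a stage flag controls which groups train
# (contrastive pretraining: encoder + vit; fine-tuning: decoder only).

#' Network configuration
#'
#' The bottleneck token grid is fixed at 8x8x8 (`L = 512` tokens), so
#' the per-stage downsampling strides must multiply to
#' `input_shape / 8`. Strides are derived automatically (factors of 2
#' and 3, e.g. 64 -> (2,2,2), 48 -> (2,3)); passing `n_down` forces
#' `n_down` stride-2 stages and errors when they do not reach 8.
#'
#' @param input_shape Edge length in voxels of the (cubic) input volume.
#' @param base_channels Channels of the first encoder stage; doubled per
#'   stage (capped at 32).
#' @param vit_layers Number of transformer layers (default 6).
#' @param vit_dim Token feature dimension `d`; must be divisible by
#'   `vit_heads`.
#' @param vit_heads Number of attention heads.
#' @param out_classes Number of output classes (2: background/lesion).
#' @param n_down Optional explicit number of 2x downsamplings.
#' @return A list of class `"net_config"`.
#' @export
net_config <- function(input_shape = 64L, base_channels = 8L, vit_layers = 6L,
                       vit_dim = 16L, vit_heads = 2L, out_classes = 2L,
                       n_down = NULL) {
  input_shape <- as.integer(input_shape[1])
  if (!is.null(n_down)) {
    strides <- rep(2L, n_down)
  } else {
    f <- input_shape / 8L
    if (f != round(f)) stop("input_shape / 8 must be an integer")
    f <- as.integer(f)
    strides <- integer(0)
    while (f %% 2L == 0L) { strides <- c(strides, 2L); f <- f %/% 2L }
    while (f %% 3L == 0L) { strides <- c(strides, 3L); f <- f %/% 3L }
    if (f != 1L)
      stop("input_shape ", input_shape,
           " cannot be reduced to an 8^3 bottleneck with stride-2/3 stages")
  }
  if (prod(strides) * 8L != input_shape)
    stop("input_shape ", input_shape, " with ", length(strides),
         " downsamplings gives a ", input_shape / prod(strides),
         "^3 bottleneck; the token grid must be 8^3")
  if (vit_dim %% vit_heads != 0L) stop("vit_dim must be divisible by vit_heads")
  channels <- pmin(base_channels * 2L^(seq_along(strides) - 1L), 32L)
  structure(list(input_shape = input_shape, strides = strides,
                 n_down = length(strides), base_channels = as.integer(base_channels),
                 channels = as.integer(channels), vit_layers = as.integer(vit_layers),
                 vit_dim = as.integer(vit_dim), vit_heads = as.integer(vit_heads),
                 out_classes = as.integer(out_classes), n_tokens = 512L),
            class = "net_config")
}

.he_w <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)

#' Build a segmentation network
#'
#' Initializes all parameter arrays deterministically from `seed`.
#' The returned object is an environment (reference semantics): training
#' updates and [set_stage()] modify it in place.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `"lesion_network"` with fields `params`
#'   (named list of arrays), `groups` (parameter-name -> group map),
#'   `config` and `stage` (one of `"pretrain"`, `"finetune"`,
#'   `"inference"`).
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  set.seed(seed)
  P <- list(); G <- character(0)
  add <- function(name, value, group) {
    P[[name]] <<- value
    G[name] <<- group
  }
  ch <- c(1L, config$channels)
  d <- config$vit_dim
  for (i in seq_len(config$n_down)) {
    ci <- ch[i]; co <- ch[i + 1]; s <- config$strides[i]
    add(paste0("enc", i, "_c1_w"), .he_w(c(3, 3, 3, ci, co), 27 * ci), "encoder")
    add(paste0("enc", i, "_c1_b"), numeric(co), "encoder")
    add(paste0("enc", i, "_n1_g"), rep(1, co), "encoder")
    add(paste0("enc", i, "_n1_b"), numeric(co), "encoder")
    add(paste0("enc", i, "_c2_w"), .he_w(c(3, 3, 3, co, co), 27 * co), "encoder")
    add(paste0("enc", i, "_c2_b"), numeric(co), "encoder")
    add(paste0("enc", i, "_n2_g"), rep(1, co), "encoder")
    add(paste0("enc", i, "_n2_b"), numeric(co), "encoder")
    add(paste0("enc", i, "_dw"), .he_w(c(s, s, s, co, co), s^3 * co), "encoder")
    add(paste0("enc", i, "_db"), numeric(co), "encoder")
    add(paste0("enc", i, "_nd_g"), rep(1, co), "encoder")
    add(paste0("enc", i, "_nd_b"), numeric(co), "encoder")
  }
  cn <- ch[config$n_down + 1]
  add("vit_proj_w", .he_w(c(1, 1, 1, cn, d), cn), "vit")
  add("vit_proj_b", numeric(d), "vit")
  add("vit_pos", matrix(rnorm(512 * d, sd = 0.02), 512, d), "vit")
  hdim <- 2L * d
  for (l in seq_len(config$vit_layers)) {
    pre <- paste0("vit", l, "_")
    add(paste0(pre, "ln1_g"), rep(1, d), "vit")
    add(paste0(pre, "ln1_b"), numeric(d), "vit")
    for (nm in c("wq", "wk", "wv", "wo"))
      add(paste0(pre, nm), matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d), "vit")
    add(paste0(pre, "ln2_g"), rep(1, d), "vit")
    add(paste0(pre, "ln2_b"), numeric(d), "vit")
    add(paste0(pre, "w1"), matrix(rnorm(d * hdim, sd = sqrt(1 / d)), d, hdim), "vit")
    add(paste0(pre, "b1"), numeric(hdim), "vit")
    add(paste0(pre, "w2"), matrix(rnorm(hdim * d, sd = sqrt(1 / hdim)), hdim, d), "vit")
    add(paste0(pre, "b2"), numeric(d), "vit")
  }
  add("dec_proj_w", .he_w(c(1, 1, 1, d, cn), d), "decoder")
  add("dec_proj_b", numeric(cn), "decoder")
  dch <- cn  # channels entering each up stage
  for (i in rev(seq_len(config$n_down))) {
    s <- config$strides[i]
    skip_c <- ch[i + 1]
    out_c <- ch[max(i, 2)]  # taper toward the base width
    add(paste0("dec", i, "_up_w"), .he_w(c(s, s, s, skip_c, dch), s^3 * dch), "decoder")
    add(paste0("dec", i, "_up_b"), numeric(skip_c), "decoder")
    add(paste0("dec", i, "_c_w"),
        .he_w(c(3, 3, 3, 2L * skip_c, out_c), 27 * 2 * skip_c), "decoder")
    add(paste0("dec", i, "_c_b"), numeric(out_c), "decoder")
    add(paste0("dec", i, "_n_g"), rep(1, out_c), "decoder")
    add(paste0("dec", i, "_n_b"), numeric(out_c), "decoder")
    dch <- out_c
  }
  add("head_w", array(rnorm(dch * config$out_classes, sd = 0.01),
                      c(1, 1, 1, dch, config$out_classes)), "decoder")
  # background-prior bias: foreground starts at ~5% probability so the
  # cross-entropy term is near its optimum for the empty-background bulk
  add("head_b", c(0, rep(-3, config$out_classes - 1L)), "decoder")
  net <- new.env(parent = emptyenv())
  net$params <- P
  net$groups <- G
  net$config <- config
  net$stage <- "inference"
  net$seed <- as.integer(seed)
  class(net) <- "lesion_network"
  net
}

.frozen_groups <- function(stage) {
  switch(stage,
         pretrain = "decoder",
         finetune = c("encoder", "vit"),
         inference = c("encoder", "vit", "decoder"),
         stop("unknown stage '", stage, "'"))
}

#' Set the training stage of a network
#'
#' `"pretrain"` trains encoder + ViT only (decoder frozen),
#' `"finetune"` trains the decoder only (encoder + ViT frozen),
#' `"inference"` freezes everything. Frozen parameters accumulate
#' exactly zero gradient.
#'
#' @param net A [build_network()] object.
#' @param stage One of `"pretrain"`, `"finetune"`, `"inference"`.
#' @return The network, invisibly (modified in place).
#' @export
set_stage <- function(net, stage) {
  .frozen_groups(stage)  # validates
  net$stage <- stage
  invisible(net)
}

# parameter nodes for one tape, with freezing per the current stage
.make_pnodes <- function(net) {
  frozen <- .frozen_groups(net$stage)
  pn <- lapply(names(net$params), function(nm)
    ag_var(net$params[[nm]], frozen = net$groups[[nm]] %in% frozen))
  names(pn) <- names(net$params)
  pn
}

# Encoder + ViT half: volume -> latent tokens (L x d) and skip features.
# `pn` may hold autograd nodes (training) or the plain parameter arrays
# (cached inference: every op then takes its numeric fast path).
.net_encode <- function(net, vol, pn) {
  cfg <- net$config
  d3 <- dim(vol)
  if (is.null(d3)) stop("volume must be a 3D array")
  if (!all(d3 == cfg$input_shape))
    stop("volume shape ", paste(d3, collapse = "x"),
         " does not match the configured input shape ", cfg$input_shape, "^3")
  # normalize intensities per volume (z-score) before the first conv
  x <- (vol - mean(vol)) / (sd(vol) + 1e-8)
  x <- ag_reshape(x, c(d3, 1L))
  skips <- list()
  for (i in seq_len(cfg$n_down)) {
    s <- cfg$strides[i]
    x <- ag_lrelu(ag_inorm(ag_conv3(x, pn[[paste0("enc", i, "_c1_w")]],
                                   pn[[paste0("enc", i, "_c1_b")]], 1L, 1L),
                          pn[[paste0("enc", i, "_n1_g")]],
                          pn[[paste0("enc", i, "_n1_b")]]))
    x <- ag_lrelu(ag_inorm(ag_conv3(x, pn[[paste0("enc", i, "_c2_w")]],
                                   pn[[paste0("enc", i, "_c2_b")]], 1L, 1L),
                          pn[[paste0("enc", i, "_n2_g")]],
                          pn[[paste0("enc", i, "_n2_b")]]))
    skips[[i]] <- x
    x <- ag_lrelu(ag_inorm(ag_conv3(x, pn[[paste0("enc", i, "_dw")]],
                                   pn[[paste0("enc", i, "_db")]], s, 0L),
                          pn[[paste0("enc", i, "_nd_g")]],
                          pn[[paste0("enc", i, "_nd_b")]]))
  }
  # tokens: 8x8x8 grid in raster order (x fastest), L x d matrix
  tk <- ag_conv3(x, pn$vit_proj_w, pn$vit_proj_b, 1L, 0L)
  tk <- ag_reshape(tk, c(512L, cfg$vit_dim))
  tk <- ag_add(tk, pn$vit_pos)
  dh <- cfg$vit_dim %/% cfg$vit_heads
  for (l in seq_len(cfg$vit_layers)) {
    pre <- paste0("vit", l, "_")
    h <- ag_layernorm(tk, pn[[paste0(pre, "ln1_g")]], pn[[paste0(pre, "ln1_b")]])
    Q <- ag_matmul(h, pn[[paste0(pre, "wq")]])
    K <- ag_matmul(h, pn[[paste0(pre, "wk")]])
    V <- ag_matmul(h, pn[[paste0(pre, "wv")]])
    heads <- vector("list", cfg$vit_heads)
    for (hd in seq_len(cfg$vit_heads)) {
      idx <- ((hd - 1L) * dh + 1L):(hd * dh)
      sc <- ag_mul(ag_matmul(ag_cols(Q, idx), ag_t(ag_cols(K, idx))), 1 / sqrt(dh))
      heads[[hd]] <- ag_matmul(ag_softmax_rows(sc), ag_cols(V, idx))
    }
    att <- ag_matmul(ag_cat_cols(heads), pn[[paste0(pre, "wo")]])
    tk <- ag_add(tk, att)
    h2 <- ag_layernorm(tk, pn[[paste0(pre, "ln2_g")]], pn[[paste0(pre, "ln2_b")]])
    mlp <- ag_add_rowvec(ag_matmul(h2, pn[[paste0(pre, "w1")]]),
                         pn[[paste0(pre, "b1")]])
    mlp <- ag_add_rowvec(ag_matmul(ag_gelu(mlp), pn[[paste0(pre, "w2")]]),
                         pn[[paste0(pre, "b2")]])
    tk <- ag_add(tk, mlp)
  }
  list(latent = tk, skips = skips)
}

# Decoder half: latent tokens + skips -> voxelwise class probabilities.
.net_decode <- function(net, latent, skips, pn) {
  cfg <- net$config
  d3 <- rep(cfg$input_shape, 3L)
  x <- ag_reshape(latent, c(8L, 8L, 8L, cfg$vit_dim))
  x <- ag_lrelu(ag_conv3(x, pn$dec_proj_w, pn$dec_proj_b, 1L, 0L))
  for (i in rev(seq_len(cfg$n_down))) {
    s <- cfg$strides[i]
    x <- ag_tconv3(x, pn[[paste0("dec", i, "_up_w")]],
                   pn[[paste0("dec", i, "_up_b")]], s)
    x <- ag_cat_ch(x, skips[[i]])
    x <- ag_lrelu(ag_inorm(ag_conv3(x, pn[[paste0("dec", i, "_c_w")]],
                                   pn[[paste0("dec", i, "_c_b")]], 1L, 1L),
                          pn[[paste0("dec", i, "_n_g")]],
                          pn[[paste0("dec", i, "_n_b")]]))
  }
  logits <- ag_conv3(x, pn$head_w, pn$head_b, 1L, 0L)
  nvox <- prod(d3)
  probs <- ag_softmax_rows(ag_reshape(logits, c(nvox, cfg$out_classes)))
  ag_reshape(probs, c(d3, cfg$out_classes))
}

# Full forward pass on the autograd tape.  Returns `probs` (voxelwise
# class-probability node), `latent` (L x d token node) and `pnodes`
# (parameter nodes, for the optimizer).  `upto = "latent"` skips the
# decoder.
.net_forward <- function(net, vol, upto = c("probs", "latent")) {
  upto <- match.arg(upto)
  pn <- .make_pnodes(net)
  enc <- .net_encode(net, vol, pn)
  if (upto == "latent")
    return(list(latent = enc$latent, probs = NULL, pnodes = pn))
  probs <- .net_decode(net, enc$latent, enc$skips, pn)
  list(probs = probs, latent = enc$latent, pnodes = pn)
}

#' Segment a volume
#'
#' Runs the forward pass and returns per-voxel class probabilities
#' (summing to 1 per voxel); thresholding the foreground channel at 0.5
#' yields the predicted binary mask.
#'
#' @param net A [build_network()] object.
#' @param vol 3D numeric array matching the configured input shape.
#' @return 4D array `(x, y, z, class)` of probabilities, classes
#'   (background, lesion).
#' @export
forward_segment <- function(net, vol) {
  vof(.net_forward(net, vol, "probs")$probs)
}

#' Predicted binary mask of a volume
#'
#' @inheritParams forward_segment
#' @param threshold Foreground threshold (default 0.5).
#' @return Binary 3D array.
#' @export
predict_mask <- function(net, vol, threshold = 0.5) {
  p <- forward_segment(net, vol)
  (p[, , , 2] > threshold) + 0
}

#' Extract the latent token field
#'
#' Returns the ViT output tokens: a `d x L` matrix (`L = 512`), one
#' column per bottleneck grid cell in raster order (x fastest), the
#' same order used by [subsample_mask()].
#'
#' @inheritParams forward_segment
#' @return `d x 512` numeric matrix.
#' @export
extract_latent <- function(net, vol) {
  t(vof(.net_forward(net, vol, "latent")$latent))
}

#' @export
print.lesion_network <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("lesion segmentation network: %d^3 input, %d down-stages (strides %s),\n",
              cfg$input_shape, cfg$n_down, paste(cfg$strides, collapse = ",")))
  cat(sprintf("  ViT: %d layers, d = %d, %d heads over 512 tokens; stage '%s'\n",
              cfg$vit_layers, cfg$vit_dim, cfg$vit_heads, x$stage))
  cat(sprintf("  %d parameters (%s)\n", npar,
              paste(sprintf("%s %d", c("encoder", "vit", "decoder"),
                            vapply(c("encoder", "vit", "decoder"), function(g)
                              sum(vapply(names(x$params)[x$groups == g],
                                         function(n) length(x$params[[n]]), numeric(1))),
                              numeric(1))), collapse = ", ")))
  invisible(x)
}

# checkpoint save/load with stage metadata (plain-text JSON)
#' Save / load network checkpoints
#'
#' Checkpoints are JSON (parameter arrays flattened with dims), so they
#' remain plain text and portable.
#'
#' @param net A network object.
#' @param path File path.
#' @return `load_checkpoint` returns a `"lesion_network"`.
#' @export
save_checkpoint <- function(net, path) {
  obj <- list(config = unclass(net$config), stage = net$stage, seed = net$seed,
              groups = as.list(net$groups),
              params = lapply(net$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- obj$config
  config <- net_config(input_shape = cfg$input_shape,
                       base_channels = cfg$base_channels,
                       vit_layers = cfg$vit_layers, vit_dim = cfg$vit_dim,
                       vit_heads = cfg$vit_heads, out_classes = cfg$out_classes)
  net <- build_network(config, seed = obj$seed %||% 1L)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    arr <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(arr) <- as.integer(p$dim)
    net$params[[nm]] <- arr
  }
  net$stage <- obj$stage
  net
}
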