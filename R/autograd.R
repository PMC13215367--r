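# Minimal reverse-mode automatic differentiation tape.
#
# Every differentiable quantity is either a plain numeric array or an
# `ag_node` environment holding a value, an accumulated gradient and the
# parent links with their local vector-Jacobian products.  All loss
# functions in the package are written against these dual-mode ops, so
# the same code path serves plain numeric evaluation (user-facing loss
# values) and training (gradient computation).  Gradients of each op are
# checked against central finite differences in the test suite.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_var <- function(value, frozen = FALSE) {
  node <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  node$id <- as.character(.ag_counter$n)
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$frozen <- frozen
  class(node) <- "ag_node"
  node
}

is_node <- function(x) inherits(x, "ag_node")

# value of a node or passthrough for numerics
vof <- function(x) if (is_node(x)) x$value else x

.ag <- function(value, parents, gradfns) {
  node <- ag_var(value)
  keep <- vapply(parents, is_node, logical(1))
  node$parents <- Map(function(p, f) list(node = p, gradfn = f),
                      parents[keep], gradfns[keep])
  node
}

.any_node <- function(...) any(vapply(list(...), is_node, logical(1)))

# Backpropagate from a scalar root.  Frozen leaf variables do not
# accumulate gradients (their grad stays zero), which realizes the
# stage-freezing contract exactly.
ag_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1L)
  order <- list()
  visited <- new.env(parent = emptyenv())
  visit <- function(node) {
    if (!is.null(visited[[node$id]])) return(invisible())
    visited[[node$id]] <- TRUE
    for (p in node$parents) visit(p$node)
    order[[length(order) + 1L]] <<- node
  }
  visit(root)
  root$grad <- 1
  for (node in rev(order)) {
    g <- node$grad
    if (is.null(g)) next
    for (p in node$parents) {
      if (isTRUE(p$node$frozen)) next
      contrib <- p$gradfn(g)
      p$node$grad <- if (is.null(p$node$grad)) contrib else p$node$grad + contrib
    }
  }
  invisible(root)
}

ag_grad <- function(node) {
  if (is.null(node$grad)) array(0, dim = dim(node$value) %||% length(node$value)) else node$grad
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reduce a gradient to a scalar parent if needed
.red <- function(g, val) if (length(val) == 1L && length(g) > 1L) sum(g) else g

# ---- elementwise arithmetic -------------------------------------------------

ag_add <- function(a, b) {
  if (!.any_node(a, b)) return(a + b)
  av <- vof(a); bv <- vof(b)
  .ag(av + bv, list(a, b),
      list(function(g) .red(g, av), function(g) .red(g, bv)))
}

ag_sub <- function(a, b) {
  if (!.any_node(a, b)) return(a - b)
  av <- vof(a); bv <- vof(b)
  .ag(av - bv, list(a, b),
      list(function(g) .red(g, av), function(g) .red(-g, bv)))
}

ag_mul <- function(a, b) {
  if (!.any_node(a, b)) return(a * b)
  av <- vof(a); bv <- vof(b)
  .ag(av * bv, list(a, b),
      list(function(g) .red(g * bv, av), function(g) .red(g * av, bv)))
}

ag_div <- function(a, b) {
  if (!.any_node(a, b)) return(a / b)
  av <- vof(a); bv <- vof(b)
  .ag(av / bv, list(a, b),
      list(function(g) .red(g / bv, av), function(g) .red(-g * av / bv^2, bv)))
}

ag_neg <- function(a) ag_mul(a, -1)

# x^p for constant exponent p
ag_pow <- function(a, p) {
  if (!is_node(a)) return(a^p)
  av <- vof(a)
  .ag(av^p, list(a), list(function(g) g * p * av^(p - 1)))
}

ag_log <- function(a) {
  if (!is_node(a)) return(log(a))
  av <- vof(a)
  .ag(log(av), list(a), list(function(g) g / av))
}

ag_exp <- function(a) {
  if (!is_node(a)) return(exp(a))
  ev <- exp(vof(a))
  .ag(ev, list(a), list(function(g) g * ev))
}

ag_clamp <- function(a, lo, hi) {
  if (!is_node(a)) return(pmin(pmax(a, lo), hi))
  av <- vof(a)
  val <- pmin(pmax(av, lo), hi)
  inside <- (av >= lo) & (av <= hi)
  .ag(val, list(a), list(function(g) g * inside))
}

ag_relu <- function(a) {
  if (!is_node(a)) return(pmax(a, 0))
  av <- vof(a)
  .ag(pmax(av, 0), list(a), list(function(g) g * (av > 0)))
}

# leaky ReLU (slope for negative inputs); avoids dead units in the
# convolutional blocks under large momentum-amplified steps
ag_lrelu <- function(a, slope = 0.01) {
  av <- vof(a)
  val <- .lrelu_fwd(av, slope)
  if (!is_node(a)) return(val)
  .ag(val, list(a), list(function(g) .lrelu_bwd(g, av, slope)))
}

ag_gelu <- function(a) {
  if (!is_node(a)) { av <- a; return(av * stats::pnorm(av)) }
  av <- vof(a)
  .ag(av * stats::pnorm(av), list(a),
      list(function(g) g * (stats::pnorm(av) + av * stats::dnorm(av))))
}

# ---- reductions -------------------------------------------------------------

ag_sum <- function(a) {
  if (!is_node(a)) return(sum(a))
  av <- vof(a)
  d <- dim(av)
  .ag(sum(av), list(a),
      list(function(g) {
        out <- rep(as.numeric(g), length(av))
        dim(out) <- d
        out
      }))
}

ag_mean <- function(a) {
  if (!is_node(a)) return(mean(a))
  ag_mul(ag_sum(a), 1 / length(vof(a)))
}

# ---- linear algebra ---------------------------------------------------------

ag_matmul <- function(a, b) {
  if (!.any_node(a, b)) return(a %*% b)
  av <- vof(a); bv <- vof(b)
  .ag(av %*% bv, list(a, b),
      list(function(g) g %*% t(bv), function(g) t(av) %*% g))
}

ag_t <- function(a) {
  if (!is_node(a)) return(t(a))
  .ag(t(vof(a)), list(a), list(function(g) t(g)))
}

ag_reshape <- function(a, dims) {
  if (!is_node(a)) { dim(a) <- dims; return(a) }
  av <- vof(a)
  od <- dim(av) %||% length(av)
  val <- av
  dim(val) <- dims
  .ag(val, list(a), list(function(g) { dim(g) <- od; g }))
}

# add a length-d row vector to every row of an n x d matrix
ag_add_rowvec <- function(a, b) {
  if (!.any_node(a, b)) return(sweep(a, 2, b, "+"))
  av <- vof(a); bv <- vof(b)
  .ag(sweep(av, 2, bv, "+"), list(a, b),
      list(function(g) g, function(g) colSums(g)))
}

ag_rows <- function(a, idx) {
  if (!is_node(a)) return(a[idx, , drop = FALSE])
  av <- vof(a)
  .ag(av[idx, , drop = FALSE], list(a),
      list(function(g) {
        out <- matrix(0, nrow(av), ncol(av))
        for (r in seq_along(idx)) out[idx[r], ] <- out[idx[r], ] + g[r, ]
        out
      }))
}

ag_cols <- function(a, idx) {
  if (!is_node(a)) return(a[, idx, drop = FALSE])
  av <- vof(a)
  .ag(av[, idx, drop = FALSE], list(a),
      list(function(g) {
        out <- matrix(0, nrow(av), ncol(av))
        for (j in seq_along(idx)) out[, idx[j]] <- out[, idx[j]] + g[, j]
        out
      }))
}

# column-bind a list of equal-height matrices
ag_cat_cols <- function(lst) {
  if (!any(vapply(lst, is_node, logical(1)))) return(do.call(cbind, lst))
  vals <- lapply(lst, vof)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  val <- do.call(cbind, vals)
  .ag(val, lst,
      lapply(seq_along(lst), function(i) {
        force(i)
        function(g) g[, starts[i]:ends[i], drop = FALSE]
      }))
}

# unit-normalize each row; eps keeps zero rows finite
ag_rownorm <- function(a, eps = 1e-12) {
  av <- vof(a)
  r <- sqrt(rowSums(av^2)) + eps
  y <- av / r
  if (!is_node(a)) return(y)
  .ag(y, list(a),
      list(function(g) (g - y * rowSums(g * y)) / r))
}

.rowmax <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# log-sum-exp along rows with an optional 0/1 inclusion mask
ag_lse_rows <- function(a, mask = NULL) {
  av <- vof(a)
  m <- if (is.null(mask)) matrix(1, nrow(av), ncol(av)) else mask
  work <- ifelse(m > 0, av, -Inf)
  mx <- .rowmax(work)
  val <- mx + log(rowSums(m * exp(av - mx)))
  if (!is_node(a)) return(val)
  sm <- m * exp(av - val)  # masked softmax rows
  .ag(val, list(a), list(function(g) sm * g))
}

ag_softmax_rows <- function(a) {
  av <- vof(a)
  mx <- .rowmax(av)
  e <- exp(av - mx)
  y <- e / rowSums(e)
  if (!is_node(a)) return(y)
  .ag(y, list(a),
      list(function(g) (g - rowSums(g * y)) * y))
}

# ---- normalization layers ---------------------------------------------------

# layer norm across columns of an n x d matrix (one normalization per row)
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- vof(a); gv <- vof(gamma); bv <- vof(beta)
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  isd <- 1 / sqrt(va + eps)
  xh <- xc * isd
  val <- sweep(xh, 2, gv, "*")
  val <- sweep(val, 2, bv, "+")
  if (!.any_node(a, gamma, beta)) return(val)
  .ag(val, list(a, gamma, beta),
      list(function(g) {
        dxh <- sweep(g, 2, gv, "*")
        (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * isd
      },
      function(g) colSums(g * xh),
      function(g) colSums(g)))
}

# instance norm over spatial dims of an (nx,ny,nz,C) array, per channel
ag_inorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- vof(a); gv <- vof(gamma); bv <- vof(beta)
  d <- dim(av)
  fw <- .inorm_fwd(av, d, gv, bv, eps)
  if (!.any_node(a, gamma, beta)) return(fw$y)
  bwd <- local({
    cache <- NULL
    function(g) {
      if (is.null(cache)) cache <<- .inorm_bwd(g, fw$xh, fw$isd, gv, d)
      cache
    }
  })
  .ag(fw$y, list(a, gamma, beta),
      list(function(g) bwd(g)$gx,
           function(g) bwd(g)$ggamma,
           function(g) bwd(g)$gbeta))
}

# ---- convolution ops (Rcpp kernels) ----------------------------------------

# x: (nx,ny,nz,Cin), w: (k,k,k,Cin,Cout), b: length Cout
ag_conv3 <- function(x, w, b, stride = 1L, pad = 1L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  val <- .conv3_fwd(xv, dim(xv), wv, dim(wv), bv, as.integer(stride), as.integer(pad))
  if (!.any_node(x, w, b)) return(val)
  ydim <- dim(val)
  .ag(val, list(x, w, b),
      list(function(g) .conv3_bwd_input(g, ydim, wv, dim(wv), dim(xv),
                                        as.integer(stride), as.integer(pad)),
           function(g) .conv3_bwd_weight(xv, dim(xv), g, ydim, dim(wv),
                                         as.integer(stride), as.integer(pad)),
           function(g) colSums(matrix(g, prod(ydim[1:3]), ydim[4]))))
}

# transposed convolution: kernel size == stride, zero pad; upsamples by
# `stride` per axis.  w: (s,s,s,Cout,Cin) in the adjoint-conv orientation.
ag_tconv3 <- function(x, w, b, stride = 2L) {
  xv <- vof(x); wv <- vof(w); bv <- vof(b)
  d <- dim(xv)
  co <- dim(wv)[4]
  odim <- c(d[1:3] * stride, co)
  s <- as.integer(stride)
  val <- .conv3_bwd_input(xv, dim(xv), wv, dim(wv), as.integer(odim), s, 0L)
  val <- val + rep(bv, each = prod(odim[1:3]))
  if (!.any_node(x, w, b)) return(val)
  .ag(val, list(x, w, b),
      list(function(g) .conv3_fwd(g, odim, wv, dim(wv), numeric(d[4]), s, 0L),
           function(g) .conv3_bwd_weight(g, odim, xv, dim(xv), dim(wv), s, 0L),
           function(g) colSums(matrix(g, prod(odim[1:3]), co))))
}

# concatenate two (nx,ny,nz,C) arrays along channels
ag_cat_ch <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  val <- array(c(av, bv), dim = c(da[1:3], da[4] + db[4]))
  if (!.any_node(a, b)) return(val)
  na <- length(av)
  .ag(val, list(a, b),
      list(function(g) array(g[seq_len(na)], dim = da),
           function(g) array(g[-seq_len(na)], dim = db)))
}

# extract one channel of an (nx,ny,nz,C) array as a 3D array
ag_channel <- function(a, i) {
  av <- vof(a)
  d <- dim(av)
  val <- array(av[, , , i], dim = d[1:3])
  if (!is_node(a)) return(val)
  .ag(val, list(a),
      list(function(g) {
        out <- array(0, dim = d)
        out[, , , i] <- g
        out
      }))
}

# max over non-overlapping p^3 patches of a 3D array
ag_patchmax <- function(a, p) {
  av <- vof(a)
  fw <- .patchmax_fwd(av, dim(av), as.integer(p))
  if (!is_node(a)) return(fw$q)
  d <- dim(av)
  .ag(fw$q, list(a),
      list(function(g) .patchmax_bwd(g, fw$idx, d)))
}
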