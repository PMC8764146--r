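# A minimal layer framework with explicit forward/backward passes. Layers are
# environments (mutable state: parameters, gradients, Adam moments, caches)
# carrying S3 classes; composites hold sub-layers. Gradients accumulate until
# nn_zero_grad() is called, mirroring the usual deep-learning convention.

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

#' @export
nn_forward <- function(layer, x, ...) UseMethod("nn_forward")

#' @export
nn_backward <- function(layer, grad, ...) UseMethod("nn_backward")

# flat list of parameter slots: each element list(env = <layer>, name = "W")
nn_param_slots <- function(layer) UseMethod("nn_param_slots")

#' @export
nn_param_slots.default <- function(layer) list()

nn_zero_grad <- function(layer) {
  for (s in nn_param_slots(layer)) {
    g <- paste0("g", s$name)
    assign(g, array(0, dim = dim_or_len(get(s$name, envir = s$env))), envir = s$env)
  }
  invisible(layer)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

kaiming_init <- function(fan_in, n, gain = 2) {
  stats::rnorm(n, sd = sqrt(gain / fan_in))
}

## ---- convolution -----------------------------------------------------------

conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                   bias = TRUE) {
  w <- matrix(kaiming_init(in_ch * k * k, in_ch * k * k * out_ch),
              nrow = in_ch * k * k, ncol = out_ch)
  new_layer("conv2d",
            in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            W = w, b = if (bias) numeric(out_ch) else NULL,
            gW = array(0, dim(w)), gb = if (bias) numeric(out_ch) else NULL,
            ix_cache = list(), cache = NULL)
}

#' @export
nn_forward.conv2d <- function(layer, x, ...) {
  d <- dim(x)
  if (d[2L] != layer$in_ch) {
    stop(sprintf("conv2d expects %d input channels, got %d", layer$in_ch, d[2L]))
  }
  key <- paste(d[2L], d[3L], d[4L], sep = "x")
  ix <- layer$ix_cache[[key]]
  if (is.null(ix)) {
    ix <- im2col_index(d[2L], d[3L], d[4L], layer$k, layer$stride, layer$pad)
    layer$ix_cache[[key]] <- ix
  }
  out <- array(0, dim = c(d[1L], layer$out_ch, ix$Ho, ix$Wo))
  Ms <- vector("list", d[1L])
  for (b in seq_len(d[1L])) {
    r <- conv_single(batch_slice(x, b), layer$W, layer$b,
                     layer$k, layer$stride, layer$pad, ix)
    out[b, , , ] <- r$out
    Ms[[b]] <- r$M
  }
  layer$cache <- list(Ms = Ms, in_dim = d, ix = ix)
  out
}

#' @export
nn_backward.conv2d <- function(layer, grad, ...) {
  cc <- layer$cache
  d <- cc$in_dim
  dx <- array(0, dim = d)
  for (b in seq_len(d[1L])) {
    dyb <- batch_slice(grad, b)                       # (O, Ho, Wo)
    dy_mat <- t(matrix(dyb, nrow = layer$out_ch))     # (Npos, O)
    layer$gW <- layer$gW + crossprod(cc$Ms[[b]], dy_mat)
    if (!is.null(layer$b)) layer$gb <- layer$gb + colSums(dy_mat)
    dM <- dy_mat %*% t(layer$W)
    dx[b, , , ] <- col2im_grad(dM, cc$ix, d[2L], d[3L], d[4L], layer$pad)
  }
  dx
}

#' @export
nn_param_slots.conv2d <- function(layer) {
  out <- list(list(env = layer, name = "W"))
  if (!is.null(layer$b)) out <- c(out, list(list(env = layer, name = "b")))
  out
}

## ---- activations -----------------------------------------------------------

act_relu <- function() new_layer("act_relu", cache = NULL)

#' @export
nn_forward.act_relu <- function(layer, x, ...) {
  y <- pmax(x, 0)
  layer$cache <- x > 0
  y
}

#' @export
nn_backward.act_relu <- function(layer, grad, ...) grad * layer$cache

act_lrelu <- function(slope = 0.2) new_layer("act_lrelu", slope = slope, cache = NULL)

#' @export
nn_forward.act_lrelu <- function(layer, x, ...) {
  layer$cache <- x > 0
  ifelse2 <- x * layer$slope
  ifelse2[layer$cache] <- x[layer$cache]
  array(ifelse2, dim = dim(x))
}

#' @export
nn_backward.act_lrelu <- function(layer, grad, ...) {
  g <- grad * layer$slope
  g[layer$cache] <- grad[layer$cache]
  array(g, dim = dim(grad))
}

act_sigmoid <- function() new_layer("act_sigmoid", cache = NULL)

#' @export
nn_forward.act_sigmoid <- function(layer, x, ...) {
  y <- 1 / (1 + exp(-x))
  layer$cache <- y
  y
}

#' @export
nn_backward.act_sigmoid <- function(layer, grad, ...) {
  y <- layer$cache
  grad * y * (1 - y)
}

## ---- fixed bilinear resize (up or down) ------------------------------------

resize_layer <- function(scale = NULL, out_hw = NULL) {
  new_layer("resize_layer", scale = scale, out_hw = out_hw,
            A_cache = list(), cache = NULL)
}

#' @export
nn_forward.resize_layer <- function(layer, x, ...) {
  d <- dim(x)
  hw <- if (!is.null(layer$out_hw)) layer$out_hw else
    c(d[3L] * layer$scale, d[4L] * layer$scale)
  key <- paste(d[3L], d[4L], hw[1L], hw[2L], sep = "x")
  A <- layer$A_cache[[key]]
  if (is.null(A)) {
    A <- list(Ah = bilinear_matrix(d[3L], hw[1L]), Aw = bilinear_matrix(d[4L], hw[2L]))
    layer$A_cache[[key]] <- A
  }
  layer$cache <- list(A = A, H = d[3L], W = d[4L])
  resize_fm(x, hw[1L], hw[2L], A$Ah, A$Aw)
}

#' @export
nn_backward.resize_layer <- function(layer, grad, ...) {
  cc <- layer$cache
  resize_fm_grad(grad, cc$A$Ah, cc$A$Aw, cc$H, cc$W)
}

## ---- sequential container --------------------------------------------------

nn_sequential <- function(...) new_layer("nn_sequential", layers = list(...))

#' @export
nn_forward.nn_sequential <- function(layer, x, ...) {
  for (l in layer$layers) x <- nn_forward(l, x)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, grad, ...) {
  for (l in rev(layer$layers)) grad <- nn_backward(l, grad)
  grad
}

#' @export
nn_param_slots.nn_sequential <- function(layer) {
  do.call(c, lapply(layer$layers, nn_param_slots))
}

## ---- residual block (two 3x3 convs, projection shortcut when needed) -------

res_block <- function(in_ch, out_ch, stride = 1L) {
  proj <- if (stride != 1L || in_ch != out_ch) conv2d(in_ch, out_ch, 1L, stride, 0L) else NULL
  new_layer("res_block",
            conv1 = conv2d(in_ch, out_ch, 3L, stride),
            relu1 = act_relu(),
            conv2 = conv2d(out_ch, out_ch, 3L, 1L),
            proj = proj,
            relu2 = act_relu())
}

#' @export
nn_forward.res_block <- function(layer, x, ...) {
  h <- nn_forward(layer$relu1, nn_forward(layer$conv1, x))
  h <- nn_forward(layer$conv2, h)
  s <- if (is.null(layer$proj)) x else nn_forward(layer$proj, x)
  nn_forward(layer$relu2, h + s)
}

#' @export
nn_backward.res_block <- function(layer, grad, ...) {
  g <- nn_backward(layer$relu2, grad)
  gs <- if (is.null(layer$proj)) g else nn_backward(layer$proj, g)
  gh <- nn_backward(layer$conv1, nn_backward(layer$relu1, nn_backward(layer$conv2, g)))
  gh + gs
}

#' @export
nn_param_slots.res_block <- function(layer) {
  out <- c(nn_param_slots(layer$conv1), nn_param_slots(layer$conv2))
  if (!is.null(layer$proj)) out <- c(out, nn_param_slots(layer$proj))
  out
}

## ---- Adam ------------------------------------------------------------------

# Adam with L2 weight decay added to the gradient (the framework-standard
# coupled form). State (first/second moments) lives beside each parameter.
adam_optimizer <- function(model, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, weight_decay = 0) {
  st <- new.env(parent = emptyenv())
  st$slots <- nn_param_slots(model)
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay; st$t <- 0L
  for (s in st$slots) {
    p <- get(s$name, envir = s$env)
    assign(paste0("adam_m_", s$name), array(0, dim_or_len(p)), envir = s$env)
    assign(paste0("adam_v_", s$name), array(0, dim_or_len(p)), envir = s$env)
  }
  class(st) <- "adam_optimizer"
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (s in opt$slots) {
    p <- get(s$name, envir = s$env)
    g <- get(paste0("g", s$name), envir = s$env)
    if (opt$wd > 0) g <- g + opt$wd * p
    m <- get(paste0("adam_m_", s$name), envir = s$env)
    v <- get(paste0("adam_v_", s$name), envir = s$env)
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g * g
    pd <- dim(p)
    p <- p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    if (is.null(pd)) p <- as.vector(p) else dim(p) <- pd
    assign(s$name, p, envir = s$env)
    assign(paste0("adam_m_", s$name), m, envir = s$env)
    assign(paste0("adam_v_", s$name), v, envir = s$env)
  }
  invisible(opt)
}

## ---- weight export / import (checkpointing) --------------------------------

get_weights <- function(model) {
  slots <- nn_param_slots(model)
  out <- vector("list", length(slots))
  for (i in seq_along(slots)) out[[i]] <- get(slots[[i]]$name, envir = slots[[i]]$env)
  out
}

set_weights <- function(model, weights) {
  slots <- nn_param_slots(model)
  if (length(slots) != length(weights)) {
    stop(sprintf("weight list has %d tensors but model has %d parameter slots",
                 length(weights), length(slots)))
  }
  for (i in seq_along(slots)) {
    cur <- get(slots[[i]]$name, envir = slots[[i]]$env)
    if (!identical(dim_or_len(cur), dim_or_len(weights[[i]]))) {
      stop(sprintf("weight tensor %d has mismatched shape", i))
    }
    assign(slots[[i]]$name, weights[[i]], envir = slots[[i]]$env)
  }
  invisible(model)
}
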