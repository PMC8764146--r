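# The multi-scale self-transformer (MsST) bottleneck: mid-level encoder
# features are bilinearly downsampled and 3x3-convolved to the top stage's
# shape, summed into a fused map F_A, and a single query/key/value spatial
# self-attention is computed with the query taken from F_A and key/value from
# the top-stage map F_T. The attended response F_M is blended back as
# F_final = F_T + gamma * F_M, with gamma a learnable scalar initialised at 0
# so the block starts as an identity on F_T.
#
# Dot products are not scaled by 1/sqrt(d); the softmax is taken over the key
# axis so each query row is a convex combination of value vectors. Spatial
# positions are flattened row-major (row index varies slowest).

#' Construct MsST block parameters
#'
#' Builds the parameter set of the multi-scale self-transformer block: 1x1
#' projections for query/key/value, one 3x3 convolution per contributing
#' encoder stage (applied after bilinear downsampling to the top stage's
#' spatial size), and the scalar blend weight `gamma`.
#'
#' @param top_channels number of channels `C` of the top-stage feature map.
#' @param reduction channel reduction factor `r`; query and key are projected
#'   to `C / r` channels. `C` must be divisible by `r`.
#' @param in_channels integer vector of length 3: channel counts of the three
#'   contributing encoder stages (defaults to `top_channels` for each).
#' @param gamma initial value of the scalar blend weight (0, the identity
#'   initialisation, unless overridden).
#' @return an object of class `msst_params` (also a usable network layer).
#' @export
msst_params <- function(top_channels, reduction = 8L,
                        in_channels = rep(top_channels, 3L), gamma = 0) {
  top_channels <- as.integer(top_channels)
  reduction <- as.integer(reduction)
  if (top_channels %% reduction != 0L) {
    stop(sprintf("top_channels (%d) must be divisible by reduction (%d)",
                 top_channels, reduction))
  }
  if (length(in_channels) != 3L) stop("in_channels must list the 3 stage channel counts")
  cr <- top_channels %/% reduction
  l <- new_layer(c("msst_params"),
                 top_channels = top_channels, reduction = reduction,
                 cr = cr,
                 ds1 = conv2d(in_channels[1L], top_channels, 3L),
                 ds2 = conv2d(in_channels[2L], top_channels, 3L),
                 ds3 = conv2d(in_channels[3L], top_channels, 3L),
                 q_conv = conv2d(top_channels, cr, 1L, pad = 0L),
                 k_conv = conv2d(top_channels, cr, 1L, pad = 0L),
                 v_conv = conv2d(top_channels, top_channels, 1L, pad = 0L),
                 rs1 = resize_layer(), rs2 = resize_layer(), rs3 = resize_layer(),
                 gamma = gamma, ggamma = 0,
                 cache = NULL)
  l
}

#' @export
nn_param_slots.msst_params <- function(layer) {
  c(nn_param_slots(layer$ds1), nn_param_slots(layer$ds2), nn_param_slots(layer$ds3),
    nn_param_slots(layer$q_conv), nn_param_slots(layer$k_conv), nn_param_slots(layer$v_conv),
    list(list(env = layer, name = "gamma")))
}

#' Project fused and top-stage maps to query, key and value
#'
#' Applies the block's 1x1 convolutions: the query derives from the fused
#' multi-scale map `f_a`, key and value from the top-stage map `f_t`.
#'
#' @param f_a fused multi-scale feature map, (B, C, H, W).
#' @param f_t top-stage feature map, same shape as `f_a`.
#' @param params an [msst_params()] object.
#' @return list with elements `q` (C/r channels), `k` (C/r), `v` (C channels).
#' @export
project_qkv <- function(f_a, f_t, params) {
  check_feature_map(f_a, "f_a"); check_feature_map(f_t, "f_t")
  if (!identical(dim(f_a), dim(f_t))) {
    stop(sprintf("f_a and f_t must have identical shapes; got (%s) and (%s)",
                 paste(dim(f_a), collapse = ","), paste(dim(f_t), collapse = ",")))
  }
  if (dim(f_a)[2L] != params$top_channels) {
    stop(sprintf("expected %d channels, got %d", params$top_channels, dim(f_a)[2L]))
  }
  list(q = nn_forward(params$q_conv, f_a),
       k = nn_forward(params$k_conv, f_t),
       v = nn_forward(params$v_conv, f_t))
}

#' Spatial attention map from query and key
#'
#' Flattens spatial positions row-major, forms the (H*W) x (H*W) energy matrix
#' of channel-vector dot products between query positions and key positions,
#' and softmax-normalises each query row over the key axis.
#'
#' @param q query feature map, (B, C/r, H, W).
#' @param k key feature map, same shape as `q`.
#' @return attention array (B, H*W, H*W); rows sum to 1.
#' @export
compute_attention <- function(q, k) {
  check_feature_map(q, "q"); check_feature_map(k, "k")
  if (!identical(dim(q), dim(k))) {
    stop(sprintf("q and k must have identical shapes; got (%s) and (%s)",
                 paste(dim(q), collapse = ","), paste(dim(k), collapse = ",")))
  }
  d <- dim(q)
  n <- d[3L] * d[4L]
  att <- array(0, dim = c(d[1L], n, n))
  for (b in seq_len(d[1L])) {
    qf <- flatten_rowmajor(batch_slice(q, b))   # (Cr, N)
    kf <- flatten_rowmajor(batch_slice(k, b))
    e <- crossprod(qf, kf)                      # (N, N): e[i, j] = q_i . k_j
    e <- e - apply(e, 1L, max)                  # rowwise shift for stability
    ex <- exp(e)
    att[b, , ] <- ex / rowSums(ex)
  }
  att
}

#' Apply an attention map to a value feature map
#'
#' Each output position i is the attention-weighted sum over positions j of
#' the value channel vectors, using row i of the attention map.
#'
#' @param v value feature map, (B, C, H, W).
#' @param att attention array (B, H*W, H*W), e.g. from [compute_attention()].
#' @return feature map of the same shape as `v`.
#' @export
apply_attention <- function(v, att) {
  check_feature_map(v, "v")
  d <- dim(v)
  n <- d[3L] * d[4L]
  if (length(dim(att)) != 3L || dim(att)[2L] != n || dim(att)[3L] != n ||
      dim(att)[1L] != d[1L]) {
    stop(sprintf("attention map (%s) does not match value map spatial size %d",
                 paste(dim(att), collapse = ","), n))
  }
  out <- array(0, dim = d)
  for (b in seq_len(d[1L])) {
    vf <- flatten_rowmajor(batch_slice(v, b))            # (C, N)
    fm <- vf %*% t(matrix(att[b, , ], n, n))             # out_i = sum_j att[i,j] v_j
    out[b, , , ] <- unflatten_rowmajor(fm, d[3L], d[4L])
  }
  out
}

#' Brute-force attention reference (test oracle)
#'
#' Computes the attention response with explicit nested loops over query
#' positions, key positions and channels — no vectorised shortcuts. Used only
#' to validate the fast path.
#'
#' @inheritParams compute_attention
#' @param v value feature map, (B, C, H, W).
#' @return feature map of the same shape as `v`.
#' @export
attention_oracle <- function(q, k, v) {
  check_feature_map(q, "q"); check_feature_map(k, "k"); check_feature_map(v, "v")
  if (!identical(dim(q), dim(k))) stop("q and k must have identical shapes")
  dq <- dim(q); dv <- dim(v)
  if (!identical(dq[c(1L, 3L, 4L)], dv[c(1L, 3L, 4L)])) {
    stop("v must share batch and spatial dims with q/k")
  }
  B <- dq[1L]; H <- dq[3L]; W <- dq[4L]; n <- H * W
  pos <- cbind(rep(seq_len(H), each = W), rep(seq_len(W), times = H)) # row-major
  out <- array(0, dim = dv)
  for (b in seq_len(B)) {
    energy <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0
      for (c in seq_len(dq[2L])) {
        s <- s + q[b, c, pos[i, 1L], pos[i, 2L]] * k[b, c, pos[j, 1L], pos[j, 2L]]
      }
      energy[i, j] <- s
    }
    att <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ex <- exp(energy[i, ] - max(energy[i, ]))
      att[i, ] <- ex / sum(ex)
    }
    for (c in seq_len(dv[2L])) for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) s <- s + att[i, j] * v[b, c, pos[j, 1L], pos[j, 2L]]
      out[b, c, pos[i, 1L], pos[i, 2L]] <- s
    }
  }
  out
}

#' MsST block forward pass
#'
#' Downsamples the three mid-stage maps to the top stage's spatial size,
#' convolves each to the top channel count, sums them into the fused map F_A,
#' computes query/key/value attention (query from F_A, key and value from
#' `f_t`) and returns `f_t + gamma * F_M`.
#'
#' @param f1,f2,f3 feature maps from the three mid encoder stages; each must be
#'   at least as large spatially as `f_t`.
#' @param f_t top-stage feature map, (B, C, H, W).
#' @param params an [msst_params()] object.
#' @return feature map with the same shape as `f_t`.
#' @export
msst_forward <- function(f1, f2, f3, f_t, params) {
  check_feature_map(f_t, "f_t")
  ht <- dim(f_t)[3L]; wt <- dim(f_t)[4L]
  for (nm in c("f1", "f2", "f3")) {
    f <- get(nm)
    check_feature_map(f, nm)
    if (dim(f)[3L] < ht || dim(f)[4L] < wt) {
      stop(sprintf("`%s` (%dx%d) is spatially smaller than f_t (%dx%d); cannot downsample upward",
                   nm, dim(f)[3L], dim(f)[4L], ht, wt))
    }
  }
  for (rs in list(params$rs1, params$rs2, params$rs3)) rs$out_hw <- c(ht, wt)
  a1 <- nn_forward(params$ds1, nn_forward(params$rs1, f1))
  a2 <- nn_forward(params$ds2, nn_forward(params$rs2, f2))
  a3 <- nn_forward(params$ds3, nn_forward(params$rs3, f3))
  f_a <- a1 + a2 + a3
  qkv <- project_qkv(f_a, f_t, params)
  att <- compute_attention(qkv$q, qkv$k)
  f_m <- apply_attention(qkv$v, att)
  params$cache <- list(att = att, f_m = f_m, q = qkv$q, k = qkv$k, v = qkv$v,
                       ht = ht, wt = wt)
  f_t + params$gamma * f_m
}

#' @export
nn_forward.msst_params <- function(layer, x, ...) {
  # x is a list(f1, f2, f3, f_t) when used inside the segmentor
  msst_forward(x[[1L]], x[[2L]], x[[3L]], x[[4L]], layer)
}

#' @export
nn_backward.msst_params <- function(layer, grad, ...) {
  cc <- layer$cache
  H <- cc$ht; W <- cc$wt; n <- H * W
  B <- dim(grad)[1L]
  layer$ggamma <- layer$ggamma + sum(grad * cc$f_m)
  dfm <- layer$gamma * grad
  dq <- array(0, dim = dim(cc$q))
  dk <- array(0, dim = dim(cc$k))
  dv <- array(0, dim = dim(cc$v))
  for (b in seq_len(B)) {
    dfm_f <- flatten_rowmajor(batch_slice(dfm, b))     # (C, N)
    vf <- flatten_rowmajor(batch_slice(cc$v, b))
    attb <- matrix(cc$att[b, , ], n, n)
    dv[b, , , ] <- unflatten_rowmajor(dfm_f %*% attb, H, W)
    datt <- crossprod(dfm_f, vf)                       # (N, N)
    # softmax backward, rowwise over keys
    de <- attb * (datt - rowSums(datt * attb))
    qf <- flatten_rowmajor(batch_slice(cc$q, b))
    kf <- flatten_rowmajor(batch_slice(cc$k, b))
    dq[b, , , ] <- unflatten_rowmajor(kf %*% t(de), H, W)
    dk[b, , , ] <- unflatten_rowmajor(qf %*% de, H, W)
  }
  dfa <- nn_backward(layer$q_conv, dq)
  dft <- grad + nn_backward(layer$k_conv, dk) + nn_backward(layer$v_conv, dv)
  df1 <- nn_backward(layer$rs1, nn_backward(layer$ds1, dfa))
  df2 <- nn_backward(layer$rs2, nn_backward(layer$ds2, dfa))
  df3 <- nn_backward(layer$rs3, nn_backward(layer$ds3, dfa))
  list(df1, df2, df3, dft)
}
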