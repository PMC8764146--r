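# Low-level array primitives shared by the network layers: im2col convolution,
# fixed bilinear resampling, and small helpers. Feature maps are 4-d arrays in
# (batch, channel, row, column) layout throughout the package.

#' Validate a feature map array
#'
#' Checks that `x` is a finite numeric 4-d array in (batch, channel, row,
#' column) layout with all dimensions at least 1.
#'
#' @param x object to validate.
#' @param name label used in error messages.
#' @return `x`, invisibly.
#' @export
check_feature_map <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop(sprintf("`%s` must be a 4-d array (batch, channel, row, column)", name))
  }
  if (!all(is.finite(x))) stop(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}

# slice one batch item, keeping the (C, H, W) dims
batch_slice <- function(x, b) {
  d <- dim(x)
  array(x[b, , , , drop = FALSE], dim = d[-1])
}

conv_out_size <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

# gather-index matrix for im2col: rows = output positions (column-major over
# (Ho, Wo)), cols = (channel, kh, kw) in column-major order of (C, k, k).
im2col_index <- function(C, H, W, k, s, p) {
  Hp <- H + 2L * p
  Ho <- conv_out_size(H, k, s, p)
  Wo <- conv_out_size(W, k, s, p)
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  cj  <- rep(seq_len(C), times = k * k)
  khj <- rep(rep(seq_len(k), each = C), times = k)
  kwj <- rep(seq_len(k), each = C * k)
  hh <- outer((oh - 1L) * s, khj, "+")       # padded row index (1-based)
  ww <- outer((ow - 1L) * s, kwj, "+")
  n_pos <- Ho * Wo
  idx <- matrix(rep(cj, each = n_pos), n_pos) + C * (hh - 1L) + (C * Hp) * (ww - 1L)
  list(idx = idx, Ho = Ho, Wo = Wo)
}

pad_chw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p))
  xp[, (p + 1L):(p + d[2L]), (p + 1L):(p + d[3L])] <- x
  xp
}

unpad_chw <- function(xp, p, H, W) {
  if (p == 0L) return(xp)
  xp[, (p + 1L):(p + H), (p + 1L):(p + W), drop = FALSE]
}

# single-item convolution: x (C,H,W), wmat (C*k*k, O). Returns list with the
# output (O,Ho,Wo) and the im2col matrix for reuse in the backward pass.
conv_single <- function(x, wmat, bias, k, s, p, ix) {
  xp <- pad_chw(x, p)
  M <- matrix(as.vector(xp)[ix$idx], nrow = nrow(ix$idx))
  y <- M %*% wmat
  if (!is.null(bias)) y <- sweep(y, 2L, bias, "+")
  list(out = array(t(y), dim = c(ncol(wmat), ix$Ho, ix$Wo)), M = M)
}

# scatter-accumulate the im2col gradient back onto the (padded) input
col2im_grad <- function(dM, ix, C, H, W, p) {
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  acc <- rowsum(as.vector(dM), group = as.vector(ix$idx))
  dxp <- numeric(C * Hp * Wp)
  dxp[as.integer(rownames(acc))] <- acc
  unpad_chw(array(dxp, dim = c(C, Hp, Wp)), p, H, W)
}

# interpolation weight matrix (n_out x n_in) for 1-d bilinear resampling with
# half-pixel (non-aligned-corner) source coordinates
bilinear_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  sc <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * sc - 0.5
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src)
    i1 <- min(i0 + 1, n_in - 1)
    f <- src - i0
    A[i, i0 + 1] <- A[i, i0 + 1] + (1 - f)
    A[i, i1 + 1] <- A[i, i1 + 1] + f
  }
  A
}

# nearest-neighbour variant (used for masks so labels stay binary)
nearest_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  sc <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * sc - 0.5
    j <- min(max(round(src), 0), n_in - 1)
    A[i, j + 1] <- 1
  }
  A
}

# resize a (B,C,H,W) feature map to (ho, wo); Ah/Aw may be precomputed
resize_fm <- function(x, ho, wo, Ah = NULL, Aw = NULL) {
  d <- dim(x)
  if (is.null(Ah)) Ah <- bilinear_matrix(d[3L], ho)
  if (is.null(Aw)) Aw <- bilinear_matrix(d[4L], wo)
  out <- array(0, dim = c(d[1L], d[2L], ho, wo))
  for (b in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    out[b, c, , ] <- Ah %*% x[b, c, , ] %*% t(Aw)
  }
  out
}

resize_fm_grad <- function(dy, Ah, Aw, H, W) {
  d <- dim(dy)
  dx <- array(0, dim = c(d[1L], d[2L], H, W))
  for (b in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    dx[b, c, , ] <- t(Ah) %*% dy[b, c, , ] %*% Aw
  }
  dx
}

# flatten spatial positions row-major (row index varies slowest): (C,H,W) -> (C, H*W)
flatten_rowmajor <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 3L, 2L)), nrow = d[1L])
}

unflatten_rowmajor <- function(m, H, W) {
  aperm(array(m, dim = c(nrow(m), W, H)), c(1L, 3L, 2L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# separable Gaussian blur of a matrix (used to soften synthetic lesion blobs)
gaussian_blur_mat <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(k)
  H <- nrow(m); W <- ncol(m)
  Ah <- matrix(0, H, H)
  for (i in seq_len(H)) {
    j <- clamp((i - r):(i + r), 1L, H)
    for (t in seq_len(n)) Ah[i, j[t]] <- Ah[i, j[t]] + k[t]
  }
  Aw <- if (W == H) Ah else {
    Aw0 <- matrix(0, W, W)
    for (i in seq_len(W)) {
      j <- clamp((i - r):(i + r), 1L, W)
      for (t in seq_len(n)) Aw0[i, j[t]] <- Aw0[i, j[t]] + k[t]
    }
    Aw0
  }
  Ah %*% m %*% t(Aw)
}

# label 4-connected components of a logical matrix by iterative label
# propagation; returns an integer matrix (0 = background)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  lab[!mask] <- NA_integer_
  repeat {
    nb <- lab
    nb[-1, ]  <- pmin(nb[-1, ],  lab[-H, ], na.rm = TRUE)
    nb[-H, ]  <- pmin(nb[-H, ],  lab[-1, ], na.rm = TRUE)
    nb[, -1]  <- pmin(nb[, -1],  lab[, -W], na.rm = TRUE)
    nb[, -W]  <- pmin(nb[, -W],  lab[, -1], na.rm = TRUE)
    nb[is.na(lab)] <- NA_integer_
    if (identical(nb, lab)) break
    lab <- nb
  }
  lab[is.na(lab)] <- 0L
  keep <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], keep)
  lab
}
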