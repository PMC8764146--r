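# shared helpers: small random feature maps, finite-difference gradients and
# a cached tiny dataset on disk

rand_fm <- function(B, C, H, W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(B * C * H * W), dim = c(B, C, H, W))
}

# central finite difference of f (scalar function of a numeric array) at x[i]
num_grad_at <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- x[i] + eps
  xm <- x; xm[i] <- x[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

# identity-weight 1x1 convolution (C -> C), used to force pass-through paths
set_identity_1x1 <- function(conv) {
  stopifnot(conv$k == 1L, conv$in_ch == conv$out_ch)
  conv$W <- diag(conv$in_ch)
  if (!is.null(conv$b)) conv$b <- numeric(conv$out_ch)
  invisible(conv)
}

# one tiny labeled+unlabeled dataset per test session
tiny_dataset <- local({
  man <- NULL
  function() {
    if (is.null(man)) {
      dir <- file.path(tempdir(), "fluoroseg-tiny-ds")
      unlink(dir, recursive = TRUE)
      man <<- generate_dataset(8, 8, size = 64, master_seed = 1, outdir = dir)
    }
    man
  }
})

held_out_set <- function(n = 8, size = 64, seed0 = 9000) {
  lapply(seq_len(n), function(i) {
    generate_sample(if (i %% 2 == 1) "flaky" else "point_flaky", size, seed0 + i)
  })
}

mean_heldout_dice <- function(G, held, threshold = 0.5) {
  hb <- fluoroseg:::stack_batch(held, with_masks = TRUE)
  pp <- segment(G, hb$images)
  n <- dim(pp)[3L]
  mean(vapply(seq_along(held), function(b) {
    dsc(confusion(binarize(matrix(pp[b, 1L, , ], n), threshold), held[[b]]$mask))
  }, numeric(1)))
}
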