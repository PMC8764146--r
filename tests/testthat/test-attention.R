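test_that("query/key/value projections have the contracted channel counts and sources", {
  set.seed(1)
  mp <- msst_params(8, reduction = 8)
  f_a <- rand_fm(1, 8, 3, 3)
  f_t <- rand_fm(1, 8, 3, 3)
  qkv <- project_qkv(f_a, f_t, mp)
  expect_equal(dim(qkv$q), c(1, 1, 3, 3))
  expect_equal(dim(qkv$k), c(1, 1, 3, 3))
  expect_equal(dim(qkv$v), c(1, 8, 3, 3))

  # q depends only on f_a; k and v only on f_t
  qkv2 <- project_qkv(f_a, rand_fm(1, 8, 3, 3), mp)
  expect_identical(qkv$q, qkv2$q)
  expect_false(identical(qkv$v, qkv2$v))
  qkv3 <- project_qkv(rand_fm(1, 8, 3, 3), f_t, mp)
  expect_identical(qkv$k, qkv3$k)
  expect_identical(qkv$v, qkv3$v)

  expect_error(project_qkv(f_a, rand_fm(1, 8, 4, 4), mp), "identical shapes")
  expect_error(msst_params(9, reduction = 8), "divisible")
})

test_that("identity-initialised 1x1 projection with r = 1 passes features through", {
  mp <- msst_params(4, reduction = 1)
  set_identity_1x1(mp$q_conv)
  f_a <- rand_fm(1, 4, 3, 3, seed = 2)
  qkv <- project_qkv(f_a, f_a, mp)
  expect_equal(qkv$q, f_a, tolerance = 1e-12)
})

test_that("projection equals an explicit per-position matrix product", {
  set.seed(3)
  mp <- msst_params(8, reduction = 8)
  f_a <- rand_fm(1, 8, 3, 3)
  f_t <- rand_fm(1, 8, 3, 3)
  qkv <- project_qkv(f_a, f_t, mp)
  # 1x1 conv = per-pixel product of the weight matrix with the channel vector
  W <- mp$q_conv$W   # (8 x 1)
  b <- mp$q_conv$b
  for (h in 1:3) for (w in 1:3) {
    expect_equal(qkv$q[1, 1, h, w],
                 sum(W[, 1] * f_a[1, , h, w]) + b[1], tolerance = 1e-12)
  }
})

test_that("attention of constant energy is uniform and rows always sum to one", {
  z <- array(0, dim = c(1, 2, 2, 2))
  att <- compute_attention(z, z)
  expect_equal(dim(att), c(1, 4, 4))
  expect_true(all(abs(att - 0.25) < 1e-12))

  for (s in 1:5) {
    q <- rand_fm(2, 3, 3, 2, seed = s)
    k <- rand_fm(2, 3, 3, 2, seed = s + 100)
    a <- compute_attention(q, k)
    expect_true(all(a >= 0 & a <= 1))
    expect_true(all(abs(apply(a, c(1, 2), sum) - 1) < 1e-5))
  }
  expect_error(compute_attention(rand_fm(1, 2, 2, 2), rand_fm(1, 2, 3, 3)),
               "identical shapes")
})

test_that("attention weights match an explicit softmax double loop", {
  q <- rand_fm(1, 2, 2, 2, seed = 11)
  k <- rand_fm(1, 2, 2, 2, seed = 12)
  att <- compute_attention(q, k)
  pos <- cbind(rep(1:2, each = 2), rep(1:2, times = 2))  # row-major
  for (i in 1:4) {
    e <- numeric(4)
    for (j in 1:4) {
      e[j] <- sum(q[1, , pos[i, 1], pos[i, 2]] * k[1, , pos[j, 1], pos[j, 2]])
    }
    expect_equal(att[1, i, ], exp(e) / sum(exp(e)), tolerance = 1e-12)
  }
})

test_that("applying attention reduces to identity, averaging and the loop oracle", {
  v <- rand_fm(1, 3, 2, 2, seed = 13)
  ident <- array(0, dim = c(1, 4, 4)); ident[1, , ] <- diag(4)
  expect_equal(apply_attention(v, ident), v, tolerance = 1e-12)

  unif <- array(1 / 4, dim = c(1, 4, 4))
  out <- apply_attention(v, unif)
  for (c in 1:3) {
    expect_true(all(abs(out[1, c, , ] - mean(v[1, c, , ])) < 1e-12))
  }

  att <- compute_attention(rand_fm(1, 2, 2, 2, seed = 14),
                           rand_fm(1, 2, 2, 2, seed = 15))
  fast <- apply_attention(v, att)
  pos <- cbind(rep(1:2, each = 2), rep(1:2, times = 2))
  for (c in 1:3) for (i in 1:4) {
    s <- 0
    for (j in 1:4) s <- s + att[1, i, j] * v[1, c, pos[j, 1], pos[j, 2]]
    expect_equal(fast[1, c, pos[i, 1], pos[i, 2]], s, tolerance = 1e-12)
  }
  expect_error(apply_attention(v, array(1 / 9, dim = c(1, 9, 9))),
               "does not match")
})

test_that("oracle handles the uniform limit and degenerate 1x1 inputs", {
  v <- rand_fm(1, 3, 2, 2, seed = 16)
  z <- array(0, dim = c(1, 2, 2, 2))
  out <- attention_oracle(z, z, v)
  for (c in 1:3) expect_true(all(abs(out[1, c, , ] - mean(v[1, c, , ])) < 1e-12))

  q1 <- rand_fm(1, 2, 1, 1, seed = 17)
  v1 <- rand_fm(1, 5, 1, 1, seed = 18)
  expect_equal(attention_oracle(q1, q1, v1), v1, tolerance = 1e-12)
})

test_that("vectorised attention agrees with the brute-force oracle on random instances", {
  set.seed(19)
  for (r in 1:50) {
    B <- sample(1:2, 1); Cr <- sample(1:4, 1); C <- sample(1:8, 1)
    H <- sample(1:4, 1)
    q <- rand_fm(B, Cr, H, H); k <- rand_fm(B, Cr, H, H); v <- rand_fm(B, C, H, H)
    fast <- apply_attention(v, compute_attention(q, k))
    expect_lt(max(abs(fast - attention_oracle(q, k, v))), 1e-5)
  }
})

test_that("attention is equivariant under consistent spatial permutation", {
  set.seed(20)
  H <- 3
  perm <- sample(H * H)
  permute_fm <- function(x) {
    m <- fluoroseg:::flatten_rowmajor(array(x[1, , , ], dim(x)[-1]))
    out <- fluoroseg:::unflatten_rowmajor(m[, perm, drop = FALSE], H, H)
    array(out, dim = dim(x))
  }
  q <- rand_fm(1, 2, H, H); k <- rand_fm(1, 2, H, H); v <- rand_fm(1, 4, H, H)
  base <- apply_attention(v, compute_attention(q, k))
  permuted <- apply_attention(permute_fm(v),
                              compute_attention(permute_fm(q), permute_fm(k)))
  expect_equal(permuted, permute_fm(base), tolerance = 1e-10)
})

test_that("the block is an exact identity at gamma = 0 and conserves shape", {
  for (s in 1:5) {
    set.seed(s)
    mp <- msst_params(8, reduction = 8, in_channels = c(4, 6, 8))
    f1 <- rand_fm(1, 4, 16, 16); f2 <- rand_fm(1, 6, 8, 8)
    f3 <- rand_fm(1, 8, 8, 8); ft <- rand_fm(1, 8, 4, 4)
    out <- msst_forward(f1, f2, f3, ft, mp)
    expect_identical(dim(out), dim(ft))
    expect_equal(max(abs(out - ft)), 0)
  }
  set.seed(1)
  mp <- msst_params(8, reduction = 8)
  small <- rand_fm(1, 8, 2, 2); ft <- rand_fm(1, 8, 4, 4)
  expect_error(msst_forward(small, ft, ft, ft, mp), "smaller than f_t")
})

test_that("gamma = 1 with identity value projection doubles a 1x1 top map", {
  set.seed(2)
  mp <- msst_params(4, reduction = 1)
  mp$gamma <- 1
  set_identity_1x1(mp$v_conv)
  # 1x1 spatial extent makes the softmax attention the identity
  f <- rand_fm(1, 4, 1, 1)
  out <- msst_forward(rand_fm(1, 4, 2, 2), rand_fm(1, 4, 2, 2),
                      rand_fm(1, 4, 1, 1), f, mp)
  expect_equal(out, 2 * f, tolerance = 1e-12)
})

test_that("the full block composes its oracle-checked sub-operations", {
  set.seed(33)
  mp <- msst_params(8, reduction = 8, in_channels = c(4, 6, 8))
  mp$gamma <- 0.37
  f1 <- rand_fm(1, 4, 16, 16); f2 <- rand_fm(1, 6, 8, 8)
  f3 <- rand_fm(1, 8, 8, 8); ft <- rand_fm(1, 8, 4, 4)
  out <- msst_forward(f1, f2, f3, ft, mp)

  rs <- function(x) fluoroseg:::resize_fm(x, 4, 4)
  fa <- nn_forward(mp$ds1, rs(f1)) + nn_forward(mp$ds2, rs(f2)) +
    nn_forward(mp$ds3, rs(f3))
  qkv <- project_qkv(fa, ft, mp)
  fm <- attention_oracle(qkv$q, qkv$k, qkv$v)
  expect_lt(max(abs(out - (ft + 0.37 * fm))), 1e-5)
})
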