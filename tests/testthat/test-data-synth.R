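test_that("sample generation is deterministic and phenotype-aware", {
  a <- generate_sample("flaky", 64, seed = 7)
  b <- generate_sample("flaky", 64, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_sample("flaky", 64, seed = 8)))

  pl <- generate_sample("point_like", 64, seed = 1)
  expect_null(pl$mask)              # too small to annotate: unlabeled
  expect_false(pl$labeled)
  expect_true(!is.null(generate_sample("point_like", 64, 1, labeled = TRUE)$mask))
  expect_error(generate_sample("flaky", 60), "divisible")
  expect_error(generate_sample("weird", 64), "arg")
})

test_that("flaky masks occupy 1-25% of the image across seeds", {
  areas <- vapply(1:100, function(s) mean(generate_sample("flaky", 128, s)$mask),
                  numeric(1))
  expect_true(all(areas > 0.01 & areas < 0.25))
})

test_that("mean lesion-component area orders the three phenotypes", {
  mean_comp <- function(phen) {
    mean(vapply(1:100, function(s) {
      m <- generate_sample(phen, 128, s, labeled = TRUE)$mask
      lab <- fluoroseg:::label_components(m == 1)
      if (max(lab) == 0) return(NA_real_)
      mean(tabulate(lab[lab > 0]))
    }, numeric(1)), na.rm = TRUE)
  }
  a_pl <- mean_comp("point_like")
  a_pf <- mean_comp("point_flaky")
  a_fl <- mean_comp("flaky")
  expect_lt(a_pl, a_pf)
  expect_lt(a_pf, a_fl)
})

test_that("noiseless renders stain exactly the mask support green", {
  s <- generate_sample("flaky", 64, seed = 3, noise = FALSE)
  inside <- s$mask == 1
  expect_gt(sum(inside), 0)
  g <- s$image[, , 2]; r <- s$image[, , 1]
  expect_true(all(g[inside] > r[inside]))
  # masks stay within the cornea (never touch the image border)
  expect_true(all(s$mask[1, ] == 0) && all(s$mask[, 1] == 0))
})

test_that("dataset generation writes a reproducible manifest with fold bookkeeping", {
  d1 <- file.path(tempdir(), "dsA"); d2 <- file.path(tempdir(), "dsB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(8, 8, size = 64, master_seed = 5, outdir = d1)
  m2 <- generate_dataset(8, 8, size = 64, master_seed = 5, outdir = d2)
  expect_equal(length(list.files(file.path(d1, "images"))), 16)
  expect_equal(length(list.files(file.path(d1, "masks"))), 8)
  expect_identical(m1$folds, m2$folds)
  f1 <- list.files(file.path(d1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "images"), full.names = TRUE)
  expect_identical(lapply(f1, readBin, what = "raw", n = 1e6),
                   lapply(f2, readBin, what = "raw", n = 1e6))
  expect_setequal(names(m1$folds), m1$labeled$id)
  expect_identical(sort(unique(m1$folds)), 1:4)
  rt <- read_manifest(d1)
  expect_identical(rt$folds, m1$folds)
  expect_error(generate_dataset(2, 0, 64, 1, tempfile()), "at least 4")
})

test_that("fold splitting honours the canonical sizes and stays a partition", {
  f354 <- make_folds(sprintf("id%03d", 1:354), k = 4, seed = 1)
  expect_identical(as.integer(table(f354)), c(90L, 90L, 90L, 84L))
  f8 <- make_folds(letters[1:8], k = 4, seed = 2)
  expect_identical(as.integer(table(f8)), rep(2L, 4))
  expect_setequal(names(f8), letters[1:8])
  expect_error(make_folds(letters[1:8], k = 4, sizes = c(3, 3, 3, 3)),
               "sum to")
  expect_error(make_folds(letters[1:8], k = 1), "at least 2")
})

test_that("bilinear resize hits the target geometry and preserves constants", {
  big <- array(runif(120 * 80 * 3), dim = c(120, 80, 3))
  out <- resize_bilinear(big, 64)
  expect_identical(dim(out), c(64L, 64L, 3L))
  same <- resize_bilinear(big[1:64, 1:64, ], 64)
  expect_identical(dim(same), c(64L, 64L, 3L))
  const <- resize_bilinear(matrix(3.7, 100, 50), 64)
  expect_true(all(abs(const - 3.7) < 1e-12))
  expect_error(resize_bilinear(big, 100), "divisible by 32")
  m <- matrix(0, 100, 100); m[30:60, 30:60] <- 1
  rm_ <- resize_nearest(m, 64)
  expect_true(all(rm_ %in% c(0, 1)))
})

test_that("augmentation transforms image and mask consistently", {
  s <- generate_sample("flaky", 64, seed = 4, noise = FALSE)

  # a seed whose five coin flips all come up tails leaves the sample unchanged
  noop_seed <- NULL
  for (cand in 1:500) {
    set.seed(cand)
    if (all(stats::runif(5) >= 0.5)) { noop_seed <- cand; break }
  }
  expect_false(is.null(noop_seed))
  expect_identical(augment(s, seed = noop_seed)$image, s$image)

  # horizontal flip mirrors the mask centroid column
  fl <- apply_transform(s, flip_h = TRUE)
  cent <- function(m) mean(which(m == 1, arr.ind = TRUE)[, 2])
  expect_lt(abs(cent(fl$mask) - (ncol(s$mask) + 1 - cent(s$mask))), 1)
  expect_true(all(fl$mask %in% c(0, 1)))

  # rotating +10 then -10 degrees nearly inverts
  r1 <- apply_transform(s, angle = 10)
  r2 <- apply_transform(r1, angle = -10)
  inter <- sum(r2$mask & s$mask); uni <- sum(r2$mask | s$mask)
  expect_gte(inter / uni, 0.95)

  # augmented masks stay binary under the full random pipeline
  for (sd in 1:5) expect_true(all(augment(s, sd)$mask %in% c(0, 1)))
})

test_that("PNG pairs round-trip losslessly and non-binary masks are rejected", {
  s <- generate_sample("point_flaky", 64, seed = 6)
  ip <- tempfile(fileext = ".png"); mp <- tempfile(fileext = ".png")
  write_pair(s, ip, mp)
  back <- read_pair(ip, mp)
  expect_identical(back$image, s$image)
  expect_identical(unname(back$mask), unname(s$mask))

  bad <- tempfile(fileext = ".png")
  png::writePNG(matrix(128 / 255, 8, 8), bad)
  expect_error(read_pair(ip, bad), "not binary")
  expect_error(read_pair(tempfile(fileext = ".png")), "not found")
})

test_that("a manifest-driven bulk load returns all sixteen samples", {
  man <- tiny_dataset()
  lab <- fluoroseg:::load_samples(man, man$labeled$id, labeled = TRUE)
  unl <- fluoroseg:::load_samples(man, man$unlabeled$id, labeled = FALSE)
  expect_length(c(lab, unl), 16)
  expect_true(all(vapply(lab, function(s) !is.null(s$mask), logical(1))))
  expect_true(all(vapply(unl, function(s) is.null(s$mask), logical(1))))
})
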