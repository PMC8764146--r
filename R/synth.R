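# Synthetic slit-lamp-like data: a centred cornea disk on a dark background
# with bright fluorescein-green lesions in three phenotypes, plus the
# preprocessing (bilinear resize), augmentation pipeline, fold splitting and
# PNG I/O. Everything is a pure function of (parameters, seed), so datasets
# regenerate byte-identically.
#
# Images are (H, W, 3) integer arrays in [0, 255]; masks are (H, W) 0/1
# matrices. Coordinates are row-major, origin top-left. Lesion geometry is
# parameterised in pixels at a 128-pixel reference size and scaled linearly
# with the image size, so phenotype proportions are size-invariant.

PHENOTYPES <- c("point_like", "point_flaky", "flaky")

disk_mask <- function(size, cy, cx, r) {
  y <- matrix(seq_len(size), size, size)
  x <- t(y)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

# union of n disks with centres jittered around (cy, cx)
blob_mask <- function(size, cy, cx, n, r_range, spread) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(n)) {
    dy <- stats::runif(1, -spread, spread)
    dx <- stats::runif(1, -spread, spread)
    r <- stats::runif(1, r_range[1L], r_range[2L])
    m <- m | disk_mask(size, cy + dy, cx + dx, r)
  }
  m
}

#' Generate one synthetic slit-lamp sample
#'
#' Renders a dark background, a centred cornea disk (bluish-green base with
#' smooth radial shading) and phenotype-dependent bright-green lesions:
#' `point_like` scatters tiny dots, `point_flaky` mixes dots with small
#' patches, `flaky` draws one or two large irregular blobs (unions of
#' overlapping disks, lightly smoothed). Gaussian pixel noise and a brightness
#' jitter are added last; the mask records the exact lesion support before
#' noise. Point-like samples are unlabeled by default, mirroring clinical
#' practice where such lesions are too small to annotate.
#'
#' @param phenotype one of `"point_like"`, `"point_flaky"`, `"flaky"`.
#' @param size image side in pixels; at least 64 and divisible by 32.
#' @param seed integer seed; the sample is a pure function of
#'   (phenotype, size, seed).
#' @param labeled attach the mask? Defaults to `TRUE` except for point-like
#'   samples.
#' @param noise add Gaussian pixel noise (sd 5 intensity levels) and ±10%
#'   brightness jitter.
#' @return object of class `synthetic_sample`: list with `image` (H, W, 3
#'   integer array), `mask` ((H, W) 0/1 matrix or `NULL`), `phenotype`,
#'   `seed`, `labeled`.
#' @export
generate_sample <- function(phenotype, size = 128L, seed = 1L,
                            labeled = !identical(phenotype, "point_like"),
                            noise = TRUE) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  size <- as.integer(size)
  if (size < 64L || size %% 32L != 0L) {
    stop("size must be >= 64 and divisible by 32")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sc <- size / 128                       # geometry scale vs the reference size

  # cornea disk with smooth shading
  cr <- stats::runif(1, 0.35, 0.45) * size
  cy <- size / 2 + stats::runif(1, -2, 2) * sc
  cx <- size / 2 + stats::runif(1, -2, 2) * sc
  cornea <- disk_mask(size, cy, cx, cr)
  y <- matrix(seq_len(size), size, size); x <- t(y)
  rad2 <- ((y - cy)^2 + (x - cx)^2) / cr^2
  shade <- 1 - 0.35 * clamp(rad2, 0, 1)   # brighter centre

  # lesion support (clipped to the cornea)
  lesion <- matrix(FALSE, size, size)
  scatter_dots <- function(n, r_range) {
    m <- matrix(FALSE, size, size)
    for (i in seq_len(n)) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * 0.8 * cr
      m <- m | disk_mask(size, cy + rr * sin(a), cx + rr * cos(a),
                         max(1, stats::runif(1, 1, 2) * sc))
    }
    m
  }
  if (phenotype == "point_like") {
    lesion <- scatter_dots(sample(3:15, 1L), c(1, 2))
  } else if (phenotype == "point_flaky") {
    lesion <- scatter_dots(sample(3:10, 1L), c(1, 2))
    for (i in seq_len(sample(1:3, 1L))) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * 0.6 * cr
      lesion <- lesion | disk_mask(size, cy + rr * sin(a), cx + rr * cos(a),
                                   stats::runif(1, 4, 10) * sc)
    }
  } else {
    for (i in seq_len(sample(1:2, 1L))) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * 0.45 * cr
      bm <- blob_mask(size, cy + rr * sin(a), cx + rr * cos(a),
                      n = sample(5:15, 1L), r_range = c(8, 18) * sc,
                      spread = 12 * sc)
      # light smoothing of the blob outline
      sm <- gaussian_blur_mat(bm * 1, sigma = max(1, 1.5 * sc))
      lesion <- lesion | (sm > 0.5)
    }
  }
  lesion <- lesion & cornea
  mask <- lesion * 1

  # compose the RGB image
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- 12; img[, , 2] <- 14; img[, , 3] <- 16          # dark background
  base <- cbind(40, 150, 140)                                    # bluish-green cornea
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[cornea] <- (base[ch] * shade)[cornea]
    img[, , ch] <- pl
  }
  les_col <- c(90, 235, 80)                                      # fluorescein green
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[lesion] <- 0.15 * pl[lesion] + 0.85 * les_col[ch]
    img[, , ch] <- pl
  }
  if (noise) {
    img <- img * stats::runif(1, 0.9, 1.1)                       # brightness jitter
    img <- img + array(stats::rnorm(length(img), sd = 5), dim = dim(img))
  }
  img <- array(as.integer(round(clamp(img, 0, 255))), dim = dim(img))

  structure(list(image = img, mask = if (labeled) mask else NULL,
                 phenotype = phenotype, seed = as.integer(seed),
                 labeled = labeled),
            class = "synthetic_sample")
}

# save/restore the global RNG state so generators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

child_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 7919) %% 2147483629)
}

#' Assign labeled ids to cross-validation folds
#'
#' Seeded shuffled partition into `k` disjoint, exhaustive folds. When `sizes`
#' is omitted the split is near-equal, except for the canonical 354-image /
#' 4-fold case which uses the historical sizes 90, 90, 90, 84.
#'
#' @param ids vector of ids.
#' @param k number of folds.
#' @param sizes optional explicit fold sizes (must sum to `length(ids)`).
#' @param seed shuffle seed.
#' @return integer vector of fold assignments (1..k), named by id.
#' @export
make_folds <- function(ids, k = 4L, sizes = NULL, seed = 1L) {
  n <- length(ids)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (is.null(sizes)) {
    sizes <- if (n == 354L && k == 4L) c(90L, 90L, 90L, 84L) else {
      s <- rep(n %/% k, k)
      if (n %% k > 0L) s[seq_len(n %% k)] <- s[seq_len(n %% k)] + 1L
      s
    }
  }
  if (sum(sizes) != n) {
    stop(sprintf("fold sizes sum to %d but there are %d ids", sum(sizes), n))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  names(fold) <- as.character(ids)
  fold
}

#' Generate a full synthetic dataset on disk
#'
#' Writes labeled image/mask PNG pairs (phenotypes alternating point-flaky and
#' flaky, as in clinical collections where only these are annotatable) and
#' unlabeled point-like images, plus a JSON manifest with fold assignments.
#' Child seeds derive deterministically from `master_seed`, so two runs with
#' the same seed produce byte-identical files.
#'
#' @param n_labeled number of labeled samples (at least 4).
#' @param n_unlabeled number of unlabeled point-like samples.
#' @param size image side in pixels.
#' @param master_seed integer master seed.
#' @param outdir output directory (created; gets `images/`, `masks/`,
#'   `manifest.json`).
#' @param k number of cross-validation folds recorded in the manifest.
#' @return the manifest, invisibly (class `dataset_manifest`).
#' @export
generate_dataset <- function(n_labeled, n_unlabeled, size = 128L,
                             master_seed = 1L, outdir, k = 4L) {
  if (n_labeled < 4L) stop("need at least 4 labeled samples (one per fold)")
  dir.create(file.path(outdir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  lab_phen <- rep(c("point_flaky", "flaky"), length.out = n_labeled)
  labeled <- data.frame(id = sprintf("lab%04d", seq_len(n_labeled)),
                        phenotype = lab_phen,
                        seed = vapply(seq_len(n_labeled),
                                      function(i) child_seed(master_seed, i),
                                      integer(1)),
                        stringsAsFactors = FALSE)
  unlabeled <- if (n_unlabeled > 0L) {
    data.frame(id = sprintf("unl%04d", seq_len(n_unlabeled)),
               phenotype = "point_like",
               seed = vapply(seq_len(n_unlabeled),
                             function(i) child_seed(master_seed, n_labeled + i),
                             integer(1)),
               stringsAsFactors = FALSE)
  } else NULL
  for (i in seq_len(nrow(labeled))) {
    s <- generate_sample(labeled$phenotype[i], size, labeled$seed[i])
    write_pair(s, file.path(outdir, "images", paste0(labeled$id[i], ".png")),
               file.path(outdir, "masks", paste0(labeled$id[i], ".png")))
  }
  if (!is.null(unlabeled)) {
    for (i in seq_len(nrow(unlabeled))) {
      s <- generate_sample("point_like", size, unlabeled$seed[i])
      write_pair(s, file.path(outdir, "images", paste0(unlabeled$id[i], ".png")))
    }
  }
  folds <- make_folds(labeled$id, k = k, seed = child_seed(master_seed, 0L))
  manifest <- structure(list(
    dir = normalizePath(outdir),
    size = as.integer(size), master_seed = as.integer(master_seed),
    labeled = labeled, unlabeled = unlabeled,
    folds = folds), class = "dataset_manifest")
  jsonlite::write_json(
    list(size = size, master_seed = master_seed,
         labeled = labeled, unlabeled = unlabeled,
         folds = as.list(folds)),
    file.path(outdir, "manifest.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest back from disk
#'
#' @param outdir a directory written by [generate_dataset()].
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(outdir) {
  path <- file.path(outdir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", outdir)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- unlist(j$folds)
  structure(list(dir = normalizePath(outdir), size = j$size,
                 master_seed = j$master_seed, labeled = j$labeled,
                 unlabeled = j$unlabeled, folds = folds),
            class = "dataset_manifest")
}

#' Bilinear image resize
#'
#' Resizes an (H, W) or (H, W, 3) image to `target_size` x `target_size` with
#' bilinear interpolation (half-pixel source coordinates).
#'
#' @param image numeric matrix or (H, W, C) array.
#' @param target_size output side, divisible by 32.
#' @return resized image, same value range as the input.
#' @export
resize_bilinear <- function(image, target_size) {
  target_size <- as.integer(target_size)
  if (target_size %% 32L != 0L) stop("target_size must be divisible by 32")
  d <- dim(image)
  Ah <- bilinear_matrix(d[1L], target_size)
  Aw <- bilinear_matrix(d[2L], target_size)
  if (length(d) == 2L) return(Ah %*% image %*% t(Aw))
  out <- array(0, dim = c(target_size, target_size, d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- Ah %*% image[, , ch] %*% t(Aw)
  out
}

#' Nearest-neighbour mask resize
#'
#' @param mask binary (H, W) matrix.
#' @param target_size output side, divisible by 32.
#' @return binary matrix `target_size` x `target_size` (re-binarised).
#' @export
resize_nearest <- function(mask, target_size) {
  target_size <- as.integer(target_size)
  if (target_size %% 32L != 0L) stop("target_size must be divisible by 32")
  Ah <- nearest_matrix(nrow(mask), target_size)
  Aw <- nearest_matrix(ncol(mask), target_size)
  out <- Ah %*% mask %*% t(Aw)
  (out >= 0.5) * 1
}

## ---- augmentation ----------------------------------------------------------

# inverse-mapped affine resampling; bilinear for images, nearest for masks.
# The 2x3 matrix maps output pixel centres to source coordinates (0-based,
# about the image centre).
affine_resample <- function(img, A, nearest = FALSE) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  cyx <- c((H - 1) / 2, (W - 1) / 2)
  yo <- rep(seq_len(H) - 1, times = W) - cyx[1L]
  xo <- rep(seq_len(W) - 1, each = H) - cyx[2L]
  ys <- A[1L, 1L] * yo + A[1L, 2L] * xo + A[1L, 3L] + cyx[1L]
  xs <- A[2L, 1L] * yo + A[2L, 2L] * xo + A[2L, 3L] + cyx[2L]
  sample_plane <- function(pl) {
    if (nearest) {
      yi <- clamp(round(ys), 0, H - 1); xi <- clamp(round(xs), 0, W - 1)
      v <- pl[cbind(yi + 1, xi + 1)]
    } else {
      y0 <- clamp(floor(ys), 0, H - 1); x0 <- clamp(floor(xs), 0, W - 1)
      y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
      fy <- clamp(ys, 0, H - 1) - y0; fx <- clamp(xs, 0, W - 1) - x0
      v <- (1 - fy) * (1 - fx) * pl[cbind(y0 + 1, x0 + 1)] +
           (1 - fy) * fx       * pl[cbind(y0 + 1, x1 + 1)] +
           fy       * (1 - fx) * pl[cbind(y1 + 1, x0 + 1)] +
           fy       * fx       * pl[cbind(y1 + 1, x1 + 1)]
    }
    out <- (ys >= 0 & ys <= H - 1 & xs >= 0 & xs <= W - 1) * v
    matrix(out, H, W)
  }
  if (length(d) == 2L) return(sample_plane(img))
  out <- array(0, dim = d)
  for (ch in seq_len(d[3L])) out[, , ch] <- sample_plane(img[, , ch])
  out
}

#' Apply a deterministic geometric/photometric transform
#'
#' Composes rotation, flips, scaling and translation into one affine resample
#' (bilinear for the image, nearest for the mask, which is re-binarised), then
#' optionally adds Gaussian pixel noise to the image only.
#'
#' @param sample a `synthetic_sample`.
#' @param angle rotation in degrees (positive = counter-clockwise).
#' @param flip_h,flip_v mirror horizontally / vertically.
#' @param scale isotropic scale factor.
#' @param translate length-2 vector, (rows, columns) shift in pixels.
#' @param noise_sd Gaussian noise standard deviation (0 = none); uses the
#'   current RNG stream.
#' @return the transformed `synthetic_sample`.
#' @export
apply_transform <- function(sample, angle = 0, flip_h = FALSE, flip_v = FALSE,
                            scale = 1, translate = c(0, 0), noise_sd = 0) {
  th <- angle * pi / 180
  # forward map: scale, rotate, flip, translate; we resample by the inverse
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L, byrow = TRUE)
  Fm <- diag(c(if (flip_v) -1 else 1, if (flip_h) -1 else 1))
  M <- Fm %*% R * scale
  Minv <- solve(M)
  A <- cbind(Minv, -Minv %*% translate)
  img <- affine_resample(sample$image, A, nearest = FALSE)
  if (noise_sd > 0) img <- img + array(stats::rnorm(length(img), sd = noise_sd),
                                       dim = dim(img))
  img <- array(as.integer(round(clamp(img, 0, 255))), dim = dim(sample$image))
  mask <- if (!is.null(sample$mask)) {
    m <- affine_resample(sample$mask, A, nearest = TRUE)
    (m >= 0.5) * 1
  } else NULL
  out <- sample
  out$image <- img
  out$mask <- mask
  out
}

#' Randomly augment a sample
#'
#' Applies, each with probability 0.5: rotation uniform in \[-10, 10\]
#' degrees, horizontal flip, vertical flip, additive Gaussian noise (sd 5) and
#' a small affine perturbation (scale 0.9–1.1, translation up to 5% of the
#' side). The identical geometric transform is applied to image and mask.
#'
#' @param sample a `synthetic_sample`.
#' @param seed integer seed making the draw reproducible.
#' @return augmented `synthetic_sample`.
#' @export
augment <- function(sample, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  coins <- stats::runif(5) < 0.5
  angle <- if (coins[1L]) stats::runif(1, -10, 10) else 0
  flip_h <- coins[2L]
  flip_v <- coins[3L]
  noise_sd <- if (coins[4L]) 5 else 0
  scale <- 1; translate <- c(0, 0)
  if (coins[5L]) {
    scale <- stats::runif(1, 0.9, 1.1)
    translate <- stats::runif(2, -0.05, 0.05) * dim(sample$image)[1:2]
  }
  apply_transform(sample, angle = angle, flip_h = flip_h, flip_v = flip_v,
                  scale = scale, translate = translate, noise_sd = noise_sd)
}

## ---- PNG I/O ---------------------------------------------------------------

#' Write an image (and optional mask) as PNG
#'
#' Images are written as 8-bit RGB, masks as 8-bit grayscale with lesion = 255.
#'
#' @param sample a `synthetic_sample`.
#' @param image_path output path for the image.
#' @param mask_path output path for the mask (required when the sample is
#'   labeled).
#' @export
write_pair <- function(sample, image_path, mask_path = NULL) {
  png::writePNG(sample$image / 255, image_path)
  if (!is.null(sample$mask)) {
    if (is.null(mask_path)) stop("labeled sample requires a mask_path")
    png::writePNG(sample$mask, mask_path)
  }
  invisible(sample)
}

#' Read an image/mask PNG pair
#'
#' @param image_path path to an 8-bit RGB PNG.
#' @param mask_path optional path to an 8-bit mask PNG; pixel values must be
#'   exactly 0 or 255.
#' @return a `synthetic_sample` (phenotype `NA`, seed `NA`).
#' @export
read_pair <- function(image_path, mask_path = NULL) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  img <- array(as.integer(round(img * 255)), dim = dim(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mv <- as.integer(round(m * 255))
    if (!all(mv %in% c(0L, 255L))) {
      stop("mask is not binary (values other than 0/255): ", mask_path)
    }
    mask <- matrix(mv / 255L, nrow(m), ncol(m))
  }
  structure(list(image = img, mask = mask, phenotype = NA_character_,
                 seed = NA_integer_, labeled = !is.null(mask)),
            class = "synthetic_sample")
}

# convert a sample image to a (1, 3, H, W) float feature map in [0, 1]
sample_to_input <- function(sample) {
  img <- sample$image / 255
  aperm(array(img, dim = c(dim(img), 1L)), c(4L, 3L, 1L, 2L))
}

mask_to_target <- function(mask) {
  array(mask, dim = c(1L, 1L, nrow(mask), ncol(mask)))
}
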