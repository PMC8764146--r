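# The segmentor (5-stage residual encoder, MsST bottleneck, upsampling
# decoder) and the patch discriminator.
#
# Encoder topology: a strided 3x3 stem halves the input, then four residual
# stages each halve it again, so the top stage sits at 1/32 of the input
# resolution — the residual-18 stage layout (channel counts 64, 64, 128, 256,
# 512 by default). The decoder mirrors the encoder: four levels of 2x bilinear
# upsampling + 3x3 convolution + ReLU with additive projections from the
# corresponding encoder stages, a final 2x upsample to undo the stem, and a
# 1x1 convolution with a logistic output giving per-pixel lesion
# probabilities.

#' Encoder specification
#'
#' @param stage_channels integer vector of 5 stage widths, or the shorthand
#'   strings `"full"` (64, 64, 128, 256, 512 — residual-18-style) and
#'   `"tiny"` (8, 8, 16, 32, 64 — used for CPU-scale tests and smoke runs).
#' @param input_channels number of image channels (3 for RGB).
#' @return an `encoder_spec` list.
#' @export
encoder_spec <- function(stage_channels = "full", input_channels = 3L) {
  if (is.character(stage_channels)) {
    stage_channels <- switch(match.arg(stage_channels, c("full", "tiny")),
                             full = c(64L, 64L, 128L, 256L, 512L),
                             tiny = c(8L, 8L, 16L, 32L, 64L))
  }
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != 5L || any(stage_channels < 1L)) {
    stop("stage_channels must give 5 positive stage widths")
  }
  structure(list(stage_channels = stage_channels,
                 input_channels = as.integer(input_channels)),
            class = "encoder_spec")
}

#' Build the segmentor network
#'
#' Assembles the encoder, the MsST bottleneck and the decoder. Weights are
#' randomly initialised (He-scaled); pass `pretrained` as a path to a saved
#' weight list to initialise from a checkpoint instead.
#'
#' @param spec an [encoder_spec()].
#' @param msst an [msst_params()] whose `top_channels` equals the 5th stage
#'   width; built automatically when `NULL`.
#' @param pretrained optional path to an RDS weight list (as written by
#'   [save_checkpoint()]); `NULL` for seeded random initialisation.
#' @param reduction channel reduction for the MsST block when it is built here.
#' @param skip_connections add 1x1-projected encoder features to the matching
#'   decoder levels. See the methods vignette for why this is the default.
#' @param seed RNG seed for weight initialisation.
#' @return a `segmentor` network object.
#' @export
build_segmentor <- function(spec = encoder_spec(), msst = NULL,
                            pretrained = NULL, reduction = 8L,
                            skip_connections = TRUE, seed = NULL) {
  if (!inherits(spec, "encoder_spec")) stop("spec must be an encoder_spec()")
  if (!is.null(seed)) set.seed(seed)
  ch <- spec$stage_channels
  if (is.null(msst)) {
    msst <- msst_params(ch[5L], reduction = reduction, in_channels = ch[2:4])
  }
  if (msst$top_channels != ch[5L]) {
    stop(sprintf("msst top_channels (%d) must equal stage-5 width (%d)",
                 msst$top_channels, ch[5L]))
  }
  dec_ch <- c(ch[4L], ch[3L], ch[2L], ch[1L])
  dec <- vector("list", 4L)
  skips <- if (skip_connections) vector("list", 4L) else NULL
  in_ch <- ch[5L]
  enc_src <- c(ch[4L], ch[3L], ch[2L], ch[1L])   # encoder stage feeding each level
  for (i in 1:4) {
    dec[[i]] <- list(up = resize_layer(scale = 2L),
                     conv = conv2d(in_ch, dec_ch[i], 3L),
                     relu = act_relu())
    if (skip_connections) {
      skips[[i]] <- conv2d(enc_src[i], in_ch, 1L, pad = 0L)
    }
    in_ch <- dec_ch[i]
  }
  g <- new_layer("segmentor",
                 spec = spec,
                 stem = conv2d(spec$input_channels, ch[1L], 3L, stride = 2L),
                 stem_relu = act_relu(),
                 stage2 = res_block(ch[1L], ch[2L], 2L),
                 stage3 = res_block(ch[2L], ch[3L], 2L),
                 stage4 = res_block(ch[3L], ch[4L], 2L),
                 stage5 = res_block(ch[4L], ch[5L], 2L),
                 msst = msst,
                 decoder = dec,
                 skips = skips,
                 final_up = resize_layer(scale = 2L),
                 head = conv2d(ch[1L], 1L, 1L, pad = 0L),
                 head_sigmoid = act_sigmoid(),
                 cache = NULL)
  # start the head near the background prior so early Dice gradients are tame
  if (!is.null(g$head$b)) g$head$b <- -1
  if (!is.null(pretrained)) {
    if (!file.exists(pretrained)) stop("pretrained weight file not found: ", pretrained)
    set_weights(g, readRDS(pretrained))
  }
  g
}

#' @export
nn_param_slots.segmentor <- function(layer) {
  out <- c(nn_param_slots(layer$stem),
           nn_param_slots(layer$stage2), nn_param_slots(layer$stage3),
           nn_param_slots(layer$stage4), nn_param_slots(layer$stage5),
           nn_param_slots(layer$msst))
  for (lv in layer$decoder) out <- c(out, nn_param_slots(lv$conv))
  if (!is.null(layer$skips)) for (s in layer$skips) out <- c(out, nn_param_slots(s))
  c(out, nn_param_slots(layer$head))
}

#' @export
nn_forward.segmentor <- function(layer, x, ...) {
  check_feature_map(x, "images")
  x <- 2 * x - 1          # map [0,1] intensities to [-1,1] (zero-centred input)
  s1 <- nn_forward(layer$stem_relu, nn_forward(layer$stem, x))
  s2 <- nn_forward(layer$stage2, s1)
  s3 <- nn_forward(layer$stage3, s2)
  s4 <- nn_forward(layer$stage4, s3)
  s5 <- nn_forward(layer$stage5, s4)
  h <- nn_forward(layer$msst, list(s2, s3, s4, s5))
  enc <- list(s4, s3, s2, s1)
  for (i in 1:4) {
    lv <- layer$decoder[[i]]
    h <- nn_forward(lv$up, h)
    if (!is.null(layer$skips)) h <- h + nn_forward(layer$skips[[i]], enc[[i]])
    h <- nn_forward(lv$relu, nn_forward(lv$conv, h))
  }
  h <- nn_forward(layer$final_up, h)
  nn_forward(layer$head_sigmoid, nn_forward(layer$head, h))
}

#' @export
nn_backward.segmentor <- function(layer, grad, from_logits = FALSE, ...) {
  # from_logits: `grad` is already d loss / d logit, so the final sigmoid's
  # (vanishing) derivative is not applied — used by the training engine to
  # keep the pixel BCE gradient alive when predictions saturate
  g <- if (from_logits) nn_backward(layer$head, grad) else
    nn_backward(layer$head, nn_backward(layer$head_sigmoid, grad))
  g <- nn_backward(layer$final_up, g)
  denc <- vector("list", 4L)   # grads for s4, s3, s2, s1 via skip paths
  for (i in 4:1) {
    lv <- layer$decoder[[i]]
    g <- nn_backward(lv$conv, nn_backward(lv$relu, g))
    if (!is.null(layer$skips)) denc[[i]] <- nn_backward(layer$skips[[i]], g)
    g <- nn_backward(lv$up, g)
  }
  dm <- nn_backward(layer$msst, g)   # list: grads for s2, s3, s4, s5
  ds5 <- dm[[4L]]
  ds4 <- dm[[3L]] + nn_backward(layer$stage5, ds5)
  if (!is.null(layer$skips)) ds4 <- ds4 + denc[[1L]]
  ds3 <- dm[[2L]] + nn_backward(layer$stage4, ds4)
  if (!is.null(layer$skips)) ds3 <- ds3 + denc[[2L]]
  ds2 <- dm[[1L]] + nn_backward(layer$stage3, ds3)
  if (!is.null(layer$skips)) ds2 <- ds2 + denc[[3L]]
  ds1 <- nn_backward(layer$stage2, ds2)
  if (!is.null(layer$skips)) ds1 <- ds1 + denc[[4L]]
  2 * nn_backward(layer$stem, nn_backward(layer$stem_relu, ds1))  # input centring
}

#' Run the segmentor on a batch of images
#'
#' @param model a `segmentor` from [build_segmentor()].
#' @param images array (B, 3, H, W) with H and W divisible by 32.
#' @return probability array (B, 1, H, W), values in \[0, 1\].
#' @export
segment <- function(model, images) {
  check_feature_map(images, "images")
  d <- dim(images)
  if (d[3L] %% 32L != 0L || d[4L] %% 32L != 0L) {
    stop(sprintf(paste0("image size %dx%d is not divisible by 32; ",
                        "pad or resize the input first"), d[3L], d[4L]))
  }
  nn_forward(model, images)
}

## ---- patch discriminator ---------------------------------------------------

#' Patch discriminator specification
#'
#' Each row of `layers` is one strided convolution (out_channels, kernel,
#' stride). The default is the canonical 70-receptive-field patch classifier:
#' four 4x4 convolutions with strides 2, 2, 2, 1 followed by a stride-1 4x4
#' output convolution, so each output unit judges one 70x70 input patch.
#'
#' @param base_width width of the first convolution (64 in the full model;
#'   use a small value for CPU-scale tests — the receptive field is unchanged).
#' @param input_channels image channels + mask channels (3 + 1).
#' @return a `discriminator_spec` list.
#' @export
discriminator_spec <- function(base_width = 64L, input_channels = 4L) {
  w <- as.integer(base_width)
  structure(list(
    layers = list(c(w, 4L, 2L), c(2L * w, 4L, 2L), c(4L * w, 4L, 2L),
                  c(8L * w, 4L, 1L), c(1L, 4L, 1L)),
    input_channels = as.integer(input_channels)), class = "discriminator_spec")
}

#' Analytic receptive field of a layer stack
#'
#' Applies the standard recurrence `rf <- rf + (k - 1) * jump; jump <- jump *
#' stride` over the convolutions listed in forward order.
#'
#' @param spec a [discriminator_spec()] (or any list with a `layers` field of
#'   (out_channels, kernel, stride) triples).
#' @return receptive field of one output unit, in input pixels.
#' @export
receptive_field <- function(spec) {
  if (length(spec$layers) == 0L) stop("layer list is empty")
  rf <- 1
  jump <- 1
  for (l in spec$layers) {
    rf <- rf + (l[2L] - 1L) * jump
    jump <- jump * l[3L]
  }
  as.integer(rf)
}

#' Build the patch discriminator
#'
#' A fully convolutional classifier on 4-channel image-plus-mask pairs whose
#' output is a map of per-patch real/fake probabilities (logistic output).
#' Hidden activations are leaky ReLU (slope 0.2).
#'
#' @param spec a [discriminator_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return a `discriminator` network object.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(spec$layers)
  layers <- list()
  in_ch <- spec$input_channels
  for (i in seq_len(n)) {
    l <- spec$layers[[i]]
    cv <- conv2d(in_ch, l[1L], l[2L], stride = l[3L], pad = 1L)
    # patch-discriminator convention: small-variance Gaussian init, so the
    # classifier starts near chance and the adversarial gradients ramp up
    # gently instead of dominating the pixel losses early on
    cv$W <- matrix(stats::rnorm(length(cv$W), sd = 0.02), nrow(cv$W), ncol(cv$W))
    layers <- c(layers, list(cv))
    if (i < n) layers <- c(layers, list(act_lrelu(0.2)))
    in_ch <- l[1L]
  }
  layers <- c(layers, list(act_sigmoid()))
  d <- do.call(nn_sequential, layers)
  class(d) <- c("discriminator", class(d))
  d$spec <- spec
  d
}

#' Score image/mask pairs with the discriminator
#'
#' Concatenates the image and the (predicted or ground-truth) mask along the
#' channel axis and returns the patch score map.
#'
#' @param d a `discriminator`.
#' @param image array (B, 3, H, W).
#' @param mask array (B, 1, H, W), spatially aligned with `image`.
#' @return patch probability map (B, 1, H', W').
#' @export
discriminate <- function(d, image, mask) {
  check_feature_map(image, "image")
  check_feature_map(mask, "mask")
  di <- dim(image); dm <- dim(mask)
  if (di[1L] != dm[1L] || di[3L] != dm[3L] || di[4L] != dm[4L]) {
    stop(sprintf("image (%s) and mask (%s) are not spatially aligned",
                 paste(di, collapse = ","), paste(dm, collapse = ",")))
  }
  x <- array(0, dim = c(di[1L], di[2L] + dm[2L], di[3L], di[4L]))
  x[, seq_len(di[2L]), , ] <- image
  x[, di[2L] + seq_len(dm[2L]), , ] <- mask
  nn_forward(d, x)
}

# backward through the discriminator down to its input, returning the
# gradient with respect to the mask channel (used for the adversarial term)
discriminate_backward_mask <- function(d, grad, n_image_ch = 3L) {
  dx <- nn_backward(d, grad)
  dx[, n_image_ch + 1L, , , drop = FALSE]
}

## ---- checkpointing ---------------------------------------------------------

#' Save model weights
#'
#' Writes the weight tensors plus a small architecture descriptor to an RDS
#' file. The architecture is rebuilt from the descriptor on load.
#'
#' @param model a `segmentor` or `discriminator`.
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  arch <- if (inherits(model, "segmentor")) {
    list(kind = "segmentor", stage_channels = model$spec$stage_channels,
         input_channels = model$spec$input_channels,
         reduction = model$msst$reduction,
         skip_connections = !is.null(model$skips))
  } else if (inherits(model, "discriminator")) {
    list(kind = "discriminator", spec = model$spec)
  } else stop("unsupported model type")
  saveRDS(list(arch = arch, weights = get_weights(model)), path)
  invisible(path)
}

#' Load model weights
#'
#' @param path an RDS file written by [save_checkpoint()].
#' @return the rebuilt model with restored weights.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  model <- if (ck$arch$kind == "segmentor") {
    build_segmentor(encoder_spec(ck$arch$stage_channels, ck$arch$input_channels),
                    reduction = ck$arch$reduction,
                    skip_connections = ck$arch$skip_connections, seed = 0L)
  } else {
    build_discriminator(ck$arch$spec, seed = 0L)
  }
  set_weights(model, ck$weights)
  model
}
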