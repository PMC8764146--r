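# Training and evaluation engine. One iteration of the adversarial protocol
# updates the segmentor first (discriminator frozen), then the discriminator
# (segmentor frozen, predictions detached). In semi-supervised mode labeled
# and unlabeled steps alternate strictly within each iteration.

#' Training configuration
#'
#' Defaults are the full-scale settings: Adam, learning rate 5e-4, weight
#' decay 1e-4, batch size 4, 100 epochs, 512-pixel images, full encoder.
#' CPU-scale smoke runs use [tiny_train_config()].
#'
#' @param learning_rate Adam learning rate (shared by both networks).
#' @param weight_decay L2 weight decay added to gradients.
#' @param batch_size images per batch.
#' @param epochs passes over the labeled set.
#' @param mode `"supervised"` or `"semi"`.
#' @param seed master seed for weight init, shuffling and augmentation.
#' @param image_size training resolution (divisible by 32).
#' @param encoder `"full"` or `"tiny"` stage widths.
#' @param disc_base_width first-layer width of the discriminator.
#' @param loss_weights named vector (`bce`, `dice`, `adv`), all 1 by default.
#' @param augment apply the random augmentation pipeline during training.
#' @param augment_unlabeled also augment unlabeled images (default yes).
#' @param d_real_resample when a discriminator update has no real pair
#'   (unlabeled step), redraw a labeled real pair instead of using the
#'   fake-only term.
#' @param d_lr_factor multiplier on the discriminator's learning rate
#'   (1 = shared setting; smoke runs use a smaller value to keep the
#'   adversarial game stable over very few updates).
#' @param threshold binarisation threshold for validation Dice.
#' @param selection `"best"` keeps the weights with the highest validation
#'   Dice; `"last"` keeps the final epoch.
#' @param warmup_epochs epochs of supervised-only training before unlabeled
#'   steps begin (semi mode).
#' @param skip_connections decoder receives projected encoder features.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-4,
                         batch_size = 4L, epochs = 100L,
                         mode = c("supervised", "semi"), seed = 1L,
                         image_size = 512L, encoder = "full",
                         disc_base_width = 64L,
                         loss_weights = c(bce = 1, dice = 1, adv = 1),
                         augment = TRUE, augment_unlabeled = TRUE,
                         d_real_resample = FALSE, d_lr_factor = 1,
                         threshold = 0.5,
                         selection = c("best", "last"), warmup_epochs = 0L,
                         skip_connections = TRUE) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  if (image_size %% 32L != 0L) stop("image_size must be divisible by 32")
  if (batch_size < 1L || epochs < 1L) stop("batch_size and epochs must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 mode = mode, seed = as.integer(seed),
                 image_size = as.integer(image_size), encoder = encoder,
                 disc_base_width = as.integer(disc_base_width),
                 loss_weights = loss_weights, augment = augment,
                 augment_unlabeled = augment_unlabeled,
                 d_real_resample = d_real_resample,
                 d_lr_factor = d_lr_factor, threshold = threshold,
                 selection = selection, warmup_epochs = as.integer(warmup_epochs),
                 skip_connections = skip_connections),
            class = "train_config")
}

#' Smoke-run configuration
#'
#' The CPU-scale setting used by the package's end-to-end trainability checks:
#' 64-pixel images, tiny encoder and discriminator, 10 epochs, batch size 1,
#' learning rate 0.01 and a discriminator rate 20x smaller. A from-scratch
#' tiny run sees only ~80 Adam updates, for which the full-scale rate of 5e-4
#' cannot move freshly initialised weights, while an equally fast
#' discriminator destabilises the adversarial game at this step count; see
#' the methods vignette for the reasoning behind both choices.
#'
#' @param mode `"supervised"` or `"semi"`.
#' @param seed master seed.
#' @param epochs passes over the labeled set.
#' @return a `train_config`.
#' @export
tiny_train_config <- function(mode = "semi", seed = 1L, epochs = 10L) {
  train_config(learning_rate = 0.01, batch_size = 1L, epochs = epochs,
               mode = mode, seed = seed, image_size = 64L, encoder = "tiny",
               disc_base_width = 8L, d_lr_factor = 0.05)
}

ensure_optimizer <- function(model, cfg) {
  if (is.null(model$optimizer)) {
    lr <- cfg$learning_rate
    if (inherits(model, "discriminator")) lr <- lr * (cfg$d_lr_factor %||% 1)
    model$optimizer <- adam_optimizer(model, lr = lr,
                                      weight_decay = cfg$weight_decay)
  }
  model$optimizer
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stack a list of samples into (B,3,H,W) images and optional (B,1,H,W) masks
stack_batch <- function(samples, with_masks = TRUE) {
  B <- length(samples)
  d <- dim(samples[[1L]]$image)
  images <- array(0, dim = c(B, 3L, d[1L], d[2L]))
  masks <- if (with_masks) array(0, dim = c(B, 1L, d[1L], d[2L])) else NULL
  for (b in seq_len(B)) {
    images[b, , , ] <- sample_to_input(samples[[b]])[1L, , , ]
    if (with_masks) {
      if (is.null(samples[[b]]$mask)) stop("labeled batch has a sample without mask")
      masks[b, 1L, , ] <- samples[[b]]$mask
    }
  }
  list(images = images, masks = masks)
}

#' One supervised training step
#'
#' Generator update minimising the joint loss (BCE + Dice + adversarial) with
#' the discriminator frozen, then a discriminator update on the detached
#' (image, prediction) fake pair and the (image, ground truth) real pair with
#' the generator frozen.
#'
#' @param G segmentor. @param D discriminator.
#' @param batch list with `images` (B,3,H,W) and `masks` (B,1,H,W), e.g. from
#'   internal batching or [stack_batch()] equivalents.
#' @param cfg a [train_config()].
#' @return named list of loss values (`bce`, `dice`, `adv`, `joint`, `d`).
#' @export
supervised_step <- function(G, D, batch, cfg) {
  if (is.null(batch$masks)) stop("supervised step requires masks")
  opt_g <- ensure_optimizer(G, cfg)
  opt_d <- ensure_optimizer(D, cfg)
  w <- cfg$loss_weights

  # --- generator update (D frozen) ---
  nn_zero_grad(G)
  pred <- nn_forward(G, batch$images)
  fake_scores <- discriminate(D, batch$images, pred)
  losses <- joint_loss(pred, batch$masks, fake_scores, weights = w)
  nn_zero_grad(D)   # discard any stale D grads; D params are not stepped here
  dpred_adv <- discriminate_backward_mask(D, w[["adv"]] * adversarial_grad(fake_scores))
  # gradients are taken at the output logit: the BCE term has the closed form
  # (p - y) / n there, which stays informative when the sigmoid saturates
  sig <- pred * (1 - pred)
  dz <- w[["bce"]] * (pred - batch$masks) / length(pred) +
    (w[["dice"]] * dice_grad(pred, batch$masks) + dpred_adv) * sig
  nn_backward(G, dz, from_logits = TRUE)
  adam_step(opt_g)

  # --- discriminator update (G frozen, prediction detached) ---
  nn_zero_grad(D)
  fake_scores_d <- discriminate(D, batch$images, pred)  # pred is a constant here
  real_scores <- discriminate(D, batch$images, batch$masks)
  # the two discriminate() calls share layer caches, so backprop each term
  # right after its forward pass
  g <- discriminator_grad(fake_scores_d, real_scores)
  l_d <- discriminator_loss(fake_scores_d, real_scores)
  nn_backward(D, g$real)                                 # caches hold real pass
  fake_scores_d <- discriminate(D, batch$images, pred)   # refresh caches
  nn_backward(D, g$fake)
  adam_step(opt_d)

  list(bce = losses$bce, dice = losses$dice, adv = losses$adv,
       joint = losses$joint, d = l_d)
}

#' One unsupervised training step
#'
#' Generator update minimising the adversarial loss only (no pixel-wise
#' terms), then a discriminator update on the detached fake pair. No mask is
#' read.
#'
#' @inheritParams supervised_step
#' @param batch list with `images`; a `masks` entry triggers a warning and is
#'   ignored.
#' @param real_batch optional labeled batch supplying a real pair for the
#'   discriminator update when `cfg$d_real_resample` is set.
#' @return named list with `adv` and `d`.
#' @export
unsupervised_step <- function(G, D, batch, cfg, real_batch = NULL) {
  if (!is.null(batch$masks)) {
    warning("unsupervised step ignores the masks present in the batch")
  }
  opt_g <- ensure_optimizer(G, cfg)
  opt_d <- ensure_optimizer(D, cfg)
  w <- cfg$loss_weights

  nn_zero_grad(G)
  pred <- nn_forward(G, batch$images)
  fake_scores <- discriminate(D, batch$images, pred)
  l_adv <- adversarial_loss(fake_scores)
  nn_zero_grad(D)
  dpred <- discriminate_backward_mask(D, w[["adv"]] * adversarial_grad(fake_scores))
  nn_backward(G, dpred * pred * (1 - pred), from_logits = TRUE)
  adam_step(opt_g)

  nn_zero_grad(D)
  use_real <- isTRUE(cfg$d_real_resample) && !is.null(real_batch)
  real_scores <- if (use_real) {
    rs <- discriminate(D, real_batch$images, real_batch$masks)
    g_r <- discriminator_grad(NULL, rs)
    nn_backward(D, g_r$real)
    rs
  } else NULL
  fake_scores_d <- discriminate(D, batch$images, pred)
  l_d <- discriminator_loss(fake_scores_d, real_scores)
  g <- discriminator_grad(fake_scores_d, NULL)
  nn_backward(D, g$fake)
  adam_step(opt_d)

  list(adv = l_adv, d = l_d)
}

load_samples <- function(manifest, ids, labeled = TRUE) {
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ip <- file.path(manifest$dir, "images", paste0(ids[i], ".png"))
    mp <- if (labeled) file.path(manifest$dir, "masks", paste0(ids[i], ".png")) else NULL
    out[[i]] <- read_pair(ip, mp)
  }
  names(out) <- ids
  out
}

prep_batch <- function(samples, idx, cfg, with_masks, augment_on, aug_seed) {
  picked <- samples[idx]
  if (augment_on) {
    picked <- lapply(seq_along(picked), function(j) {
      augment(picked[[j]], seed = aug_seed + j)
    })
  }
  stack_batch(picked, with_masks = with_masks)
}

#' Train the adversarial segmentation model
#'
#' Runs the two-branch protocol: supervised iterations minimise the joint loss
#' and update the discriminator on real and fake pairs; in `"semi"` mode each
#' iteration additionally draws an unlabeled batch and applies the adversarial
#' branch. Validation Dice is computed each epoch and the best (or last)
#' weights are kept.
#'
#' @param manifest a `dataset_manifest` (from [generate_dataset()] or
#'   [read_manifest()]).
#' @param cfg a [train_config()].
#' @param train_ids labeled ids to train on (default: all labeled ids).
#' @param val_ids labeled ids for validation (default: none — the final model
#'   is then the last epoch's).
#' @param log_file optional CSV path receiving per-epoch losses.
#' @param verbose print one line per epoch.
#' @return a `run_record`: list with `G`, `D`, per-epoch `history` data frame,
#'   `best_epoch`, `val_dice`, and the `config`.
#' @export
train <- function(manifest, cfg, train_ids = NULL, val_ids = NULL,
                  log_file = NULL, verbose = FALSE) {
  if (!inherits(manifest, "dataset_manifest")) stop("manifest must be a dataset_manifest")
  if (is.null(train_ids)) train_ids <- manifest$labeled$id
  if (length(train_ids) == 0L) stop("no labeled training ids")
  unl_ids <- if (!is.null(manifest$unlabeled)) manifest$unlabeled$id else character(0)
  if (cfg$mode == "semi" && length(unl_ids) == 0L) {
    stop("semi-supervised mode requires unlabeled images in the manifest")
  }
  set.seed(cfg$seed)
  spec <- encoder_spec(cfg$encoder)
  G <- build_segmentor(spec, skip_connections = cfg$skip_connections)
  D <- build_discriminator(discriminator_spec(cfg$disc_base_width))
  labeled <- load_samples(manifest, train_ids, labeled = TRUE)
  unlabeled <- if (length(unl_ids) > 0L) load_samples(manifest, unl_ids, labeled = FALSE) else list()
  val <- if (!is.null(val_ids)) load_samples(manifest, val_ids, labeled = TRUE) else NULL

  nl <- length(labeled)
  bs <- min(cfg$batch_size, nl)
  iters <- ceiling(nl / bs)
  hist <- list()
  val_dice <- numeric(0)
  best <- -Inf; best_epoch <- NA_integer_; best_weights <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(nl)
    unl_ord <- if (length(unlabeled) > 0L) sample.int(length(unlabeled)) else integer(0)
    ep <- c(bce = 0, dice = 0, adv = 0, joint = 0, d = 0, adv_u = 0, d_u = 0)
    nsup <- 0L; nuns <- 0L
    for (it in seq_len(iters)) {
      idx <- ord[((it - 1L) * bs + 1L):min(it * bs, nl)]
      batch <- prep_batch(labeled, idx, cfg, TRUE, cfg$augment,
                          aug_seed = cfg$seed + 1000L * epoch + 10L * it)
      ls <- supervised_step(G, D, batch, cfg)
      ep[c("bce", "dice", "adv", "joint", "d")] <-
        ep[c("bce", "dice", "adv", "joint", "d")] + unlist(ls)
      nsup <- nsup + 1L
      if (cfg$mode == "semi" && epoch > cfg$warmup_epochs) {
        nu <- length(unlabeled)
        start <- ((it - 1L) * bs) %% nu
        uidx <- unl_ord[(start + seq_len(min(bs, nu)) - 1L) %% nu + 1L]
        ubatch <- prep_batch(unlabeled, uidx,
                             cfg, FALSE, cfg$augment && cfg$augment_unlabeled,
                             aug_seed = cfg$seed + 1000L * epoch + 10L * it + 5L)
        us <- unsupervised_step(G, D, ubatch, cfg,
                                real_batch = if (cfg$d_real_resample) batch else NULL)
        ep["adv_u"] <- ep["adv_u"] + us$adv
        ep["d_u"] <- ep["d_u"] + us$d
        nuns <- nuns + 1L
      }
    }
    ep[c("bce", "dice", "adv", "joint", "d")] <-
      ep[c("bce", "dice", "adv", "joint", "d")] / max(nsup, 1L)
    if (nuns > 0L) ep[c("adv_u", "d_u")] <- ep[c("adv_u", "d_u")] / nuns
    vd <- NA_real_
    if (!is.null(val)) {
      vb <- stack_batch(val, with_masks = TRUE)
      vp <- segment(G, vb$images)
      dices <- vapply(seq_along(val), function(b) {
        cm <- confusion(binarize(matrix(vp[b, 1L, , ], dim(vp)[3L]), cfg$threshold),
                        matrix(vb$masks[b, 1L, , ], dim(vp)[3L]))
        dsc(cm)
      }, numeric(1))
      vd <- mean(dices)
      if (cfg$selection == "best" && vd >= best) {
        best <- vd; best_epoch <- epoch; best_weights <- get_weights(G)
      }
    }
    val_dice <- c(val_dice, vd)
    hist[[epoch]] <- c(epoch = epoch, ep, val_dice = vd)
    if (verbose) {
      message(sprintf("epoch %3d  joint %.4f  d %.4f  adv_u %.4f  val_dice %s",
                      epoch, ep[["joint"]], ep[["d"]], ep[["adv_u"]],
                      ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  }
  if (cfg$selection == "best" && !is.null(best_weights)) set_weights(G, best_weights)
  if (is.na(best_epoch)) best_epoch <- cfg$epochs
  history <- as.data.frame(do.call(rbind, hist))
  if (!is.null(log_file)) utils::write.csv(history, log_file, row.names = FALSE)
  structure(list(G = G, D = D, history = history, best_epoch = best_epoch,
                 val_dice = val_dice, config = cfg),
            class = "run_record")
}

#' k-fold cross-validation
#'
#' Trains one model per fold (on the other folds) and evaluates it on the
#' held-out fold; per-image metrics are pooled over all folds.
#'
#' @param manifest a `dataset_manifest` carrying fold assignments.
#' @param cfg a [train_config()].
#' @param k number of folds (must match the manifest's assignment).
#' @param verbose print per-epoch lines.
#' @return list with `records` (per-fold `run_record`s), `reports` (per-fold
#'   [evaluate_set()] results) and `pooled` (a `metric_report` over all
#'   held-out images).
#' @export
cross_validate <- function(manifest, cfg, k = 4L, verbose = FALSE) {
  if (k < 2L) stop("k must be at least 2")
  folds <- manifest$folds
  if (length(unique(folds)) != k) stop("manifest folds do not match k")
  records <- list(); reports <- list()
  all_preds <- list(); all_gts <- list(); all_ids <- character(0)
  for (f in seq_len(k)) {
    hold <- names(folds)[folds == f]
    rest <- names(folds)[folds != f]
    rec <- train(manifest, cfg, train_ids = rest, val_ids = hold,
                 verbose = verbose)
    held <- load_samples(manifest, hold, labeled = TRUE)
    hb <- stack_batch(held, with_masks = TRUE)
    pp <- segment(rec$G, hb$images)
    preds <- lapply(seq_along(held), function(b) matrix(pp[b, 1L, , ], dim(pp)[3L]))
    gts <- lapply(held, function(s) s$mask)
    reports[[f]] <- evaluate_set(preds, gts, threshold = cfg$threshold, ids = hold)
    records[[f]] <- rec
    all_preds <- c(all_preds, preds); all_gts <- c(all_gts, gts)
    all_ids <- c(all_ids, hold)
  }
  pooled <- evaluate_set(all_preds, all_gts, threshold = cfg$threshold, ids = all_ids)
  list(records = records, reports = reports, pooled = pooled)
}

#' Evaluate a trained model on an image/mask directory pair
#'
#' Segments every image, binarises at the threshold, computes the metric
#' report, and optionally writes CSV/JSON reports and overlay PNGs (yellow =
#' correct lesion, red = false positive, blue = false negative).
#'
#' @param model a `segmentor` or a checkpoint path (RDS from
#'   [save_checkpoint()]).
#' @param image_dir directory of RGB PNGs.
#' @param mask_dir directory of mask PNGs with matching file names.
#' @param threshold binarisation threshold.
#' @param out_dir optional output directory for `report.csv`, `report.json`
#'   and overlays.
#' @param overlays write overlay PNGs.
#' @return a `metric_report`.
#' @export
evaluate <- function(model, image_dir, mask_dir, threshold = 0.5,
                     out_dir = NULL, overlays = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  imgs <- sort(list.files(image_dir, pattern = "\\.png$"))
  msks <- sort(list.files(mask_dir, pattern = "\\.png$"))
  orphans <- c(setdiff(imgs, msks), setdiff(msks, imgs))
  if (length(orphans) > 0L) {
    stop("unpaired files: ", paste(orphans, collapse = ", "))
  }
  if (length(imgs) == 0L) stop("no PNG images found in ", image_dir)
  preds <- list(); gts <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(imgs)) {
    s <- read_pair(file.path(image_dir, imgs[i]), file.path(mask_dir, msks[i]))
    x <- sample_to_input(s)
    p <- segment(model, x)
    pm <- matrix(p[1L, 1L, , ], dim(p)[3L])
    preds[[i]] <- pm
    gts[[i]] <- s$mask
    if (overlays && !is.null(out_dir)) {
      bm <- binarize(pm, threshold)
      ov <- s$image / 255
      tp <- bm == 1 & s$mask == 1; fp <- bm == 1 & s$mask == 0
      fn <- bm == 0 & s$mask == 1
      r <- ov[, , 1]; g <- ov[, , 2]; b <- ov[, , 3]
      r[tp] <- 1; g[tp] <- 1; b[tp] <- 0      # yellow: correct
      r[fp] <- 1; g[fp] <- 0; b[fp] <- 0      # red: false positive
      r[fn] <- 0; g[fn] <- 0; b[fn] <- 1      # blue: false negative
      ov[, , 1] <- r; ov[, , 2] <- g; ov[, , 3] <- b
      png::writePNG(ov, file.path(out_dir, paste0("overlay_", imgs[i])))
    }
  }
  report <- evaluate_set(preds, gts, threshold = threshold,
                         ids = sub("\\.png$", "", imgs))
  if (!is.null(out_dir)) {
    write_metric_report(report, file.path(out_dir, "report.csv"),
                        file.path(out_dir, "report.json"))
  }
  report
}
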