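test_that("configuration defaults match the published training setting", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 5e-4)
  expect_equal(cfg$weight_decay, 1e-4)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$image_size, 512L)
  expect_equal(unname(cfg$loss_weights), c(1, 1, 1))
  expect_error(train_config(image_size = 100), "divisible")
})

make_toy_batch <- function(n = 2, seed = 1) {
  samples <- lapply(seq_len(n), function(i) generate_sample("flaky", 64, seed + i))
  fluoroseg:::stack_batch(samples, with_masks = TRUE)
}

test_that("a zero learning rate freezes both networks", {
  set.seed(1)
  G <- build_segmentor(encoder_spec("tiny"))
  D <- build_discriminator(discriminator_spec(8L))
  cfg <- train_config(learning_rate = 0, mode = "supervised",
                      image_size = 64, encoder = "tiny", disc_base_width = 8)
  b <- make_toy_batch()
  l1 <- supervised_step(G, D, b, cfg)
  l2 <- supervised_step(G, D, b, cfg)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("the discriminator update leaves generator parameters untouched", {
  set.seed(2)
  G <- build_segmentor(encoder_spec("tiny"))
  D <- build_discriminator(discriminator_spec(8L))
  cfg <- train_config(learning_rate = 0.01, mode = "supervised",
                      image_size = 64, encoder = "tiny", disc_base_width = 8)
  b <- make_toy_batch()
  pred <- nn_forward(G, b$images)
  before <- get_weights(G)
  # run only the discriminator's half of the iteration
  fluoroseg:::nn_zero_grad(D)
  fs <- discriminate(D, b$images, pred)
  rs <- discriminate(D, b$images, b$masks)
  g <- fluoroseg:::discriminator_grad(fs, rs)
  nn_backward(D, g$real)
  fs <- discriminate(D, b$images, pred)
  nn_backward(D, g$fake)
  fluoroseg:::adam_step(fluoroseg:::ensure_optimizer(D, cfg))
  expect_identical(get_weights(G), before)
})

test_that("twenty steps on one easy batch strictly reduce the joint loss", {
  set.seed(3)
  G <- build_segmentor(encoder_spec("tiny"))
  D <- build_discriminator(discriminator_spec(8L))
  cfg <- train_config(learning_rate = 0.01, mode = "supervised",
                      image_size = 64, encoder = "tiny", disc_base_width = 8,
                      d_lr_factor = 0.05)
  b <- make_toy_batch(n = 2, seed = 40)
  first <- NULL; last <- NULL
  for (s in 1:20) {
    ls <- supervised_step(G, D, b, cfg)
    if (s == 1) first <- ls$joint
    last <- ls$joint
    expect_true(all(is.finite(unlist(ls))))
  }
  expect_lt(last, first)
})

test_that("unsupervised steps ignore masks and stay finite when alternated", {
  set.seed(4)
  G <- build_segmentor(encoder_spec("tiny"))
  D <- build_discriminator(discriminator_spec(8L))
  cfg <- train_config(learning_rate = 0.005, mode = "semi",
                      image_size = 64, encoder = "tiny", disc_base_width = 8,
                      d_lr_factor = 0.05)
  lb <- make_toy_batch(n = 2, seed = 50)
  ub <- list(images = fluoroseg:::stack_batch(
    lapply(1:2, function(i) generate_sample("point_like", 64, 60 + i)),
    with_masks = FALSE)$images, masks = NULL)
  ub_markered <- ub; ub_markered$masks <- lb$masks
  expect_warning(unsupervised_step(G, D, ub_markered, cfg),
                 "ignores the masks")
  for (s in 1:10) {
    sl <- supervised_step(G, D, lb, cfg)
    ul <- unsupervised_step(G, D, ub, cfg)
    expect_true(all(is.finite(c(unlist(sl), unlist(ul)))))
    expect_gt(ul$adv, 0)
  }
})

test_that("training validates its inputs and reproduces identical loss curves", {
  man <- tiny_dataset()
  # manifest without unlabeled data cannot run the semi protocol
  man_nou <- man; man_nou$unlabeled <- NULL
  expect_error(train(man_nou, tiny_train_config("semi")), "requires unlabeled")

  cfg <- tiny_train_config(mode = "supervised", seed = 5, epochs = 2)
  ids <- man$labeled$id
  r1 <- train(man, cfg, train_ids = ids[1:4], val_ids = ids[5:6])
  r2 <- train(man, cfg, train_ids = ids[1:4], val_ids = ids[5:6])
  expect_equal(r1$history, r2$history, tolerance = 1e-12)
  expect_true(all(is.finite(as.matrix(r1$history))))
  expect_length(r1$val_dice, 2)
})

test_that("the two optimizers hold disjoint parameter sets", {
  man <- tiny_dataset()
  cfg <- tiny_train_config(mode = "supervised", seed = 6, epochs = 1)
  rec <- train(man, cfg, train_ids = man$labeled$id[1:4])
  eg <- lapply(rec$G$optimizer$slots, function(s) s$env)
  ed <- lapply(rec$D$optimizer$slots, function(s) s$env)
  for (a in eg) for (b in ed) expect_false(identical(a, b))
})

test_that("cross-validation holds each image out exactly once and pools metrics", {
  man <- tiny_dataset()
  cfg <- tiny_train_config(mode = "supervised", seed = 7, epochs = 1)
  cv <- cross_validate(man, cfg, k = 4)
  expect_length(cv$records, 4)
  held <- unlist(lapply(cv$reports, function(r) r$per_image$id))
  expect_setequal(held, man$labeled$id)
  expect_length(held, length(man$labeled$id))
  # pooled aggregate equals recomputation from the pooled per-image rows
  pooled_dsc <- cv$pooled$per_image$dsc[match(held, cv$pooled$per_image$id)]
  per_fold <- unlist(lapply(cv$reports, function(r) r$per_image$dsc))
  expect_equal(pooled_dsc, per_fold, tolerance = 1e-12)
  expect_equal(cv$pooled$summary$mean[1], mean(per_fold), tolerance = 1e-12)
  expect_error(cross_validate(man, cfg, k = 1), "at least 2")
})

test_that("directory evaluation reports sensitivity zero for an all-background model", {
  man <- tiny_dataset()
  G <- build_segmentor(encoder_spec("tiny"), seed = 8)
  G$head$W[] <- 0
  G$head$b <- -10          # logistic(-10) ~ 0: predicts background everywhere
  # paired directories: labeled images only
  idir <- file.path(tempdir(), "eval-imgs"); mdir <- file.path(tempdir(), "eval-msks")
  unlink(c(idir, mdir), recursive = TRUE)
  dir.create(idir); dir.create(mdir)
  for (id in man$labeled$id[1:4]) {
    file.copy(file.path(man$dir, "images", paste0(id, ".png")), idir)
    file.copy(file.path(man$dir, "masks", paste0(id, ".png")), mdir)
  }
  rep <- suppressWarnings(
    evaluate(G, idir, mdir,
             out_dir = file.path(tempdir(), "evalout"), overlays = TRUE))
  expect_equal(rep$summary$mean[rep$summary$metric == "sen"], 0)
  expect_true(file.exists(file.path(tempdir(), "evalout", "report.csv")))
  expect_true(file.exists(file.path(tempdir(), "evalout", "report.json")))
  expect_gt(length(list.files(file.path(tempdir(), "evalout"),
                              pattern = "^overlay_")), 0)

  # orphaned files are reported by name
  file.copy(list.files(idir, full.names = TRUE)[1], file.path(idir, "extra.png"))
  expect_error(evaluate(G, idir, mdir), "extra.png")
})
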