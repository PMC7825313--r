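# Learning-rate schedule, augmentation, and the fitting loop.

test_that("learning-rate schedule decays exponentially", {
  expect_equal(lr_schedule(3e-4, 0), 3e-4)
  expect_equal(lr_schedule(3e-4, 10), 2.7e-4)
  expect_equal(lr_schedule(5e-3, 20), 0.81 * 5e-3)
  e <- 0:50
  lr <- lr_schedule(1e-3, e)
  expect_true(all(diff(lr) < 0))                    # strictly decreasing
  expect_equal(lr_schedule(2e-3, e), 2 * lr)        # linear in ilr
  # floor semantics agree at multiples of 10 and are piecewise constant
  expect_equal(lr_schedule(1, 10, floor = TRUE), lr_schedule(1, 10))
  expect_equal(lr_schedule(1, 19, floor = TRUE), 0.9)
  expect_error(lr_schedule(1e-3, -1), "nonnegative")
})

test_that("augmentation with zero ranges and no flip is the identity", {
  set.seed(61)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  cfg0 <- augment_config(shear = 0, rotation = 0, zoom = 0,
                         horizontal_flip = FALSE, shift = 0)
  a <- augment_pair(img, mask, cfg0)
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_equal(a$mask, mask)
})

test_that("augmentation is deterministic under a fixed RNG seed", {
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  set.seed(62); a <- augment_pair(img, mask)
  set.seed(62); b <- augment_pair(img, mask)
  expect_identical(a, b)
  set.seed(63); c_ <- augment_pair(img, mask)
  expect_false(identical(a$image, c_$image))
})

test_that("augmented image and mask stay aligned on noise-free blobs", {
  g <- generate_blobs(synth_spec(n_images = 3, size = 96, noise_sd = 0,
                                 foreground_fraction = c(0.08, 0.3),
                                 seed = 17))
  set.seed(64)
  for (i in 1:3) {
    a <- augment_pair(g$images[[i]], g$masks[[i]])
    # foreground intensity 0.8, background 0.2: threshold recovers the mask
    recovered <- (a$image >= 0.5) * 1L
    iou <- overlap_metrics(a$mask, recovered)$miou
    expect_gt(iou, 0.95)
    expect_true(all(a$mask %in% c(0, 1)))
  }
})

test_that("one small Adam step on a single sample decreases its hybrid loss", {
  m <- build_model(tiny_config("tunet", dropout_rate = 0))
  img <- rand_image(16, 1, seed = 65)
  mask <- rand_mask(16, 0.4, seed = 65)
  lc <- loss_config("dice_bce")
  loss_of <- function(model) {
    p <- predict(model, img)$final_output
    hybrid_loss(mask, c(p), lc)
  }
  before <- loss_of(m)
  tc <- train_config(ilr = 1e-4, epochs = 1, batch_size = 1, loss = lc,
                     input_size = 16, augment = FALSE, patience = 0, seed = 66)
  f <- fit_model(m, list(img), list(mask), tc)
  expect_lt(f$history$train_loss[1], before + 1e-9)
  expect_lt(loss_of(f$model), before)
})

test_that("fitting is reproducible run-to-run with a fixed seed", {
  imgs <- lapply(1:2, function(i) rand_image(16, 1, seed = i))
  msks <- lapply(1:2, function(i) rand_mask(16, 0.35, seed = i + 10))
  tc <- train_config(ilr = 3e-4, epochs = 2, batch_size = 2,
                     loss = loss_config("dice_bce"), input_size = 16,
                     augment = TRUE, patience = 0, seed = 9)
  set.seed(100)
  m <- build_model(tiny_config("tmdunet"))
  f1 <- fit_model(m, imgs, msks, tc)
  f2 <- fit_model(m, imgs, msks, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("early stopping halts within patience of the best validation epoch", {
  imgs <- lapply(1:3, function(i) rand_image(16, 1, seed = i))
  msks <- lapply(1:3, function(i) rand_mask(16, 0.35, seed = i + 20))
  tc <- train_config(ilr = 1e-3, epochs = 30, batch_size = 3,
                     loss = loss_config("dice_bce"), input_size = 16,
                     augment = FALSE, patience = 3, seed = 5)
  set.seed(101)
  m <- build_model(tiny_config("tunet"))
  f <- fit_model(m, imgs, msks, tc,
                 val_images = list(rand_image(16, 1, seed = 99)),
                 val_masks = list(rand_mask(16, 0.35, seed = 99)))
  h <- f$history
  best <- which.min(h$val_loss)
  expect_lte(nrow(h), best + 3)
  # empty dataset and shape mismatches are rejected
  expect_error(fit_model(m, list(), list(), tc), "empty")
  expect_error(fit_model(m, imgs, msks[1:2], tc), "differ in length")
})

test_that("history export writes one JSON object per epoch", {
  imgs <- list(rand_image(16, 1, seed = 1))
  msks <- list(rand_mask(16, 0.3, seed = 2))
  tc <- train_config(ilr = 1e-4, epochs = 2, batch_size = 1,
                     loss = loss_config("dice_bce"), input_size = 16,
                     augment = FALSE, patience = 0, seed = 8)
  set.seed(102)
  f <- fit_model(build_model(tiny_config("tunet")), imgs, msks, tc)
  path <- tempfile(fileext = ".jsonl")
  write_history_jsonl(f, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_equal(rec$epoch, 1)
  expect_equal(rec$lr, 1e-4)
})
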