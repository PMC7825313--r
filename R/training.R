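# Training harness: Adam, exponential learning-rate decay, paired
# image/mask augmentation, early stopping on validation loss.

#' Exponential learning-rate schedule
#'
#' `lr = ilr * 0.9^(epoch / 10)` with a real-valued exponent (smooth
#' decay); `floor = TRUE` switches to integer-division semantics
#' (piecewise-constant, dropping 10% every 10 epochs). Both readings agree
#' at multiples of 10.
#'
#' @param ilr initial learning rate.
#' @param epoch 0-based epoch number (scalar or vector).
#' @param floor use `floor(epoch / 10)` as the exponent.
#' @return learning rate(s).
#' @export
lr_schedule <- function(ilr, epoch, floor = FALSE) {
  if (any(epoch < 0)) stop("epoch must be nonnegative")
  e <- if (floor) epoch %/% 10 else epoch / 10
  ilr * 0.9^e
}

#' Augmentation configuration
#'
#' One random affine transform per sample, drawn from: shear angle
#' `U(-shear, shear)` radians, rotation `U(-rotation, rotation)` degrees,
#' per-axis zoom `U(1 - zoom, 1 + zoom)`, horizontal flip with probability
#' 1/2, and x/y shifts `U(-shift, shift)` of the image side. Out-of-image
#' samples are filled by reflection. The identical transform is applied to
#' the image and its mask; the mask is sampled nearest-neighbour and
#' re-binarized.
#'
#' @param shear shear intensity (radians).
#' @param rotation rotation range (degrees).
#' @param zoom zoom range.
#' @param horizontal_flip allow flips.
#' @param shift width/height shift range (fraction of the side).
#' @return object of class `tmd_augment_config`.
#' @export
augment_config <- function(shear = 0.5, rotation = 50, zoom = 0.2,
                           horizontal_flip = TRUE, shift = 0.2) {
  structure(list(shear = shear, rotation = rotation, zoom = zoom,
                 horizontal_flip = horizontal_flip, shift = shift),
            class = "tmd_augment_config")
}

#' Training configuration
#'
#' Defaults mirror the polyp learning setting: hybrid dice + weighted
#' cross-entropy, initial learning rate 3e-4, 200 epochs, batch size 8,
#' 224-pixel inputs, augmentation on.
#'
#' @param ilr initial learning rate.
#' @param epochs maximum number of epochs.
#' @param batch_size images per optimization step.
#' @param loss a [loss_config()].
#' @param input_size square input side in pixels.
#' @param augment logical; apply [augment_pair()] to every training sample.
#' @param augment_cfg an [augment_config()].
#' @param patience early-stopping patience in epochs (on validation loss;
#'   ignored without a validation set).
#' @param lr_floor use integer-division semantics in [lr_schedule()].
#' @param target_dsc optional training-DSC level at which to stop early.
#' @param seed integer seed fixing shuffling, dropout and augmentation.
#' @return object of class `tmd_train_config`.
#' @export
train_config <- function(ilr = 3e-4, epochs = 200L, batch_size = 8L,
                         loss = loss_config("dice_wce"),
                         input_size = 224L, augment = TRUE,
                         augment_cfg = augment_config(),
                         patience = 10L, lr_floor = FALSE,
                         target_dsc = NULL, seed = 1L) {
  stopifnot(inherits(loss, "tmd_loss_config"),
            inherits(augment_cfg, "tmd_augment_config"))
  if (ilr <= 0) stop("ilr must be positive")
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  structure(list(ilr = ilr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 input_size = as.integer(input_size), augment = augment,
                 augment_cfg = augment_cfg, patience = as.integer(patience),
                 lr_floor = lr_floor, target_dsc = target_dsc,
                 seed = as.integer(seed)),
            class = "tmd_train_config")
}

# reflect 0-based coordinates into [0, n): (dcba|abcd|dcba) boundary
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- i %% (2 * n)
  p <- ifelse(p < 0, p + 2 * n, p)
  ifelse(p >= n, 2 * n - 1 - p, p)
}

# sample image at fractional 0-based coords with reflection fill
sample_bilinear <- function(m, ys, xs) {
  d <- dim(m)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  at <- function(yy, xx)
    m[cbind(reflect_index(yy, d[1]) + 1, reflect_index(xx, d[2]) + 1)]
  at(y0, x0) * (1 - fy) * (1 - fx) + at(y0 + 1, x0) * fy * (1 - fx) +
    at(y0, x0 + 1) * (1 - fy) * fx + at(y0 + 1, x0 + 1) * fy * fx
}

sample_nearest <- function(m, ys, xs) {
  d <- dim(m)
  m[cbind(reflect_index(round(ys), d[1]) + 1,
          reflect_index(round(xs), d[2]) + 1)]
}

#' Apply one random affine augmentation to an image/mask pair
#'
#' Draws a transform from `config` using the current RNG state and applies
#' it identically to both. With all ranges zero and flips off this is the
#' identity.
#'
#' @param image matrix or `H x W x C` array.
#' @param mask binary matrix congruent with `image`.
#' @param config an [augment_config()].
#' @return list with transformed `image` and (re-binarized) `mask`.
#' @export
augment_pair <- function(image, mask, config = augment_config()) {
  stopifnot(inherits(config, "tmd_augment_config"))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  theta <- stats::runif(1, -config$rotation, config$rotation) * pi / 180
  shear <- stats::runif(1, -config$shear, config$shear)
  zx <- stats::runif(1, 1 - config$zoom, 1 + config$zoom)
  zy <- stats::runif(1, 1 - config$zoom, 1 + config$zoom)
  tx <- stats::runif(1, -config$shift, config$shift) * w
  ty <- stats::runif(1, -config$shift, config$shift) * h
  flip <- config$horizontal_flip && stats::runif(1) < 0.5

  # forward map: rotate . shear . zoom (about the center), then shift/flip;
  # we sample the inverse at every output pixel
  ct <- cos(theta); st <- sin(theta)
  A <- matrix(c(ct, st, -st, ct), 2) %*%
       matrix(c(1, 0, -sin(shear), cos(shear)), 2) %*%
       diag(c(zx, zy))
  Ai <- solve(A)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  out_x <- rep(seq_len(w) - 1, each = h)
  out_y <- rep(seq_len(h) - 1, times = w)
  ox <- if (flip) (w - 1) - out_x else out_x
  dx <- ox - cx - tx; dy <- out_y - cy - ty
  src_x <- Ai[1, 1] * dx + Ai[1, 2] * dy + cx
  src_y <- Ai[2, 1] * dx + Ai[2, 2] * dy + cy

  warp_one <- function(m, fun) {
    out <- fun(m, src_y, src_x)
    dim(out) <- c(h, w)
    out
  }
  img_out <- if (length(d) == 2L) warp_one(image, sample_bilinear)
  else {
    o <- array(0, d)
    for (c_ in seq_len(d[3])) o[, , c_] <- warp_one(image[, , c_],
                                                    sample_bilinear)
    o
  }
  mask_out <- (warp_one(mask, sample_nearest) >= 0.5) * 1L
  list(image = img_out, mask = mask_out)
}

soft_to_hard_dsc <- function(y, p, threshold = 0.5) {
  overlap_metrics(as.vector(y), as.vector((p >= threshold) * 1L))$dsc
}

#' Fit a segmentation model
#'
#' Adam optimization of the hybrid loss on the final fused output, with the
#' exponential learning-rate schedule, optional paired augmentation, and
#' early stopping on validation loss (best-validation weights restored).
#' Batch normalization uses per-sample spatial statistics during training
#' and running moments at evaluation. The run is deterministic for a fixed
#' config seed.
#'
#' @param model a [build_model()] result.
#' @param images list of training images (arrays matching the model input).
#' @param masks list of binary masks congruent with `images`.
#' @param config a [train_config()].
#' @param val_images,val_masks optional validation set; enables early
#'   stopping and the `val_*` history columns.
#' @param deep_supervision also apply the loss to the three sub-outputs
#'   (averaged with the final-output loss). Off by default: the loss is
#'   applied to the fused output only.
#' @param verbose print one line per epoch.
#' @return object of class `tmd_fit`: list with `model` (trained weights;
#'   best-validation weights when early stopping is active), `history`
#'   (data frame: epoch, lr, train_loss, train_dsc, val_loss, val_dsc) and
#'   `config`.
#' @export
fit_model <- function(model, images, masks, config = train_config(),
                      val_images = NULL, val_masks = NULL,
                      deep_supervision = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "tmd_model"), inherits(config, "tmd_train_config"))
  if (length(images) == 0L) stop("empty training set")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  has_val <- !is.null(val_images)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  params <- model$params
  st <- adam_state(params)
  final_id <- model$outputs[["final_output"]]
  sub_ids <- model$outputs[grepl("^sub_output_", names(model$outputs))]
  loss_cfg <- config$loss

  hist <- list()
  best_val <- Inf; best_params <- NULL; wait <- 0L
  n <- length(images)

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(config$ilr, epoch - 1L, config$lr_floor)
    ord <- sample.int(n)
    ep_loss <- 0; ep_dsc <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      bgrads <- NULL
      for (i in idx) {
        img <- images[[i]]; msk <- masks[[i]]
        if (config$augment) {
          a <- augment_pair(img, msk, config$augment_cfg)
          img <- a$image; msk <- a$mask
        }
        if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
        mdl <- model; mdl$params <- params
        fw <- graph_forward(mdl, img, training = TRUE)
        for (layer in names(fw$bn_updates))
          params[[layer]][c("rmean", "rvar")] <- fw$bn_updates[[layer]]
        pred <- fw$vals[[final_id]]
        ep_loss <- ep_loss + hybrid_loss(msk, c(pred), loss_cfg)
        ep_dsc <- ep_dsc + soft_to_hard_dsc(msk, c(pred))
        seeds <- list()
        gF <- hybrid_loss_grad(msk, c(pred), loss_cfg)
        if (deep_supervision) {
          scale <- 1 / (1 + length(sub_ids))
          seeds[[final_id]] <- array(gF * scale, dim = dim(pred))
          for (sid in sub_ids) {
            ps <- fw$vals[[sid]]
            gs <- hybrid_loss_grad(msk, c(ps), loss_cfg) * scale
            seeds[[sid]] <- array(gs, dim = dim(ps))
          }
        } else {
          seeds[[final_id]] <- array(gF, dim = dim(pred))
        }
        g <- graph_backward(mdl, fw, seeds)
        bgrads <- if (is.null(bgrads)) g else merge_grads(bgrads, g)
      }
      bgrads <- scale_grads(bgrads, 1 / length(idx))
      upd <- adam_step(params, bgrads, st, lr)
      params <- upd$params; st <- upd$state
    }
    ep_loss <- ep_loss / n; ep_dsc <- ep_dsc / n

    val_loss <- NA_real_; val_dsc <- NA_real_
    if (has_val) {
      mdl <- model; mdl$params <- params
      vl <- 0; vd <- 0
      for (i in seq_along(val_images)) {
        vi <- val_images[[i]]
        if (is.matrix(vi)) dim(vi) <- c(dim(vi), 1L)
        fw <- graph_forward(mdl, vi, training = FALSE, keep_cache = FALSE)
        p <- fw$vals[[final_id]]
        vl <- vl + hybrid_loss(val_masks[[i]], c(p), loss_cfg)
        vd <- vd + soft_to_hard_dsc(val_masks[[i]], c(p))
      }
      val_loss <- vl / length(val_images)
      val_dsc <- vd / length(val_images)
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss, train_dsc = ep_dsc,
                                val_loss = val_loss, val_dsc = val_dsc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  dsc %.4f%s",
                      epoch, lr, ep_loss, ep_dsc,
                      if (has_val) sprintf("  val_loss %.4f  val_dsc %.4f",
                                           val_loss, val_dsc) else ""))
    if (has_val && config$patience > 0L) {
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    if (!is.null(config$target_dsc) && ep_dsc >= config$target_dsc) break
  }

  model$params <- if (!is.null(best_params)) best_params else params
  structure(list(model = model, history = do.call(rbind, hist),
                 config = config),
            class = "tmd_fit")
}

merge_grads <- function(a, b) {
  for (layer in names(b))
    for (nm in names(b[[layer]]))
      a[[layer]][[nm]] <- if (is.null(a[[layer]][[nm]])) b[[layer]][[nm]]
                          else a[[layer]][[nm]] + b[[layer]][[nm]]
  a
}

scale_grads <- function(g, s) {
  for (layer in names(g))
    for (nm in names(g[[layer]]))
      g[[layer]][[nm]] <- g[[layer]][[nm]] * s
  g
}

#' @export
print.tmd_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<tmd_fit> %d epoch(s); final train loss %.4f, train DSC %.4f\n",
              nrow(h), last$train_loss, last$train_dsc))
  if (!is.na(last$val_loss))
    cat(sprintf("          final val loss %.4f, val DSC %.4f\n",
                last$val_loss, last$val_dsc))
  invisible(x)
}

#' Write a training history as JSON lines
#'
#' @param fit a [fit_model()] result.
#' @param path destination .jsonl, one epoch per line.
#' @return `path`, invisibly.
#' @export
write_history_jsonl <- function(fit, path) {
  stopifnot(inherits(fit, "tmd_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fit$history)))
    writeLines(jsonlite::toJSON(as.list(fit$history[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}
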