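# Deterministic synthetic blob images, masks and slice volumes.  These
# stand in for real 2-D medical images in tests and examples: bright
# elliptical foreground structures on a darker background with additive
# Gaussian noise, plus the exact rasterized mask.  They emulate foreground/
# background contrast and class imbalance, not modality texture or physics.

#' Synthetic data specification
#'
#' @param n_images number of image/mask pairs.
#' @param size square image side in pixels (128 and 224 mirror the two
#'   input sizes the networks are trained at).
#' @param channels 1 (grayscale) or 3 (identical structure per channel
#'   before noise).
#' @param n_blobs range (min, max) of ellipses per image.
#' @param foreground_fraction admissible range of the realized per-image
#'   mask fraction; images are redrawn until the rasterized mask falls in
#'   the range.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensities are finally clipped to `[0, 1]`).
#' @param seed integer seed making the spec fully deterministic.
#' @return object of class `tmd_synth_spec`.
#' @export
synth_spec <- function(n_images = 8L, size = 128L, channels = 1L,
                       n_blobs = c(1L, 3L),
                       foreground_fraction = c(0.05, 0.45),
                       noise_sd = 0.05, seed = 1L) {
  if (!channels %in% c(1L, 3L)) stop("channels must be 1 or 3")
  if (length(n_blobs) != 2L || n_blobs[1] < 1L || n_blobs[2] < n_blobs[1])
    stop("n_blobs must be an increasing positive range")
  if (length(foreground_fraction) != 2L ||
      foreground_fraction[1] <= 0 || foreground_fraction[2] >= 1 ||
      diff(foreground_fraction) <= 0)
    stop("foreground_fraction must be an increasing range inside (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 channels = as.integer(channels),
                 n_blobs = as.integer(n_blobs),
                 foreground_fraction = foreground_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tmd_synth_spec")
}

# exact raster of a union of ellipses on an s x s grid (pixel centers)
rasterize_ellipses <- function(size, ellipses) {
  m <- matrix(0L, size, size)
  xs <- matrix(rep(seq_len(size), each = size), size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size)  # row index
  for (e in ellipses) {
    ct <- cos(e$theta); st <- sin(e$theta)
    dx <- xs - e$cx; dy <- ys - e$cy
    u <- (dx * ct + dy * st) / e$rx
    v <- (-dx * st + dy * ct) / e$ry
    m[u^2 + v^2 <= 1] <- 1L
  }
  m
}

draw_ellipses <- function(size, n, target_range) {
  # radii scaled so that n blobs can plausibly land inside the target range
  mid <- mean(target_range)
  r0 <- size * sqrt(mid / (pi * n))
  lapply(seq_len(n), function(i)
    list(cx = stats::runif(1, 0.2 * size, 0.8 * size),
         cy = stats::runif(1, 0.2 * size, 0.8 * size),
         rx = r0 * stats::runif(1, 0.6, 1.4),
         ry = r0 * stats::runif(1, 0.6, 1.4),
         theta = stats::runif(1, 0, pi)))
}

#' Generate synthetic blob images and masks
#'
#' Each image is the union of randomly placed ellipses (foreground
#' intensity about 0.8, background about 0.2) with additive Gaussian noise;
#' the mask is the exact rasterized ellipse union. Output is reproducible:
#' the same spec yields bit-identical results.
#'
#' @param spec a [synth_spec()].
#' @return list with `images` (list of `size x size` matrices or
#'   `size x size x 3` arrays, values in `[0, 1]`) and `masks` (list of
#'   binary matrices whose foreground fraction lies in the spec's range).
#' @export
generate_blobs <- function(spec) {
  stopifnot(inherits(spec, "tmd_synth_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  images <- vector("list", spec$n_images)
  masks <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    for (try in 1:200) {
      n <- sample(spec$n_blobs[1]:spec$n_blobs[2], 1L)
      mask <- rasterize_ellipses(spec$size,
                                 draw_ellipses(spec$size, n,
                                               spec$foreground_fraction))
      frac <- mean(mask)
      if (frac >= spec$foreground_fraction[1] &&
          frac <= spec$foreground_fraction[2]) break
      if (try == 200)
        stop("foreground_fraction range infeasible for this geometry")
    }
    base <- 0.2 + 0.6 * mask
    img <- if (spec$channels == 1L) {
      base + stats::rnorm(length(base), sd = spec$noise_sd)
    } else {
      array(rep(base, 3L), dim = c(spec$size, spec$size, 3L)) +
        stats::rnorm(3L * length(base), sd = spec$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- if (spec$channels == 1L) c(spec$size, spec$size)
                else c(spec$size, spec$size, 3L)
    images[[i]] <- img
    masks[[i]] <- mask
  }
  list(images = images, masks = masks)
}

#' Generate a synthetic slice volume
#'
#' Slices inside `organ_span` contain one centered blob (foreground flag
#' true); slices outside are empty. Exercises the volume operators
#' ([stack_adjacent()], [decimate_empty()]) deterministically.
#'
#' @param n_slices number of slices.
#' @param size square slice side in pixels.
#' @param organ_span integer range `c(first, last)` of slices containing
#'   foreground, or `NULL` for an entirely empty volume.
#' @param seed integer seed.
#' @return a [slice_volume()].
#' @export
generate_volume <- function(n_slices, size = 64L, organ_span = NULL,
                            seed = 1L) {
  if (!is.null(organ_span)) {
    if (length(organ_span) != 2L || organ_span[1] < 1L ||
        organ_span[2] > n_slices || organ_span[1] > organ_span[2])
      stop("organ_span must lie inside [1, n_slices]")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  slices <- vector("list", n_slices)
  masks <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    inside <- !is.null(organ_span) && i >= organ_span[1] && i <= organ_span[2]
    mask <- if (inside) {
      r <- size * stats::runif(1, 0.12, 0.25)
      rasterize_ellipses(size, list(list(cx = size / 2, cy = size / 2,
                                         rx = r, ry = r, theta = 0)))
    } else matrix(0L, size, size)
    img <- pmin(pmax(0.2 + 0.6 * mask +
                       stats::rnorm(size * size, sd = 0.05), 0), 1)
    dim(img) <- c(size, size)
    slices[[i]] <- img
    masks[[i]] <- mask
  }
  slice_volume(slices, masks)
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
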