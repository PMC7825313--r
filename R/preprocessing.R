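# Dataset-preparation operators for 2-D images and CT/MRI slice volumes.
# Coordinates are 0-based with half-open windows [origin, origin + window),
# matching the tile manifest written by the command-line interface.

#' Sliding-window tile grid
#'
#' Deterministic decomposition of an `size_y x size_x` image into square
#' windows laid out row-major. The geometry must divide exactly:
#' `(size - window)` must be a multiple of `stride` on both axes; partial
#' windows are rejected rather than padded. Adjacent same-row windows
#' overlap in a `window x (window - stride)` region.
#'
#' @param size_y,size_x image size in pixels.
#' @param window square window side.
#' @param stride step between window origins (both axes).
#' @return object of class `tmd_tile_grid`: list with `window`, `stride`,
#'   and `origins`, a row-major data frame of 0-based `row`, `col`,
#'   `origin_y`, `origin_x`.
#' @export
tile_grid <- function(size_y, size_x, window, stride) {
  if (window > size_y || window > size_x)
    stop("window (", window, ") exceeds image size")
  if ((size_y - window) %% stride != 0 || (size_x - window) %% stride != 0)
    stop("tiling geometry does not divide exactly: (size - window) must be ",
         "a multiple of stride; got size ", size_y, "x", size_x,
         ", window ", window, ", stride ", stride)
  oy <- seq.int(0L, size_y - window, by = stride)
  ox <- seq.int(0L, size_x - window, by = stride)
  origins <- data.frame(
    row = rep(seq_along(oy) - 1L, each = length(ox)),
    col = rep(seq_along(ox) - 1L, times = length(oy)),
    origin_y = rep(oy, each = length(ox)),
    origin_x = rep(ox, times = length(oy)))
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 size_y = as.integer(size_y), size_x = as.integer(size_x),
                 origins = origins),
            class = "tmd_tile_grid")
}

#' Extract sliding-window tiles from an image
#'
#' @param image matrix (`H x W`) or array (`H x W x C`).
#' @param window square window side in pixels.
#' @param stride step between window origins.
#' @return list with `tiles` (list of arrays in row-major grid order) and
#'   `grid` (the [tile_grid()]).
#' @export
tile_image <- function(image, window, stride) {
  d <- dim(image)
  grid <- tile_grid(d[1], d[2], window, stride)
  tiles <- lapply(seq_len(nrow(grid$origins)), function(i) {
    y <- grid$origins$origin_y[i]
    x <- grid$origins$origin_x[i]
    if (length(d) == 2L) image[y + seq_len(window), x + seq_len(window)]
    else image[y + seq_len(window), x + seq_len(window), , drop = FALSE]
  })
  list(tiles = tiles, grid = grid)
}

#' Reassemble tiles by averaging overlaps
#'
#' Inverse of [tile_image()] for single-channel tiles: overlapping regions
#' are averaged, so tiling a constant image and reassembling reproduces it
#' exactly, and any valid geometry covers every pixel at least once.
#'
#' @param tiles list of matrices in the grid's row-major order.
#' @param grid a [tile_grid()].
#' @return matrix of the original image size.
#' @export
untile_image <- function(tiles, grid) {
  stopifnot(inherits(grid, "tmd_tile_grid"))
  acc <- matrix(0, grid$size_y, grid$size_x)
  cnt <- matrix(0, grid$size_y, grid$size_x)
  w <- grid$window
  for (i in seq_len(nrow(grid$origins))) {
    ys <- grid$origins$origin_y[i] + seq_len(w)
    xs <- grid$origins$origin_x[i] + seq_len(w)
    acc[ys, xs] <- acc[ys, xs] + tiles[[i]]
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  if (any(cnt == 0)) stop("grid does not cover the image")
  acc / cnt
}

#' Intensity windowing
#'
#' Clips intensities to `[low, high]` (a Hounsfield-unit window for CT) and
#' maps the range affinely to `[0, 1]`. Idempotent on already-windowed data
#' whenever `low <= 0` and `high >= 1`. The same operator is applied to MRI
#' with stated bounds even though Hounsfield units are not physically
#' defined there.
#'
#' @param x numeric vector, matrix, array or volume.
#' @param low,high window bounds, `low < high`.
#' @return `x` rescaled to `[0, 1]`, same shape.
#' @export
intensity_window <- function(x, low, high) {
  if (low >= high) stop("window requires low < high, got [", low, ", ",
                        high, "]")
  out <- (pmin(pmax(x, low), high) - low) / (high - low)
  dim(out) <- dim(x)
  out
}

#' Center crop
#'
#' Crops a centered `size x size` window; when a margin is odd the extra
#' pixel is dropped from the trailing side (the leading margin is the floor
#' of half).
#'
#' @param image matrix or `H x W x C` array.
#' @param size target side in pixels, at most the image size.
#' @return cropped image.
#' @export
center_crop <- function(image, size) {
  d <- dim(image)
  if (size > d[1] || size > d[2])
    stop("crop size ", size, " exceeds image size ", d[1], "x", d[2])
  oy <- (d[1] - size) %/% 2L
  ox <- (d[2] - size) %/% 2L
  if (length(d) == 2L) image[oy + seq_len(size), ox + seq_len(size)]
  else image[oy + seq_len(size), ox + seq_len(size), , drop = FALSE]
}

#' Resize an image or mask
#'
#' Bilinear interpolation for intensity images, nearest-neighbour for masks
#' (so binary masks stay binary). Delegates to `EBImage::resize()` when
#' EBImage is installed and falls back to a vectorized implementation of the
#' same interpolations otherwise.
#'
#' @param image matrix or `H x W x C` array.
#' @param size target size: one side (square) or `c(height, width)`.
#' @param kind `"bilinear"` or `"nearest"`.
#' @return resized image.
#' @export
resize_image <- function(image, size, kind = c("bilinear", "nearest")) {
  kind <- match.arg(kind)
  if (length(size) == 1L) size <- c(size, size)
  d <- dim(image)
  if (identical(as.integer(d[1:2]), as.integer(size)))
    return(image)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    out <- EBImage::resize(image, w = size[1], h = size[2],
                           filter = if (kind == "bilinear") "bilinear"
                                    else "none")
    out <- as.array(out)
    if (length(d) == 2L) dim(out) <- size else dim(out) <- c(size, d[3])
    return(out)
  }
  resize_fallback(image, size, kind)
}

# plain-R bilinear / nearest resize (align-corners = FALSE convention)
resize_fallback <- function(image, size, kind) {
  d <- dim(image)
  one <- function(m) {
    sy <- d[1] / size[1]; sx <- d[2] / size[2]
    cy <- (seq_len(size[1]) - 0.5) * sy - 0.5
    cx <- (seq_len(size[2]) - 0.5) * sx - 0.5
    if (kind == "nearest") {
      iy <- pmin(pmax(round(cy) + 1, 1), d[1])
      ix <- pmin(pmax(round(cx) + 1, 1), d[2])
      m[iy, ix, drop = FALSE]
    } else {
      y0 <- pmin(pmax(floor(cy), 0), d[1] - 1); fy <- cy - y0
      x0 <- pmin(pmax(floor(cx), 0), d[2] - 1); fx <- cx - x0
      y1 <- pmin(y0 + 1, d[1] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
      fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
      a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
      b <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
      cc <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
      dd <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
      a + b + cc + dd
    }
  }
  if (length(d) == 2L) one(image)
  else {
    out <- array(0, c(size, d[3]))
    for (c_ in seq_len(d[3])) out[, , c_] <- one(image[, , c_])
    out
  }
}

#' Slice volume
#'
#' An ordered stack of 2-D slices with per-slice foreground flags (mask
#' nonempty), the container consumed by [stack_adjacent()] and
#' [decimate_empty()].
#'
#' @param slices list of matrices (one per slice, congruent sizes).
#' @param masks optional list of binary masks congruent with `slices`; used
#'   to derive `flags`.
#' @param flags optional logical vector; overrides derivation from masks.
#' @return object of class `tmd_slice_volume`.
#' @export
slice_volume <- function(slices, masks = NULL, flags = NULL) {
  if (length(slices) == 0L) stop("empty volume")
  if (is.null(flags)) {
    if (is.null(masks)) stop("provide masks or flags")
    if (length(masks) != length(slices))
      stop("masks and slices differ in length")
    flags <- vapply(masks, function(m) any(m != 0), logical(1))
  }
  if (length(flags) != length(slices))
    stop("flags and slices differ in length")
  structure(list(slices = slices, masks = masks, flags = flags),
            class = "tmd_slice_volume")
}

#' Stack adjacent slices into a 3-channel image
#'
#' Channels are (slice i-1, slice i, slice i+1); at the volume boundary the
#' edge slice is duplicated. This exposes through-plane context to a 2-D
#' network.
#'
#' @param volume a [slice_volume()].
#' @param index slice position (1-based).
#' @return `H x W x 3` array.
#' @export
stack_adjacent <- function(volume, index) {
  stopifnot(inherits(volume, "tmd_slice_volume"))
  n <- length(volume$slices)
  if (index < 1L || index > n) stop("slice index out of range")
  pick <- function(i) volume$slices[[min(max(i, 1L), n)]]
  d <- dim(pick(index))
  array(c(pick(index - 1L), pick(index), pick(index + 1L)), dim = c(d, 3L))
}

#' Decimate foreground-free slices
#'
#' Scans maximal runs of consecutive slices without foreground and keeps
#' every third slice of each run starting from its first, dropping the
#' other two; all foreground slices are kept. A foreground-free run of
#' length L therefore keeps `ceiling(L / 3)` slices. This rebalances
#' volumes dominated by organ-free slices.
#'
#' @param volume a [slice_volume()].
#' @return integer vector of kept slice positions (1-based, increasing).
#' @export
decimate_empty <- function(volume) {
  stopifnot(inherits(volume, "tmd_slice_volume"))
  flags <- volume$flags
  keep <- logical(length(flags))
  i <- 1L
  while (i <= length(flags)) {
    if (flags[i]) {
      keep[i] <- TRUE
      i <- i + 1L
    } else {
      j <- i
      while (j <= length(flags) && !flags[j]) j <- j + 1L
      run <- i:(j - 1L)
      keep[run[(seq_along(run) - 1L) %% 3L == 0L]] <- TRUE
      i <- j
    }
  }
  which(keep)
}
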