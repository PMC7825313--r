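# Reading and writing the supported file formats: PNG/TIFF for 2-D images
# and masks, NIfTI for volumes, CSV for tile manifests.

#' Read a 2-D image (PNG or TIFF)
#'
#' @param path file ending in .png, .tif or .tiff.
#' @return numeric array, `H x W` or `H x W x C`, values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- switch(tolower(tools::file_ext(path)),
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", path))
  img
}

#' Write a 2-D image (PNG or TIFF)
#'
#' @param image numeric matrix or array with values in `[0, 1]`.
#' @param path destination ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image[] <- pmin(pmax(image, 0), 1)
  switch(tolower(tools::file_ext(path)),
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path),
         stop("unsupported image format: ", path))
  invisible(path)
}

#' Read a binary mask image
#'
#' Reads like [read_image()], collapses multi-channel files to their first
#' channel and binarizes at 0.5.
#'
#' @param path mask file.
#' @return binary matrix (0/1).
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m >= 0.5) * 1L
}

#' Write a probability map as an 8-bit PNG
#'
#' Pixel value is `round(255 * p)`, for quick visual inspection of
#' sub-network outputs.
#'
#' @param prob numeric matrix or `H x W x 1` array of probabilities.
#' @param path destination .png.
#' @return `path`, invisibly.
#' @export
write_prediction_png <- function(prob, path) {
  if (length(dim(prob)) == 3L) prob <- prob[, , 1L]
  png::writePNG(round(255 * pmin(pmax(prob, 0), 1)) / 255, path)
  invisible(path)
}

#' Read a NIfTI volume as a slice stack
#'
#' @param path .nii or .nii.gz file.
#' @return numeric 3-D array (`x, y, slice`).
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  arr <- as.array(v)
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
  arr
}

#' Write a 3-D array as NIfTI
#'
#' @param volume numeric 3-D array.
#' @param path destination .nii or .nii.gz.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' Write a tile manifest CSV
#'
#' Columns `image_id, row, col, origin_y, origin_x` (0-based origins).
#'
#' @param grid a [tile_grid()].
#' @param image_id identifier recorded for every tile row.
#' @param path destination .csv.
#' @return `path`, invisibly.
#' @export
write_tile_manifest <- function(grid, image_id, path) {
  stopifnot(inherits(grid, "tmd_tile_grid"))
  df <- cbind(image_id = image_id, grid$origins)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
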