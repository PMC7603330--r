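# ParenchymaMask: a binary image of lung parenchyma where TRUE marks open
# airspace and FALSE marks tissue, plus the pixel calibration needed to
# report chord lengths in micrometres.

#' Construct a parenchyma mask
#'
#' A `parenchyma_mask` wraps a logical matrix (`TRUE` = airspace, `FALSE` =
#' tissue) together with the pixel size in micrometres per pixel and an image
#' label. Matrix rows index y (top to bottom) and columns index x, matching
#' how raster images are stored.
#'
#' @param grid Logical matrix; `TRUE` marks airspace pixels.
#' @param pixel_size Micrometres per pixel; must be positive.
#' @param image_id Character label for the image.
#' @return An object of class `parenchyma_mask`.
#' @export
parenchyma_mask <- function(grid, pixel_size = 1, image_id = "image") {
  if (is.numeric(grid)) grid <- grid != 0
  if (!is.logical(grid) || !is.matrix(grid)) {
    abort("`grid` must be a logical (or numeric 0/1) matrix")
  }
  check_number(pixel_size, "pixel_size", min = .Machine$double.eps)
  structure(
    list(grid = grid, pixel_size = pixel_size, image_id = as.character(image_id)),
    class = "parenchyma_mask"
  )
}

#' @export
print.parenchyma_mask <- function(x, ...) {
  cat(sprintf(
    "<parenchyma_mask '%s'> %d x %d px, %.4g um/px, %.1f%% airspace\n",
    x$image_id, ncol(x$grid), nrow(x$grid), x$pixel_size,
    100 * mean(x$grid)
  ))
  invisible(x)
}

#' @export
dim.parenchyma_mask <- function(x) dim(x$grid)
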