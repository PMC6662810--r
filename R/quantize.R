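#' Reduce an 8-bit grayscale image to G gray levels
#'
#' Uniformly bins the intensity range \[0, 255\] into `levels` equal-width
#' bins, mapping each pixel to an integer level in `0:(levels - 1)`. All
#' texture matrices ([compute_glcm()], [compute_glrlm()]) operate on the
#' quantized grid. The mapping is monotone: brighter pixels never map to a
#' lower level.
#'
#' @param image numeric or integer matrix of gray values in \[0, 255\]
#'   (values in \[0, 1\], e.g. from [EBImage::readImage()], are rescaled).
#' @param levels number of gray levels G (>= 2). Default 64, a 6-bit
#'   reduction commonly applied before co-occurrence analysis of
#'   low-dynamic-range micrographs.
#' @param mask optional logical/binary matrix of identical dimensions;
#'   `TRUE`/nonzero marks pixels inside the region of interest.
#' @return an object of class `quantized_image`: list with `pixels`
#'   (integer matrix in `0:(levels-1)`), `levels`, and `mask` (logical
#'   matrix or `NULL`).
#' @examples
#' q <- quantize(matrix(0:255, 16, 16), levels = 4)
#' range(q$pixels)
#' @export
quantize <- function(image, levels = 64L, mask = NULL) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a nonempty matrix")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be an integer >= 2")
  v <- as.numeric(image)
  if (anyNA(v)) stop("`image` contains NA values")
  if (max(v) <= 1 && min(v) >= 0) v <- v * 255
  if (min(v) < 0 || max(v) > 255)
    stop("`image` values must lie in [0, 255] (or [0, 1])")
  px <- pmin(as.integer(floor(v * levels / 256)), levels - 1L)
  px <- matrix(px, nrow(image), ncol(image))
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image)))
      stop("`mask` dimensions must equal `image` dimensions")
    mask <- matrix(as.logical(mask != 0), nrow(image), ncol(image))
    if (!any(mask)) stop("`mask` excludes every pixel")
  }
  structure(list(pixels = px, levels = levels, mask = mask),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("quantized_image: %d x %d pixels, %d gray levels%s\n",
              nrow(x$pixels), ncol(x$pixels), x$levels,
              if (is.null(x$mask)) "" else
                sprintf(", mask (%d px inside)", sum(x$mask))))
  invisible(x)
}

#' Read a grayscale image (PNG/TIFF) as an 8-bit matrix
#'
#' Thin wrapper over [EBImage::readImage()] that collapses color channels
#' to luminance and returns a plain `(row, col)` matrix of values in
#' \[0, 255\], row 1 at the top.
#'
#' @param path image file path.
#' @return numeric matrix of gray values in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- EBImage::channel(img, "gray")
  # EBImage stores (x, y) = (col, row); transpose to (row, col)
  t(EBImage::imageData(img)) * 255
}

#' Read a binary mask image (nonzero = inside)
#'
#' @param path image file path.
#' @return logical matrix, `TRUE` inside the region of interest.
#' @export
read_mask_image <- function(path) {
  read_gray_image(path) > 0
}

# the four canonical texture directions, as (row, col) pixel offsets at
# unit distance; row index grows downward, so 45 deg points up-right
.DIRECTIONS <- list(
  "0"   = c(0L,  1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

#' @keywords internal
direction_offset <- function(direction, distance = 1L) {
  key <- as.character(direction)
  key <- sub("^deg", "", key)
  if (!key %in% names(.DIRECTIONS))
    stop("`direction` must be one of 0, 45, 90, 135")
  .DIRECTIONS[[key]] * as.integer(distance)
}

#' The four canonical direction labels
#' @return character vector `c("0", "45", "90", "135")`.
#' @export
texture_directions <- function() names(.DIRECTIONS)
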