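#' veinviz: NIR vein-visualization image pipeline and module design tools
#'
#' Images are plain base-R matrices: `height x width`, integer-valued in
#' \[0, 255\], origin at the top-left, indexed `[row, col]` (1-based, as usual
#' in R). Binary masks use the two levels 0 (background) and 255
#' (foreground). All user-facing operations validate their inputs with
#' [as_gray_image()] / [as_binary_image()].
#'
#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' The single rounding rule used throughout the package wherever a real-valued
#' intermediate is converted back to an 8-bit gray level (base `round()` rounds
#' half to even, which would make results depend on parity).
#'
#' @param x numeric vector or matrix.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Validate and coerce a grayscale image matrix
#'
#' @param x numeric matrix with values in \[0, 255\].
#' @param arg name used in error messages.
#' @return the validated matrix, storage mode numeric, dimensions preserved.
#' @export
as_gray_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 255) {
    stop(sprintf("`%s` must contain finite values in [0, 255]", arg),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Validate a binary image (levels 0 and 255)
#'
#' @inheritParams as_gray_image
#' @return the validated matrix.
#' @export
as_binary_image <- function(x, arg = "mask") {
  x <- as_gray_image(x, arg)
  if (!all(x == 0 | x == 255)) {
    stop(sprintf("`%s` must be binary: only levels 0 and 255 allowed", arg),
         call. = FALSE)
  }
  x
}

#' Rectangular region of interest
#'
#' Half-open on neither side: the rectangle covers rows
#' `row0 .. row0 + height - 1` and the analogous columns, 0-based like pixel
#' coordinates in the rest of the imaging literature. Validation against a
#' target image happens in [extract_roi()].
#'
#' @param row0,col0 top-left corner, 0-based pixel coordinates.
#' @param height,width extent in pixels, both at least 1.
#' @return an object of class `roi_rect`.
#' @export
#' @examples
#' roi_rect(10, 20, 80, 320)
roi_rect <- function(row0, col0, height, width) {
  for (v in list(row0, col0, height, width)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v)) {
      stop("roi_rect fields must be single integer values", call. = FALSE)
    }
  }
  if (row0 < 0 || col0 < 0) stop("ROI origin must be non-negative", call. = FALSE)
  if (height < 1 || width < 1) stop("ROI height and width must be >= 1", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("ROI: origin (row %d, col %d), %d x %d px\n",
              x$row0, x$col0, x$height, x$width))
  invisible(x)
}
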