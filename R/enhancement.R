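#' Extract a rectangular region of interest
#'
#' With two-sided illumination and a band-pass filter in front of the camera,
#' everything outside the illuminated band is essentially black; processing is
#' restricted to the band by cropping it out. Pixels are copied untouched.
#'
#' @param image grayscale matrix, see [as_gray_image()].
#' @param roi an [roi_rect()]; must lie fully inside `image`.
#' @return the `roi$height x roi$width` sub-image.
#' @export
extract_roi <- function(image, roi) {
  image <- as_gray_image(image)
  if (!inherits(roi, "roi_rect")) stop("`roi` must be an roi_rect", call. = FALSE)
  if (roi$row0 + roi$height > nrow(image) || roi$col0 + roi$width > ncol(image)) {
    stop(sprintf("ROI (%d,%d)+%dx%d exceeds image bounds %dx%d",
                 roi$row0, roi$col0, roi$height, roi$width,
                 nrow(image), ncol(image)), call. = FALSE)
  }
  image[(roi$row0 + 1L):(roi$row0 + roi$height),
        (roi$col0 + 1L):(roi$col0 + roi$width), drop = FALSE]
}

#' Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel (radius
#' `ceiling(3 sigma)`), edge-replicated borders. Used before equalization to
#' suppress sensor noise, to which the downstream Hessian filter is sensitive.
#'
#' @inheritParams extract_roi
#' @param sigma kernel standard deviation in pixels; `0` returns the input
#'   unchanged.
#' @return blurred image, 8-bit (rounded half away from zero).
#' @export
gaussian_blur <- function(image, sigma) {
  image <- as_gray_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (sigma == 0) return(image)
  k <- gaussian_kernel(sigma)
  clamp255(round_half_away(conv_sep(image, k, k)))
}

#' Global histogram equalization (GHE)
#'
#' Maps gray level `v` to `round(255 * cdf(v))` where `cdf` is the empirical
#' cumulative distribution of all pixels. The mapping is monotone, so the rank
#' order of any two pixels is preserved; an image whose levels are already
#' uniformly spread is (up to rounding) a fixed point.
#'
#' @inheritParams extract_roi
#' @return equalized image.
#' @export
ghe <- function(image) {
  image <- as_gray_image(image)
  v <- as.integer(round_half_away(image))
  cdf <- cumsum(tabulate(v + 1L, nbins = 256L)) / length(v)
  map <- round_half_away(255 * cdf)
  matrix(map[v + 1L], nrow(image), ncol(image))
}

#' CLAHE parameters
#'
#' @param tile_rows,tile_cols number of tiles along each axis, at least 1.
#' @param clip_limit contrast limit as a multiple of the uniform (average)
#'   histogram bin height, the convention of Zuiderveld's original algorithm:
#'   a tile's bin is clipped at `clip_limit * n_tile / 256` counts and the
#'   clipped mass is redistributed uniformly. Values of 256 or more disable
#'   clipping entirely (plain tiled adaptive equalization).
#' @return an object of class `clahe_params`.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_limit = 2.0) {
  if (tile_rows < 1 || tile_cols < 1) stop("tile counts must be >= 1", call. = FALSE)
  if (!is.numeric(clip_limit) || clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 clip_limit = as.numeric(clip_limit)),
            class = "clahe_params")
}

# tile index/weight pair for bilinear blending along one axis: for each pixel
# position (1-based), the two bracketing tile centers and the weight of the
# lower one; positions beyond the outermost centers clamp to the nearest tile
tile_interp <- function(n, ntiles) {
  edges <- floor(seq(0, n, length.out = ntiles + 1L))
  centers <- (edges[-length(edges)] + edges[-1L] + 1) / 2   # 1-based, fractional
  pos <- seq_len(n)
  i0 <- findInterval(pos, centers)            # 0 .. ntiles
  i1 <- pmin(i0 + 1L, ntiles)
  i0 <- pmax(i0, 1L)
  w0 <- ifelse(i0 == i1, 1,
               (centers[i1] - pos) / (centers[i1] - centers[i0]))
  w0 <- pmin(pmax(w0, 0), 1)
  list(lo = i0, hi = i1, w = w0, edges = edges)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is divided into a `tile_rows x tile_cols` grid; each tile gets a
#' clipped-histogram equalization mapping (clipped mass redistributed
#' uniformly over all 256 bins), and each pixel is transformed by bilinear
#' interpolation between the mappings of the four nearest tile centers, which
#' removes block seams. Local equalization flattens slow illumination
#' gradients — such as the bright-edges/dim-center band of a two-sided light
#' module — that global equalization leaves in place.
#'
#' With a single tile and clipping disabled this reduces exactly to [ghe()].
#'
#' @inheritParams extract_roi
#' @param params a [clahe_params()] object.
#' @return equalized image.
#' @export
clahe <- function(image, params = clahe_params()) {
  image <- as_gray_image(image)
  if (!inherits(params, "clahe_params")) stop("`params` must be clahe_params", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  tr <- params$tile_rows; tc <- params$tile_cols
  if (tr > nr || tc > nc) {
    stop("tile grid finer than the image: need at least one pixel per tile",
         call. = FALSE)
  }
  v <- as.integer(round_half_away(image))
  ri <- tile_interp(nr, tr)
  ci <- tile_interp(nc, tc)

  # per-tile mappings: maps[t_row, t_col, level+1] = real-valued output level
  maps <- array(0, dim = c(tr, tc, 256L))
  vm <- matrix(v, nr, nc)
  for (i in seq_len(tr)) {
    rows <- (ri$edges[i] + 1L):ri$edges[i + 1L]
    for (j in seq_len(tc)) {
      cols <- (ci$edges[j] + 1L):ci$edges[j + 1L]
      tile <- vm[rows, cols]
      h <- tabulate(tile + 1L, nbins = 256L)
      n <- length(tile)
      lim <- params$clip_limit * n / 256
      excess <- sum(pmax(h - lim, 0))
      if (excess > 0) h <- pmin(h, lim) + excess / 256
      maps[i, j, ] <- 255 * cumsum(h) / n
    }
  }

  # bilinear blend of the four neighbouring tile mappings at each pixel
  rlo <- ri$lo; rhi <- ri$hi; rw <- ri$w
  clo <- matrix(ci$lo, nr, nc, byrow = TRUE)
  chi <- matrix(ci$hi, nr, nc, byrow = TRUE)
  cw  <- matrix(ci$w,  nr, nc, byrow = TRUE)
  rlo <- matrix(rlo, nr, nc); rhi <- matrix(rhi, nr, nc); rw <- matrix(rw, nr, nc)
  lev <- vm * (tr * tc)
  look <- function(i, j) maps[i + (j - 1L) * tr + lev]
  out <- rw * cw * look(rlo, clo) +
    rw * (1 - cw) * look(rlo, chi) +
    (1 - rw) * cw * look(rhi, clo) +
    (1 - rw) * (1 - cw) * look(rhi, chi)
  clamp255(round_half_away(matrix(out, nr, nc)))
}

#' Complex histogram equalization (CHE)
#'
#' The pixelwise average of the global and the contrast-limited adaptive
#' equalization: `0.5 * GHE + 0.5 * CLAHE`, computed in real arithmetic and
#' rounded half away from zero at the end. GHE gives strong overall contrast
#' but amplifies the non-uniform two-sided illumination; CLAHE flattens the
#' illumination but can promote spurious local structure. Their average keeps
#' faint vein branches visible while damping both failure modes.
#'
#' @inheritParams clahe
#' @return enhanced image; every pixel lies between the corresponding GHE and
#'   CLAHE values (up to the final rounding).
#' @export
che <- function(image, params = clahe_params()) {
  image <- as_gray_image(image)
  g <- ghe(image)
  l <- clahe(image, params)
  clamp255(round_half_away(0.5 * g + 0.5 * l))
}
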