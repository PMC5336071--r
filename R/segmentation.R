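#' Segmentation parameters
#'
#' @param mask_size odd side length (px) of the local window of the adaptive
#'   mean threshold. The default 63 is matched to an 80 x 320 ROI.
#' @param se_width,se_height bounding box (px) of the filled-ellipse
#'   structuring element used by the morphological closing; the default
#'   13 x 3 suits roughly horizontal vein tracks.
#' @param offset gray levels added to the local window mean before
#'   comparison (the offset constant of mean-based adaptive thresholding):
#'   only pixels exceeding the local mean by at least `offset` become
#'   foreground. 0 accepts anything at or above the bare mean, which on a
#'   noise-only flat region marks about half the pixels foreground; the
#'   pipeline default of 10 (~4% of the 8-bit range) demands a response
#'   genuinely above the local noise floor.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(mask_size = 63L, se_width = 13L, se_height = 3L,
                                offset = 10) {
  if (mask_size < 3 || mask_size %% 2 == 0) {
    stop("`mask_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (se_width < 1 || se_height < 1) {
    stop("structuring element dimensions must be >= 1", call. = FALSE)
  }
  if (!is.numeric(offset) || offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  structure(list(mask_size = as.integer(mask_size),
                 se_width = as.integer(se_width),
                 se_height = as.integer(se_height),
                 offset = as.numeric(offset)),
            class = "segmentation_params")
}

#' Adaptive mean threshold
#'
#' Each pixel is compared against the mean intensity of the
#' `mask_size x mask_size` window centered on it (edge-replicated borders):
#' below the local mean maps to 0, at or above it to 255. A local threshold
#' follows the slowly varying illumination of a two-sided light module where
#' a single global threshold cannot. The comparison uses a 1e-6 tolerance so
#' that pixels exactly at the window mean land on the "at or above" branch
#' despite floating-point accumulation.
#'
#' @inheritParams extract_roi
#' @param mask_size odd window side, >= 3.
#' @param offset gray levels added to the window mean before comparison
#'   (see [segmentation_params()]); 0 compares against the bare mean.
#' @return binary matrix with levels 0 and 255.
#' @export
adaptive_threshold <- function(image, mask_size = 63L, offset = 0) {
  image <- as_gray_image(image)
  if (!is.numeric(mask_size) || mask_size < 3 || mask_size %% 2 == 0) {
    stop("`mask_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset)) {
    stop("`offset` must be a single number", call. = FALSE)
  }
  k <- rep(1 / mask_size, mask_size)
  t_local <- conv_sep(image, k, k) + offset
  ifelse(image >= t_local - 1e-6, 255, 0) * 1
}

# offsets (dr, dc) of a filled discrete ellipse inscribed in a w x h box,
# anchored at the center pixel
ellipse_se_offsets <- function(se_width, se_height) {
  rw <- (se_width - 1) / 2
  rh <- (se_height - 1) / 2
  dr <- rep(-floor(rh):floor(rh), each = 2 * floor(rw) + 1)
  dc <- rep(-floor(rw):floor(rw), times = 2 * floor(rh) + 1)
  a2 <- max(rw, 0.5)^2   # degenerate axes keep at least the center row/col
  b2 <- max(rh, 0.5)^2
  keep <- dc^2 / a2 + dr^2 / b2 <= 1 + 1e-9
  cbind(dr = dr[keep], dc = dc[keep])
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

#' Morphological closing with a filled-ellipse structuring element
#'
#' Dilation followed by erosion, `A . B = (A + B) - B`, with a discrete
#' filled ellipse inscribed in the `se_width x se_height` bounding box. The
#' mask is conceptually embedded in an infinite background (implemented by
#' zero-padding wide enough that border effects cannot reach the frame), so
#' the textbook identities hold exactly: closing is extensive (the input
#' foreground is preserved) and idempotent. Its practical role here is to
#' fill small holes and reconnect broken vessel segments before thinning.
#'
#' @param mask binary matrix (levels 0/255).
#' @param se_width,se_height structuring element bounding box, px.
#' @return closed binary matrix.
#' @export
morph_close <- function(mask, se_width = 13L, se_height = 3L) {
  mask <- as_binary_image(mask)
  off <- ellipse_se_offsets(se_width, se_height)
  pr <- 2L * max(abs(off[, "dr"]), 1L)
  pc <- 2L * max(abs(off[, "dc"]), 1L)
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(0, nr + 2L * pr, nc + 2L * pc)
  big[(pr + 1L):(pr + nr), (pc + 1L):(pc + nc)] <- mask / 255

  dil <- matrix(0, nrow(big), ncol(big))
  for (i in seq_len(nrow(off))) {
    dil <- pmax(dil, shift_mat(big, off[i, "dr"], off[i, "dc"], fill = 0))
  }
  ero <- matrix(1, nrow(big), ncol(big))
  for (i in seq_len(nrow(off))) {
    ero <- pmin(ero, shift_mat(dil, -off[i, "dr"], -off[i, "dc"], fill = 0))
  }
  ero[(pr + 1L):(pr + nr), (pc + 1L):(pc + nc)] * 255
}

#' Zhang-Suen thinning
#'
#' Classic two-subiteration iterative thinning to a one-pixel skeleton. Per
#' subiteration a foreground pixel `p` is flagged for deletion when its
#' 8-neighborhood has between 2 and 6 foreground members (`B(p)`), exactly
#' one 0-to-1 transition around the neighbor cycle (`A(p) = 1`), and the
#' subiteration's directional neighbor products vanish (first pass:
#' `P2*P4*P6 = 0` and `P4*P6*P8 = 0`; second pass: `P2*P4*P8 = 0` and
#' `P2*P6*P8 = 0`, with P2..P9 enumerated clockwise from the north neighbor).
#' Flagged pixels are removed simultaneously; iteration stops when a full
#' pass deletes nothing. The skeleton is a subset of the input foreground and
#' preserves its connectivity.
#'
#' @param mask binary matrix (levels 0/255); pixels outside the frame count
#'   as background.
#' @return binary skeleton matrix (levels 0/255).
#' @export
zhang_suen_skeleton <- function(mask) {
  mask <- as_binary_image(mask)
  m <- mask / 255
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift_mat(m, 1, 0)    # north neighbor (value of pixel above)
      p3 <- shift_mat(m, 1, -1)   # north-east
      p4 <- shift_mat(m, 0, -1)   # east
      p5 <- shift_mat(m, -1, -1)  # south-east
      p6 <- shift_mat(m, -1, 0)   # south
      p7 <- shift_mat(m, -1, 1)   # south-west
      p8 <- shift_mat(m, 0, 1)    # west
      p9 <- shift_mat(m, 1, 1)    # north-west
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        dircond <- (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        dircond <- (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & dircond
      if (any(del)) {
        m[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m * 255
}

#' Overlay a skeleton on an enhanced image
#'
#' Saturating per-pixel addition: skeleton pixels (255) render pure white on
#' top of the CHE image, all other pixels are unchanged.
#'
#' @param che grayscale matrix, typically the output of [che()].
#' @param skeleton binary matrix of matching dimensions.
#' @return grayscale matrix.
#' @export
overlay_skeleton <- function(che, skeleton) {
  che <- as_gray_image(che, "che")
  skeleton <- as_binary_image(skeleton, "skeleton")
  if (!identical(dim(che), dim(skeleton))) {
    stop("`che` and `skeleton` dimensions differ", call. = FALSE)
  }
  clamp255(che + skeleton)
}
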