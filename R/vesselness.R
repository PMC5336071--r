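#' Multiscale vesselness filter parameters
#'
#' @param scales strictly increasing positive Gaussian scales (sigma, px) over
#'   which the per-pixel response is maximized. The response of a line of
#'   half-width `w` peaks near `sigma = w`, so the scales must bracket the
#'   vein half-widths expected in the image; the defaults bracket the
#'   nominal 4 px half-width of an 80 x 320 ROI.
#' @param beta sensitivity of the blobness term: lines give a blobness ratio
#'   near 0, blobs near 1, and `exp(-R_B^2 / (2 beta^2))` discounts the
#'   latter. 0.5 is the conventional 2D choice.
#' @param c sensitivity of the structureness term in gray-level units, or
#'   `"auto"` to use half the maximum Hessian norm observed in the image over
#'   all scales (an adaptive choice that tracks the gray-scale range of the
#'   image while leaving the cross-scale comparison intact).
#' @param gamma scale-normalization exponent of the Gaussian derivatives;
#'   1 weights all scales equally.
#' @param polarity `"dark"` enhances structures darker than their background
#'   (veins under NIR trans-illumination absorb and appear dark);
#'   `"bright"` inverts the eigenvalue sign condition.
#' @return an object of class `vesselness_params`.
#' @export
vesselness_params <- function(scales = c(2, 3, 4, 5, 6), beta = 0.5,
                              c = "auto", gamma = 1,
                              polarity = c("dark", "bright")) {
  if (length(scales) < 1L || any(scales <= 0) || is.unsorted(scales, strictly = TRUE)) {
    stop("`scales` must be non-empty, positive and strictly increasing", call. = FALSE)
  }
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!(identical(c, "auto") || (is.numeric(c) && c > 0))) {
    stop('`c` must be > 0 or "auto"', call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  structure(list(scales = as.numeric(scales), beta = as.numeric(beta),
                 c = c, gamma = as.numeric(gamma),
                 polarity = match.arg(polarity)),
            class = "vesselness_params")
}

#' Scale-normalized Hessian field at one scale
#'
#' Second-order intensity structure obtained by separable convolution with
#' analytic Gaussian-derivative kernels (truncation radius `ceiling(3 sigma)`,
#' edge-replicated borders), multiplied by `sigma^(2 gamma)` — the
#' scale-normalization factor `sigma^gamma` applied once per differentiation
#' order, which makes responses comparable across scales. `x` is the column
#' axis, `y` the row axis.
#'
#' @inheritParams extract_roi
#' @param sigma derivative scale in pixels, > 0.
#' @param gamma normalization exponent (1 = no preferred scale).
#' @return list of matrices `ixx`, `ixy`, `iyy` (class `hessian_field`).
#' @export
hessian_at_scale <- function(image, sigma, gamma = 1) {
  image <- as_gray_image(image)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  g0 <- gaussian_deriv_kernel(sigma, 0L)
  g1 <- gaussian_deriv_kernel(sigma, 1L)
  g2 <- gaussian_deriv_kernel(sigma, 2L)
  s <- sigma^(2 * gamma)
  # the differentiated direction is always the inner stage, so that a
  # 90-degree rotation maps ixx and iyy onto each other bit for bit
  structure(list(
    ixx = s * conv_rows(conv_cols(image, g2), g0),   # d2/dx2 (x = columns)
    ixy = s * 0.5 * (conv_rows(conv_cols(image, g1, anti = TRUE), g1, anti = TRUE) +
                     conv_cols(conv_rows(image, g1, anti = TRUE), g1, anti = TRUE)),
    iyy = s * conv_cols(conv_rows(image, g2), g0),   # d2/dy2 (y = rows)
    sigma = sigma
  ), class = "hessian_field")
}

#' Closed-form eigendecomposition of a 2x2 symmetric Hessian field
#'
#' Per pixel, the eigenvalues of `[[ixx, ixy], [ixy, iyy]]` ordered by
#' absolute value (`|lambda1| <= |lambda2|`) and the matching unit
#' eigenvectors. Along a vessel, `lambda1` is near zero and its eigenvector
#' points along the vessel axis; `lambda2` measures the cross-sectional
#' curvature. Eigenvector sign convention: first nonzero component positive.
#'
#' @param h a `hessian_field` from [hessian_at_scale()], or a bare list with
#'   matrices `ixx`, `ixy`, `iyy`.
#' @return list (class `eigen_field`) with matrices `lambda1`, `lambda2` and
#'   arrays `v1`, `v2` of dimension `c(nrow, ncol, 2)` holding the (x, y)
#'   components.
#' @export
eigen_decompose <- function(h) {
  a <- h$ixx; b <- h$ixy; d <- h$iyy
  tr <- a + d
  disc <- sqrt((a - d)^2 + 4 * b^2)
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  swap <- abs(e1) > abs(e2)           # ensure |lambda1| <= |lambda2|
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)

  vec_for <- function(lam) {
    vx <- b
    vy <- lam - a
    degen <- abs(vx) < 1e-300 & abs(vy) < 1e-300   # diagonal matrix case
    other_is_x <- abs(d - lam) >= abs(a - lam)     # lam belongs to the x axis
    vx <- ifelse(degen, as.numeric(other_is_x), vx)
    vy <- ifelse(degen, as.numeric(!other_is_x), vy)
    n <- sqrt(vx^2 + vy^2)
    vx <- vx / n; vy <- vy / n
    s <- ifelse(vx != 0, sign(vx), sign(vy))
    list(x = s * vx, y = s * vy)
  }
  u1 <- vec_for(ifelse(swap, e2, e1))
  u2 <- vec_for(ifelse(swap, e1, e2))
  iso <- (b == 0) & (a == d)    # scalar matrix: any basis works, pick axes
  u1$x[iso] <- 1; u1$y[iso] <- 0
  u2$x[iso] <- 0; u2$y[iso] <- 1
  dm <- dim(a)
  mk <- function(u) array(c(u$x, u$y), dim = c(dm, 2L))
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 v1 = mk(u1), v2 = mk(u2)),
            class = "eigen_field")
}

#' Blobness ratio R_B
#'
#' `R_B = lambda1 / lambda2`: near 0 on line structures (where the smaller
#' eigenvalue vanishes), near 1 on blob-like isotropic patterns. Where
#' `lambda2 = 0` there is no second-order structure at all; the ratio is
#' defined as 0 there and the vesselness score is forced to 0 separately.
#'
#' @param lambda1,lambda2 eigenvalue matrices or scalars, `|l1| <= |l2|`.
#' @return the ratio, same shape as the inputs.
#' @export
blobness_ratio <- function(lambda1, lambda2) {
  ifelse(lambda2 == 0, 0, lambda1 / lambda2)
}

#' Structureness S
#'
#' Frobenius norm of the Hessian eigenvalues, `sqrt(lambda1^2 + lambda2^2)`:
#' low in flat background, high wherever any second-order structure exists.
#'
#' @inheritParams blobness_ratio
#' @return the norm, same shape as the inputs.
#' @export
structureness <- function(lambda1, lambda2) {
  sqrt(lambda1^2 + lambda2^2)
}

#' Single-scale vesselness score
#'
#' `V0 = exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, set to 0
#' wherever the eigenvalue sign rules the structure out: for dark vessels the
#' cross-sectional curvature must be positive (`lambda2 > 0`, a dark ridge),
#' so `lambda2 < 0` scores 0; for bright vessels the condition is inverted.
#' Pixels with `lambda2 = 0` carry no orientation information and score 0.
#'
#' @param e an `eigen_field` from [eigen_decompose()].
#' @param beta,c positive sensitivity parameters (see [vesselness_params()]);
#'   `c` must be numeric here.
#' @param polarity `"dark"` or `"bright"`.
#' @return matrix of scores in \[0, 1).
#' @export
vesselness_at_scale <- function(e, beta, c, polarity = "dark") {
  if (!is.numeric(c) || c <= 0) stop("`c` must be a positive number", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive", call. = FALSE)
  l1 <- e$lambda1; l2 <- e$lambda2
  rb <- blobness_ratio(l1, l2)
  s <- structureness(l1, l2)
  v <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-s^2 / (2 * c^2)))
  bad <- if (identical(polarity, "dark")) l2 <= 0 else l2 >= 0
  # a Hessian norm at floating-point residue level (far below the 8-bit
  # quantization step) is no structure: score it zero exactly
  v[bad | s <= 1e-8] <- 0
  v
}

#' Multiscale vesselness (Frangi) filter
#'
#' Per-pixel maximum of the single-scale vesselness over `params$scales`; the
#' response peaks at the scale matching the local vessel half-width, so the
#' maximum both selects and records that scale. Deterministic; all arithmetic
#' in doubles.
#'
#' @inheritParams extract_roi
#' @param params a [vesselness_params()] object.
#' @return object of class `vesselness_map`: list with `values` (matrix in
#'   \[0, 1)), `argmax_scale` (matrix of sigma attaining the maximum, from
#'   `params$scales`) and the `params` used, with the resolved numeric `c`
#'   in `c_used`.
#' @export
frangi <- function(image, params = vesselness_params()) {
  image <- as_gray_image(image)
  if (!inherits(params, "vesselness_params")) {
    stop("`params` must be vesselness_params", call. = FALSE)
  }
  best <- matrix(0, nrow(image), ncol(image))
  arg <- matrix(params$scales[1L], nrow(image), ncol(image))
  fields <- lapply(params$scales, function(s) {
    eigen_decompose(hessian_at_scale(image, s, params$gamma))
  })
  if (identical(params$c, "auto")) {
    smax <- max(vapply(fields, function(e) {
      max(structureness(e$lambda1, e$lambda2))
    }, numeric(1)))
    # a Hessian norm at floating-point residue level means no structure at
    # all (constant or linear image); never adapt c to numerical noise
    if (smax <= 1e-8) {
      return(structure(list(values = best, argmax_scale = arg,
                            params = params, c_used = NA_real_),
                       class = "vesselness_map"))
    }
    cc <- smax / 2
  } else {
    cc <- params$c
  }
  for (i in seq_along(params$scales)) {
    v <- vesselness_at_scale(fields[[i]], params$beta, cc, params$polarity)
    better <- v > best
    best[better] <- v[better]
    arg[better] <- params$scales[i]
  }
  structure(list(values = best, argmax_scale = arg, params = params,
                 c_used = cc),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("vesselness map %d x %d, scales {%s}, max %.4f\n",
              nrow(x$values), ncol(x$values),
              paste(x$params$scales, collapse = ", "), max(x$values)))
  invisible(x)
}

#' Convert a vesselness map to an 8-bit gray image
#'
#' Max-normalization: values are scaled so the largest response maps to 255,
#' then rounded. An all-zero map stays zero. This is the representation handed
#' to the segmentation stage and written to disk.
#'
#' @param map a `vesselness_map` from [frangi()].
#' @return 8-bit grayscale matrix.
#' @export
vesselness_to_gray <- function(map) {
  if (!inherits(map, "vesselness_map")) stop("`map` must be a vesselness_map", call. = FALSE)
  m <- max(map$values)
  if (m == 0) return(matrix(0, nrow(map$values), ncol(map$values)))
  clamp255(round_half_away(map$values / m * 255))
}
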