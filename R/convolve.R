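# Separable 1D correlations with edge replication, the border rule used by
# every linear filtering stage (blur, Gaussian derivatives, windowed mean).
#
# Kernels are either even (Gaussian, box, second derivative) or odd (first
# derivative) about the center. Taps are accumulated as symmetric pairs
# k[t] * (x[+t] +/- x[-t]) from the center outward: because IEEE addition is
# commutative, a reflected or 90-degree-rotated image then yields bitwise
# identical (up to sign, for odd kernels) responses, which makes the
# vesselness filter exactly equivariant under right-angle rotations.

conv_rows <- function(m, k, anti = FALSE) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  out <- if (anti) matrix(0, nr, ncol(m)) else k[r + 1L] * m
  if (r == 0L) return(out)
  base <- seq_len(nr)
  for (t in seq_len(r)) {
    up <- m[pmin(base + t, nr), , drop = FALSE]
    dn <- m[pmax(base - t, 1L), , drop = FALSE]
    out <- out + k[r + 1L + t] * (if (anti) up - dn else up + dn)
  }
  out
}

conv_cols <- function(m, k, anti = FALSE) {
  r <- (length(k) - 1L) %/% 2L
  nc <- ncol(m)
  out <- if (anti) matrix(0, nrow(m), nc) else k[r + 1L] * m
  if (r == 0L) return(out)
  base <- seq_len(nc)
  for (t in seq_len(r)) {
    rt <- m[, pmin(base + t, nc), drop = FALSE]
    lt <- m[, pmax(base - t, 1L), drop = FALSE]
    out <- out + k[r + 1L + t] * (if (anti) rt - lt else rt + lt)
  }
  out
}

# columns first, then rows, for even kernels
conv_sep <- function(m, k_row, k_col) {
  conv_rows(conv_cols(m, k_col), k_row)
}

#' Discretized Gaussian kernel
#'
#' Samples of the 1D Gaussian `exp(-x^2 / (2 sigma^2))` at integer offsets,
#' truncated at radius `ceiling(3 * sigma)` and renormalized to sum 1.
#'
#' @param sigma standard deviation in pixels, must be positive.
#' @return numeric vector of odd length `2 * ceiling(3 * sigma) + 1`.
#' @export
#' @examples
#' k <- gaussian_kernel(1)
#' sum(k)            # 1
#' k[5] / k[4]       # ~ exp(-0.5): renormalization cancels in the ratio
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Derivative-of-Gaussian kernels. The even kernels have their (tiny)
# truncation residual removed so that a constant image maps to exactly zero.
gaussian_deriv_kernel <- function(sigma, order) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    (-x / sigma^2) * g            # odd: zero-sum by construction
  } else if (order == 2L) {
    k <- ((x^2 - sigma^2) / sigma^4) * g
    k - mean(k)
  } else {
    stop("derivative order must be 0, 1 or 2", call. = FALSE)
  }
}
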