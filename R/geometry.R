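#' NIR module penetration angle
#'
#' For a two-sided light module whose beams meet under the skin at the vein,
#' the beam angle from the skin surface satisfies `sin(theta) = D / d`, with
#' `D` the target vein depth and `d` the penetration depth of the light in
#' tissue. The clinically motivated defaults elsewhere in the package are
#' D = 1.5 cm (typical cubital-fossa vein depth) and d = 2 cm, giving
#' theta ~ 48.6 degrees.
#'
#' @param vein_depth_D vein depth below the skin surface, cm.
#' @param pen_depth_d light penetration depth, cm; must be >= `vein_depth_D`
#'   or the beams are absorbed before reaching the vein.
#' @return angle in degrees, in (0, 90\].
#' @export
#' @examples
#' design_angle(1.5, 2.0)   # 48.59 degrees
design_angle <- function(vein_depth_D, pen_depth_d) {
  check_depths(vein_depth_D, pen_depth_d)
  asin(vein_depth_D / pen_depth_d) * 180 / pi
}

#' NIR module light width
#'
#' Horizontal separation of the two diode lines so that beams entering at the
#' design angle meet at depth `D`: each beam covers a horizontal run of
#' `sqrt(d^2 - D^2)` (= `d cos(theta)`), so `W = 2 sqrt(d^2 - D^2)`. With
#' D = 1.5 cm and d = 2 cm this gives 2.65 cm.
#'
#' @inheritParams design_angle
#' @return width in cm.
#' @export
#' @examples
#' design_width(1.5, 2.0)   # 2.6458 cm
design_width <- function(vein_depth_D, pen_depth_d) {
  check_depths(vein_depth_D, pen_depth_d)
  2 * sqrt(pen_depth_d^2 - vein_depth_D^2)
}

check_depths <- function(D, d) {
  if (!is.numeric(D) || !is.numeric(d) || length(D) != 1L || length(d) != 1L ||
      is.na(D) || is.na(d) || D <= 0 || d <= 0) {
    stop("depths must be single positive numbers (cm)", call. = FALSE)
  }
  if (D > d) {
    stop("vein deeper than light penetration: need vein_depth_D <= pen_depth_d",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Complete module design from the two depths
#'
#' @inheritParams design_angle
#' @return object of class `module_design` with fields `vein_depth_D`,
#'   `pen_depth_d`, `angle_theta` (degrees) and `width_W` (cm).
#' @export
module_design <- function(vein_depth_D = 1.5, pen_depth_d = 2.0) {
  structure(list(vein_depth_D = vein_depth_D, pen_depth_d = pen_depth_d,
                 angle_theta = design_angle(vein_depth_D, pen_depth_d),
                 width_W = design_width(vein_depth_D, pen_depth_d)),
            class = "module_design")
}

#' @export
print.module_design <- function(x, ...) {
  cat(sprintf("NIR module design: vein depth D = %.2f cm, penetration depth d = %.2f cm\n",
              x$vein_depth_D, x$pen_depth_d))
  cat(sprintf("  penetration angle theta = %.1f deg\n", x$angle_theta))
  cat(sprintf("  light width W = %.2f cm\n", x$width_W))
  invisible(x)
}

#' Transmitted-intensity profile along tissue thickness
#'
#' @param depths strictly increasing thicknesses starting at 0, cm.
#' @param intensities matching non-negative detector readings; the first
#'   (zero-thickness) reading is the source-side intensity and must be
#'   positive.
#' @return data.frame of class `intensity_profile` with columns `depth`,
#'   `intensity`.
#' @export
intensity_profile <- function(depths, intensities) {
  if (length(depths) < 1L || length(depths) != length(intensities)) {
    stop("`depths` and `intensities` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (depths[1L] != 0 || is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing and start at 0", call. = FALSE)
  }
  if (any(intensities < 0) || intensities[1L] <= 0) {
    stop("intensities must be non-negative with a positive source reading",
         call. = FALSE)
  }
  structure(data.frame(depth = as.numeric(depths),
                       intensity = as.numeric(intensities)),
            class = c("intensity_profile", "data.frame"))
}

#' Penetration depth from a transmitted-intensity profile
#'
#' The penetration depth is defined operationally as the smallest tissue
#' thickness at which the transmitted intensity has fallen to `fraction` of
#' the source-side (zero-thickness) reading — 80% by default, the criterion
#' used to size the illumination module. (Note this is deliberately not the
#' 1/e attenuation length.) The crossing is located by linear interpolation
#' between the two bracketing samples; if the profile is non-monotone, the
#' first crossing counts.
#'
#' @param profile an [intensity_profile()].
#' @param fraction threshold fraction in (0, 1).
#' @return depth in cm, or `NA_real_` with a warning when the profile never
#'   drops to the threshold within the measured range.
#' @export
#' @examples
#' p <- intensity_profile(seq(0, 3, 0.5), 100 * exp(-log(1.25) / 2 * seq(0, 3, 0.5)))
#' penetration_depth(p)   # 2.0 cm
penetration_depth <- function(profile, fraction = 0.8) {
  if (!inherits(profile, "intensity_profile")) {
    profile <- intensity_profile(profile$depth, profile$intensity)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  target <- fraction * profile$intensity[1L]
  below <- which(profile$intensity <= target)
  if (length(below) == 0L) {
    warning("intensity never drops to the threshold: penetration depth beyond measured range")
    return(NA_real_)
  }
  i <- below[1L]
  if (i == 1L) return(profile$depth[1L])
  d0 <- profile$depth[i - 1L]; d1 <- profile$depth[i]
  y0 <- profile$intensity[i - 1L]; y1 <- profile$intensity[i]
  if (y1 == y0) return(d1)
  d0 + (target - y0) * (d1 - d0) / (y1 - y0)
}
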