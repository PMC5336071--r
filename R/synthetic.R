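#' Vein track for a phantom scene
#'
#' A polyline centerline with a Gaussian cross-profile: the rendered vein
#' subtracts `contrast * exp(-dist^2 / (2 half_width^2))` from the background,
#' `dist` being the distance to the centerline. A negative contrast renders a
#' bright line (used as a polarity probe).
#'
#' @param points numeric matrix with columns `row`, `col` (0-based pixel
#'   coordinates of the polyline vertices, at least 2 rows).
#' @param half_width Gaussian half-width in px, >= 1.
#' @param contrast depth of the track in gray levels.
#' @return list of class `vein_track`.
#' @export
vein_track <- function(points, half_width = 4, contrast = 40) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L) {
    stop("`points` must be an n x 2 matrix (row, col) with n >= 2", call. = FALSE)
  }
  if (abs(half_width) < 1) stop("`half_width` must be >= 1 px", call. = FALSE)
  structure(list(points = points, half_width = half_width, contrast = contrast),
            class = "vein_track")
}

#' Synthetic tissue-phantom scene description
#'
#' Emulates the images produced by a two-sided NIR illumination module over a
#' tissue-mimicking phantom: a background band that is brightest near the
#' left/right edges (where the diode lines sit) and dimmest in the center,
#' dark curvilinear vein tracks (a silicone tube filled with absorber appears
#' as a dark ridge), optional blob-shaped distractors, and additive Gaussian
#' sensor noise. Default frame 80 x 320 px matching the processing ROI, vein
#' half-width 4 px standing in for a 3 mm tube at the prototype's working
#' distance (no px/mm calibration exists; the value is a documented
#' convention).
#'
#' @param height,width frame size in px.
#' @param vein_tracks list of [vein_track()] objects; vertices must lie
#'   inside the frame.
#' @param blob_artifacts list of lists `(row, col, radius, contrast)`;
#'   rendered as radial Gaussian bumps (sigma = radius / 2) subtracted from
#'   the background.
#' @param illumination list `(edge, center)`: background gray level at the
#'   left/right edges and at mid-frame; the profile is a sum of two mirrored
#'   exponential falloffs with length scale `width / 8`.
#' @param noise_sigma standard deviation of additive Gaussian noise, gray
#'   levels.
#' @param seed integer seed making the rendering reproducible.
#' @return list of class `phantom_scene`.
#' @export
phantom_scene <- function(height = 80L, width = 320L,
                          vein_tracks = list(),
                          blob_artifacts = list(),
                          illumination = list(edge = 180, center = 110),
                          noise_sigma = 5, seed = 1L) {
  if (height < 1 || width < 1) stop("frame must be at least 1 x 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  for (tr in vein_tracks) {
    if (!inherits(tr, "vein_track")) stop("vein_tracks must be vein_track objects", call. = FALSE)
    p <- tr$points
    if (any(p[, 1] < 0 | p[, 1] > height - 1 | p[, 2] < 0 | p[, 2] > width - 1)) {
      stop("vein track vertices must lie inside the frame", call. = FALSE)
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 vein_tracks = vein_tracks, blob_artifacts = blob_artifacts,
                 illumination = illumination, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

# dense sample of a polyline at ~4 points per pixel of arc length
sample_polyline <- function(points, step = 0.25) {
  out <- NULL
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    out <- rbind(out, if (i > 1L) seg[-1L, , drop = FALSE] else seg)
  }
  out
}

# squared distance of every pixel to the sampled centerline, computed by
# local window updates around each sample (influence truncated at 4 sigma)
centerline_dist2 <- function(height, width, samples, reach) {
  d2 <- matrix(Inf, height, width)
  r <- ceiling(reach)
  for (i in seq_len(nrow(samples))) {
    pr <- samples[i, 1]; pc <- samples[i, 2]
    r0 <- max(0L, floor(pr - r)); r1 <- min(height - 1L, ceiling(pr + r))
    c0 <- max(0L, floor(pc - r)); c1 <- min(width - 1L, ceiling(pc + r))
    if (r0 > r1 || c0 > c1) next
    rows <- r0:r1; cols <- c0:c1
    dd <- outer((rows - pr)^2, (cols - pc)^2, `+`)
    sub <- d2[rows + 1L, cols + 1L, drop = FALSE]
    d2[rows + 1L, cols + 1L] <- pmin(sub, dd)
  }
  d2
}

#' Render a phantom scene
#'
#' Deterministic for a fixed scene (including its seed). Rendering order:
#' illumination background, minus vein ridges, minus blob bumps, plus
#' Gaussian noise, clamped to \[0, 255\] and rounded. The ground-truth mask
#' marks the exact (rounded) centerline pixels of every vein track.
#'
#' @param scene a [phantom_scene()].
#' @return list with `image` (grayscale matrix) and `mask` (binary matrix of
#'   centerline pixels).
#' @export
render_phantom <- function(scene) {
  if (!inherits(scene, "phantom_scene")) stop("`scene` must be a phantom_scene", call. = FALSE)
  h <- scene$height; w <- scene$width
  x <- 0:(w - 1L)
  L <- max(w / 8, 1)
  fall <- exp(-x / L) + exp(-(w - 1L - x) / L)
  fall <- fall / max(fall)
  bg_row <- scene$illumination$center +
    (scene$illumination$edge - scene$illumination$center) * fall
  img <- matrix(bg_row, h, w, byrow = TRUE)

  mask <- matrix(0, h, w)
  for (tr in scene$vein_tracks) {
    samples <- sample_polyline(tr$points)
    d2 <- centerline_dist2(h, w, samples, reach = 4 * abs(tr$half_width))
    img <- img - tr$contrast * exp(-d2 / (2 * tr$half_width^2))
    cpix <- unique(round(samples))
    keep <- cpix[, 1] >= 0 & cpix[, 1] <= h - 1 & cpix[, 2] >= 0 & cpix[, 2] <= w - 1
    mask[cbind(cpix[keep, 1] + 1L, cpix[keep, 2] + 1L)] <- 255
  }
  for (bl in scene$blob_artifacts) {
    rows <- 0:(h - 1L); cols <- 0:(w - 1L)
    d2 <- outer((rows - bl$row)^2, (cols - bl$col)^2, `+`)
    img <- img - bl$contrast * exp(-d2 / (2 * (bl$radius / 2)^2))
  }
  if (scene$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(scene$seed)
    img <- img + matrix(rnorm(h * w, sd = scene$noise_sigma), h, w)
  }
  list(image = clamp255(round_half_away(img)), mask = mask)
}

#' Light attenuation model for phantom experiments
#'
#' Phenomenological stand-in for the two bench experiments that size the
#' illumination module: transmitted intensity through increasing phantom
#' thickness follows a Beer-Lambert exponential `I(t) = i0 exp(-mu t)`, and
#' moving the source away from the phantom surface (detached mode) adds an
#' inverse-square distance factor.
#'
#' @param mu attenuation constant, 1/cm. The default `log(1.25) / 2`
#'   (~0.1116) is calibrated so that intensity falls to 80% of the source
#'   reading at exactly 2 cm, the measured behavior the module design is
#'   based on.
#' @param i0 source-side intensity, arbitrary units.
#' @param mode `"attached"` (source on the phantom) or `"detached"`.
#' @param standoff source-to-surface distance z in cm (detached mode).
#' @param z0 reference offset (source aperture scale) of the inverse-square
#'   factor `(z0 / (z0 + z))^2`, cm.
#' @return list of class `attenuation_model`.
#' @export
attenuation_model <- function(mu = log(1.25) / 2, i0 = 100,
                              mode = c("attached", "detached"),
                              standoff = 0, z0 = 1) {
  if (mu <= 0 || i0 <= 0) stop("`mu` and `i0` must be positive", call. = FALSE)
  if (standoff < 0) stop("`standoff` must be >= 0", call. = FALSE)
  if (z0 <= 0) stop("`z0` must be positive", call. = FALSE)
  structure(list(mu = mu, i0 = i0, mode = match.arg(mode),
                 standoff = standoff, z0 = z0),
            class = "attenuation_model")
}

#' Simulate the thickness-stacking experiment
#'
#' Transmitted intensity with the source attached to a phantom stack of
#' growing thickness: `I(t) = i0 exp(-mu t)`.
#'
#' @param model an [attenuation_model()] in attached mode.
#' @param thicknesses strictly increasing thicknesses starting at 0, cm.
#' @return an [intensity_profile()].
#' @export
simulate_thickness_series <- function(model, thicknesses = seq(0, 4, 0.5)) {
  if (!inherits(model, "attenuation_model")) stop("`model` must be an attenuation_model", call. = FALSE)
  if (model$mode != "attached") {
    stop("thickness series is defined for the attached mode", call. = FALSE)
  }
  intensity_profile(thicknesses, model$i0 * exp(-model$mu * thicknesses))
}

#' Simulate the source-distance experiment
#'
#' Transmitted intensity through a fixed phantom thickness while lifting the
#' source: `I(z) = i0 exp(-mu * thickness) * (z0 / (z0 + z))^2`. The
#' intensity is maximal at z = 0 — the attached mode outperforms any
#' detached standoff.
#'
#' @param model an [attenuation_model()].
#' @param distances non-negative source-to-surface distances, cm.
#' @param thickness phantom thickness, cm.
#' @return data.frame with columns `distance`, `intensity`.
#' @export
simulate_distance_series <- function(model, distances = seq(0, 20, 1),
                                     thickness = 1.5) {
  if (!inherits(model, "attenuation_model")) stop("`model` must be an attenuation_model", call. = FALSE)
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  data.frame(distance = as.numeric(distances),
             intensity = model$i0 * exp(-model$mu * thickness) *
               (model$z0 / (model$z0 + distances))^2)
}

# canonical scenes used by tests, examples and the CLI
canonical_scene <- function(name, seed = 1L) {
  straight <- vein_track(cbind(rep(40, 2), c(10, 309)), half_width = 4, contrast = 40)
  switch(name,
    straight = phantom_scene(vein_tracks = list(straight), seed = seed),
    curved = {
      cx <- seq(10, 309, length.out = 40)
      cy <- 40 + 18 * sin((cx - 10) / 299 * 2 * pi)
      phantom_scene(vein_tracks = list(vein_track(cbind(cy, cx))), seed = seed)
    },
    yjunction = {
      stem <- vein_track(cbind(rep(40, 2), c(10, 160)))
      up <- vein_track(cbind(c(40, 12), c(160, 300)))
      down <- vein_track(cbind(c(40, 68), c(160, 300)))
      phantom_scene(vein_tracks = list(stem, up, down), seed = seed)
    },
    blob = phantom_scene(
      vein_tracks = list(straight),
      blob_artifacts = list(list(row = 20, col = 80, radius = 8, contrast = 40),
                            list(row = 60, col = 240, radius = 8, contrast = 40)),
      seed = seed),
    bright = phantom_scene(
      vein_tracks = list(vein_track(cbind(rep(40, 2), c(10, 309)),
                                    half_width = 4, contrast = -40)),
      seed = seed),
    flat = phantom_scene(vein_tracks = list(),
                         illumination = list(edge = 120, center = 120),
                         noise_sigma = 0, seed = seed),
    stop(sprintf("unknown scene '%s'", name), call. = FALSE)
  )
}

#' Write the canonical synthetic fixture set
#'
#' Emits six scenes (straight vein, curved vein, Y-junction, blob-distractor,
#' bright-line polarity probe, constant frame) as 8-bit PNG images with their
#' ground-truth centerline masks, plus a plain-text manifest listing every
#' file and the scene parameters. Bit-identical across runs for a fixed seed.
#'
#' @param output_dir writable directory (created if missing).
#' @param seed integer seed for the noise of every scene.
#' @return invisibly, the manifest path.
#' @export
make_test_suite_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  names <- c("straight", "curved", "yjunction", "blob", "bright", "flat")
  manifest <- file.path(output_dir, "manifest.txt")
  lines <- c(sprintf("seed = %d", as.integer(seed)))
  for (nm in names) {
    sc <- canonical_scene(nm, seed = seed)
    rp <- render_phantom(sc)
    img_file <- sprintf("%s.png", nm)
    mask_file <- sprintf("%s_mask.png", nm)
    write_gray_image(rp$image, file.path(output_dir, img_file))
    write_gray_image(rp$mask, file.path(output_dir, mask_file))
    lines <- c(lines,
               sprintf("%s.image = %s", nm, img_file),
               sprintf("%s.mask = %s", nm, mask_file),
               sprintf("%s.size = %dx%d", nm, sc$height, sc$width),
               sprintf("%s.tracks = %d", nm, length(sc$vein_tracks)),
               sprintf("%s.noise_sigma = %g", nm, sc$noise_sigma))
  }
  writeLines(lines, manifest)
  invisible(manifest)
}
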