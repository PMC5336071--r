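#' Read an 8-bit grayscale image
#'
#' PNG or TIFF, selected by file extension. Color inputs are converted to
#' gray deterministically by the unweighted channel mean (rounded half away
#' from zero); an alpha channel, if present, is ignored.
#'
#' @param path path to an existing `.png`, `.tif` or `.tiff` file.
#' @return grayscale matrix, values in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = , tiff = tiff::readTIFF(path),
           stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
                call. = FALSE)),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (length(arr) == 0L) {
    stop(sprintf("image '%s' has zero size", path), call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    color <- arr[, , seq_len(min(nch, 3L)), drop = FALSE]   # drop alpha
    arr <- apply(color, c(1L, 2L), mean)
  }
  as_gray_image(clamp255(round_half_away(arr * 255)))
}

#' Write an 8-bit grayscale image
#'
#' Lossless single-channel PNG or TIFF (by extension); reading the file back
#' reproduces the pixels exactly.
#'
#' @param image grayscale matrix, values in \[0, 255\] (rounded to integers
#'   on write).
#' @param path destination path; the parent directory must exist.
#' @return invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write image: directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  }
  norm <- round_half_away(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(norm, target = path),
         tif = , tiff = tiff::writeTIFF(norm, where = path, bits.per.sample = 8L),
         stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
              call. = FALSE))
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the parameters of every stage of the vein-enhancement pipeline.
#'
#' @param roi optional [roi_rect()]; `NULL` processes the whole frame.
#' @param blur_sigma sigma (px) of the sensor-noise Gaussian blur applied to
#'   the raw ROI before equalization (0 disables).
#' @param presmooth_sigma sigma (px) of the second Gaussian blur, applied to
#'   the CHE output before the vesselness filter. Histogram equalization
#'   steepens the intensity mapping exactly where the histogram peaks — the
#'   flat background — so it amplifies background noise, and the Hessian
#'   filter is highly noise-sensitive. The default 4 px equals the nominal
#'   vein half-width: structures narrower than the narrowest vessel of
#'   interest are treated as noise. 0 disables.
#' @param clahe a [clahe_params()] object (used inside [che()]).
#' @param vesselness a [vesselness_params()] object.
#' @param segmentation a [segmentation_params()] object.
#' @param save_intermediates write each stage as a numbered PNG.
#' @param seed integer seed recorded for synthetic runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(roi = NULL, blur_sigma = 1.0, presmooth_sigma = 4.0,
                            clahe = clahe_params(),
                            vesselness = vesselness_params(),
                            segmentation = segmentation_params(),
                            save_intermediates = FALSE, seed = 1L) {
  if (!is.null(roi) && !inherits(roi, "roi_rect")) {
    stop("`roi` must be NULL or an roi_rect", call. = FALSE)
  }
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0", call. = FALSE)
  if (presmooth_sigma < 0) stop("`presmooth_sigma` must be >= 0", call. = FALSE)
  stopifnot(inherits(clahe, "clahe_params"),
            inherits(vesselness, "vesselness_params"),
            inherits(segmentation, "segmentation_params"))
  structure(list(roi = roi, blur_sigma = blur_sigma,
                 presmooth_sigma = presmooth_sigma, clahe = clahe,
                 vesselness = vesselness, segmentation = segmentation,
                 save_intermediates = isTRUE(save_intermediates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key/value text file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are an
#' error (this catches typos silently changing nothing). Recognized keys:
#' `roi` (`row0,col0,height,width`), `blur_sigma`, `clahe_tiles`
#' (`rows x cols`), `clahe_clip`, `frangi_scales` (comma list),
#' `frangi_beta`, `frangi_c` (number or `auto`), `frangi_gamma`,
#' `frangi_polarity` (`dark`/`bright`), `thresh_mask_size`, `close_se`
#' (`width x height`), `save_intermediates` (`true`/`false`), `seed`.
#'
#' @param path path to the config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line (expected key = value): '%s'", ln),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  known <- c("roi", "blur_sigma", "presmooth_sigma", "clahe_tiles",
             "clahe_clip", "frangi_scales", "frangi_beta", "frangi_c",
             "frangi_gamma", "frangi_polarity", "thresh_mask_size",
             "thresh_offset", "close_se", "save_intermediates", "seed")
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  num <- function(key, default) if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  pair <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    as.numeric(strsplit(kv[[key]], "[x,]")[[1L]])
  }
  roi <- NULL
  if (!is.null(kv$roi)) {
    p <- as.integer(strsplit(kv$roi, ",")[[1L]])
    if (length(p) != 4L || anyNA(p)) stop("roi must be row0,col0,height,width", call. = FALSE)
    roi <- roi_rect(p[1L], p[2L], p[3L], p[4L])
  }
  tiles <- pair("clahe_tiles", c(8, 8))
  cse <- pair("close_se", c(13, 3))
  cval <- if (is.null(kv$frangi_c) || identical(kv$frangi_c, "auto")) "auto" else as.numeric(kv$frangi_c)
  scales <- if (is.null(kv$frangi_scales)) c(1, 1.5, 2, 2.5, 3) else
    as.numeric(strsplit(kv$frangi_scales, ",")[[1L]])
  pipeline_config(
    roi = roi,
    blur_sigma = num("blur_sigma", 1.0),
    presmooth_sigma = num("presmooth_sigma", 4.0),
    clahe = clahe_params(tiles[1L], tiles[2L], num("clahe_clip", 2.0)),
    vesselness = vesselness_params(scales = scales, beta = num("frangi_beta", 0.5),
                                   c = cval, gamma = num("frangi_gamma", 1),
                                   polarity = if (is.null(kv$frangi_polarity)) "dark"
                                              else kv$frangi_polarity),
    segmentation = segmentation_params(num("thresh_mask_size", 63),
                                       cse[1L], cse[2L],
                                       offset = num("thresh_offset", 10)),
    save_intermediates = identical(tolower(kv$save_intermediates %||% "false"), "true"),
    seed = as.integer(num("seed", 1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full vein-enhancement pipeline
#'
#' Stage order: ROI crop, Gaussian blur, complex histogram equalization,
#' second Gaussian blur (the vesselness filter is noise-sensitive and
#' equalization amplifies background noise, see [pipeline_config()]),
#' multiscale vesselness filter (rescaled to 8-bit by max-normalization),
#' adaptive mean threshold with offset, morphological closing, Zhang-Suen
#' thinning, skeleton overlay on the CHE image. Every intermediate is kept in the
#' returned object; the run is deterministic for a fixed input and config,
#' and composing the exported stage functions with the same parameters
#' reproduces it exactly. A degenerate input with no line structure anywhere
#' (all-zero vesselness, e.g. a constant image) short-circuits to an empty
#' mask and skeleton with a warning.
#'
#' @param image grayscale matrix.
#' @param config a [pipeline_config()].
#' @param output_dir directory for numbered stage images when
#'   `config$save_intermediates` is on.
#' @param verbose log each stage and its parameters to the console.
#' @return object of class `vein_pipeline`: list with elements `roi`,
#'   `blurred`, `che`, `presmoothed`, `vesselness` (the `vesselness_map`),
#'   `vesselness8`, `mask`, `closed`, `skeleton`, `overlay` and `config`.
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         output_dir = NULL, verbose = FALSE) {
  image <- as_gray_image(image)
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  roi_img <- if (is.null(config$roi)) image else extract_roi(image, config$roi)
  say("stage roi: %d x %d", nrow(roi_img), ncol(roi_img))

  blurred <- gaussian_blur(roi_img, config$blur_sigma)
  say("stage blur: sigma = %g px", config$blur_sigma)

  enhanced <- che(blurred, config$clahe)
  say("stage che: tiles %d x %d, clip %g", config$clahe$tile_rows,
      config$clahe$tile_cols, config$clahe$clip_limit)

  presmoothed <- gaussian_blur(enhanced, config$presmooth_sigma)
  say("stage presmooth: sigma = %g px", config$presmooth_sigma)

  vmap <- frangi(presmoothed, config$vesselness)
  v8 <- vesselness_to_gray(vmap)
  say("stage frangi: scales {%s}, beta %g, gamma %g",
      paste(config$vesselness$scales, collapse = ", "),
      config$vesselness$beta, config$vesselness$gamma)

  if (max(vmap$values) == 0) {
    warning("no line structure detected: vesselness is zero everywhere; skeleton is empty")
    mask <- matrix(0, nrow(v8), ncol(v8))
    closed <- mask
    skel <- mask
  } else {
    mask <- adaptive_threshold(v8, config$segmentation$mask_size,
                               config$segmentation$offset)
    closed <- morph_close(mask, config$segmentation$se_width,
                          config$segmentation$se_height)
    skel <- zhang_suen_skeleton(closed)
  }
  say("stage segmentation: mask %d, closing SE %d x %d",
      config$segmentation$mask_size, config$segmentation$se_width,
      config$segmentation$se_height)

  overlay <- overlay_skeleton(enhanced, skel)
  say("stage overlay: %d skeleton px", sum(skel > 0))

  result <- structure(list(roi = roi_img, blurred = blurred, che = enhanced,
                           presmoothed = presmoothed,
                           vesselness = vmap, vesselness8 = v8, mask = mask,
                           closed = closed, skeleton = skel, overlay = overlay,
                           config = config),
                      class = "vein_pipeline")
  if (config$save_intermediates) {
    if (is.null(output_dir)) {
      stop("`output_dir` is required when save_intermediates is on", call. = FALSE)
    }
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    stages <- list("01_roi" = roi_img, "02_che" = enhanced,
                   "03_vesselness" = v8, "04_mask" = mask,
                   "05_closed" = closed, "06_skeleton" = skel,
                   "07_overlay" = overlay)
    for (nm in names(stages)) {
      write_gray_image(stages[[nm]], file.path(output_dir, paste0(nm, ".png")))
    }
  }
  result
}

#' @export
print.vein_pipeline <- function(x, ...) {
  cat(sprintf("vein pipeline result: %d x %d px\n", nrow(x$roi), ncol(x$roi)))
  cat(sprintf("  max vesselness %.4f, mask %d px, skeleton %d px\n",
              max(x$vesselness$values), sum(x$mask > 0), sum(x$skeleton > 0)))
  invisible(x)
}
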