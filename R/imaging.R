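# Projected-area measurement: segment a bright sponge body against a
# dark background and convert pixel areas to mm^2.
#
# Segmentation is threshold-plus-morphology: a global Otsu threshold on
# the intensity histogram, morphological closing, largest connected
# component, hole filling. The boundary of the resulting mask is the
# detected edge; the projected area is the mask pixel count. An optional
# gradient-based mode thresholds the Sobel gradient magnitude instead.

#' Default segmentation configuration
#'
#' @param close_radius Radius (pixels) of the disc brush used for
#'   morphological closing.
#' @param min_size Minimum component size (pixels) below which a frame is
#'   reported as containing no object.
#' @param contrast_floor Minimum intensity range (8-bit units) required
#'   to attempt thresholding; flatter frames yield "no object".
#' @param method `"threshold"` (default) or `"gradient"`.
#' @param background Optional background frame subtracted before
#'   thresholding.
#' @return Configuration list.
#' @export
segmentation_config <- function(close_radius = 3L, min_size = 20L,
                                contrast_floor = 20, method = "threshold",
                                background = NULL) {
  stopifnot(close_radius >= 0, min_size >= 1,
            method %in% c("threshold", "gradient"))
  list(close_radius = as.integer(close_radius),
       min_size = as.integer(min_size),
       contrast_floor = contrast_floor, method = method,
       background = background)
}

#' Segment one frame
#'
#' @param frame Numeric matrix of grayscale intensities (8-bit 0-255 or
#'   already scaled to 0-1), at least 16 x 16.
#' @param config A [segmentation_config()].
#' @return List of class `segmentation_result`: `mask` (logical matrix),
#'   `area_pixels`, `threshold` (on the 0-1 scale), `found` (FALSE for a
#'   "no object" frame, in which case `mask` is all-FALSE and
#'   `area_pixels` is `NA`).
#' @export
segment_frame <- function(frame, config = segmentation_config()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (nrow(frame) < 16 || ncol(frame) < 16)
    stop("frame must be at least 16 x 16 pixels")
  img <- frame
  if (!is.null(config$background)) img <- img - config$background
  scale8 <- max(img) > 1
  if (scale8) img <- img / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  floor01 <- config$contrast_floor / 255
  no_object <- function(thr) structure(
    list(mask = matrix(FALSE, nrow(frame), ncol(frame)),
         area_pixels = NA_integer_, threshold = thr, found = FALSE),
    class = "segmentation_result")
  if (diff(range(img)) < floor01) return(no_object(NA_real_))
  if (config$method == "gradient") {
    e <- EBImage::Image(img)
    # Sobel gradient magnitude; interior of the strongest edge ring is
    # recovered by the same closing + fill steps
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
    gx <- EBImage::filter2(e, kx)
    gy <- EBImage::filter2(e, t(kx))
    g <- sqrt(gx^2 + gy^2)
    g <- g / max(g)
    thr <- EBImage::otsu(EBImage::Image(as.matrix(g)))
    bin <- as.matrix(g) > thr
  } else {
    thr <- EBImage::otsu(EBImage::Image(img))
    bin <- img > thr
  }
  m <- EBImage::Image(bin * 1)
  if (config$close_radius > 0) {
    brush <- EBImage::makeBrush(2L * config$close_radius + 1L, "disc")
    m <- EBImage::closing(m, brush)
  }
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0L || max(tab) < config$min_size)
    return(no_object(thr))
  biggest <- which.max(tab)
  m <- EBImage::Image((as.matrix(lab) == biggest) * 1)
  m <- EBImage::fillHull(m)
  mask <- as.matrix(m) > 0
  structure(list(mask = mask, area_pixels = sum(mask), threshold = thr,
                 found = TRUE),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$found)
    cat(sprintf("segmentation_result: %d px at threshold %.3f\n",
                x$area_pixels, x$threshold))
  else cat("segmentation_result: no object\n")
  invisible(x)
}

#' Convert a pixel area to mm^2
#'
#' @param area_pixels Area in pixels.
#' @param pixels_per_mm Scale calibration (> 0), e.g. from a ruler placed
#'   in the frame.
#' @return Area in mm^2 (`NA` in, `NA` out).
#' @export
calibrate_area <- function(area_pixels, pixels_per_mm) {
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0)
    stop("pixels_per_mm must be a positive number")
  area_pixels / pixels_per_mm^2
}

#' Per-frame projected area of a frame stack
#'
#' @param frames List of grayscale matrices.
#' @param timestamps_s Numeric vector of timestamps (seconds), strictly
#'   increasing, one per frame.
#' @param config A [segmentation_config()].
#' @param pixels_per_mm Optional scale; when given, `area_mm2` is filled.
#' @return Data.frame (`timestamp_s`, `area_px`, `area_mm2`); "no
#'   object" frames carry `NA` areas.
#' @export
frames_to_trace <- function(frames, timestamps_s,
                            config = segmentation_config(),
                            pixels_per_mm = NULL) {
  stopifnot(is.list(frames), length(frames) == length(timestamps_s))
  if (length(frames) == 0L)
    return(data.frame(timestamp_s = numeric(0), area_px = numeric(0),
                      area_mm2 = numeric(0)))
  if (any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  px <- vapply(frames, function(f)
    as.numeric(segment_frame(f, config)$area_pixels), numeric(1))
  mm2 <- if (is.null(pixels_per_mm)) rep(NA_real_, length(px))
         else calibrate_area(px, pixels_per_mm)
  data.frame(timestamp_s = timestamps_s, area_px = px, area_mm2 = mm2)
}

#' Read a grayscale PNG frame
#'
#' @param path PNG path; RGB images are averaged to grayscale.
#' @return Numeric matrix of 8-bit intensities (0-255).
#' @export
read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  a * 255
}
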