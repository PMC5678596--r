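#' Threshold specification for VIS segmentation
#'
#' Foreground is the conjunction of three per-channel inclusive ranges in the
#' chosen colour space. Channel scales: RGB and grayscale in `[0, 255]`; hue in
#' `[0, 360)` with circular wrap (a hue range with `low > high` means
#' `[low, 360) U [0, high]`); S and V in `[0, 1]`; L in `[0, 100]`; a and b in
#' `[-128, 127]`. The `GRAY_OTSU` space takes no ranges: the threshold is
#' computed from the luminance histogram by [otsu_threshold()].
#'
#' @param space One of `"RGB"`, `"HSV"`, `"Lab"`, `"GRAY_OTSU"`.
#' @param ranges For the three-channel spaces, a 3x2 matrix (or length-6
#'   vector, row-wise low/high per channel) of inclusive bounds.
#' @return A `threshold_spec` object.
#' @examples
#' threshold_spec("HSV", c(90, 150, 0.2, 1, 0.1, 1))
#' @export
threshold_spec <- function(space = c("HSV", "RGB", "Lab", "GRAY_OTSU"),
                           ranges = NULL) {
  space <- match.arg(space)
  if (space == "GRAY_OTSU") {
    if (!is.null(ranges)) stop("GRAY_OTSU takes no ranges")
    return(structure(list(space = space, ranges = NULL), class = "threshold_spec"))
  }
  if (is.null(ranges)) stop("ranges are required for space ", space)
  if (is.vector(ranges) && length(ranges) == 6L)
    ranges <- matrix(ranges, nrow = 3, byrow = TRUE)
  stopifnot(is.matrix(ranges), dim(ranges) == c(3, 2))
  # low > high is allowed: it wraps for hue and denotes an empty range elsewhere
  dimnames(ranges) <- list(channel_names(space), c("low", "high"))
  structure(list(space = space, ranges = ranges), class = "threshold_spec")
}

channel_names <- function(space) {
  switch(space,
         RGB = c("R", "G", "B"),
         HSV = c("H", "S", "V"),
         Lab = c("L", "a", "b"))
}

#' Convert a VIS frame to another colour space
#'
#' Standard sRGB transforms: HSV via [grDevices::rgb2hsv()] (hue rescaled to
#' degrees) and CIE Lab (D65) via [grDevices::convertColor()].
#'
#' @param frame A VIS `diel_frame` or an h x w x 3 array on `[0, 255]`.
#' @param space `"RGB"`, `"HSV"` or `"Lab"`.
#' @return An h x w x 3 numeric array on the scales documented in
#'   [threshold_spec()].
#' @export
convert_space <- function(frame, space = c("RGB", "HSV", "Lab")) {
  space <- match.arg(space)
  px <- if (inherits(frame, "diel_frame")) frame$pixels else frame
  if (!is_rgb_raster(px))
    stop("colour conversion requires an RGB frame; NIR frames are single-channel")
  if (space == "RGB") return(px * 1.0)
  h <- dim(px)[1]; w <- dim(px)[2]
  flat <- matrix(px, ncol = 3)  # n x RGB
  if (space == "HSV") {
    hsv <- t(grDevices::rgb2hsv(t(flat), maxColorValue = 255))
    hsv[, 1] <- hsv[, 1] * 360
    out <- array(hsv, dim = c(h, w, 3))
  } else {
    lab <- grDevices::convertColor(flat / 255, from = "sRGB", to = "Lab")
    out <- array(lab, dim = c(h, w, 3))
  }
  out
}

#' Range-threshold a VIS frame
#'
#' A pixel is foreground iff all three channel values lie inside their
#' inclusive ranges; hue ranges wrap around 360.
#'
#' @param frame VIS frame or RGB array.
#' @param spec A [threshold_spec()] with `space != "GRAY_OTSU"`.
#' @return Logical foreground mask, same dimensions as the frame.
#' @export
threshold_ranges <- function(frame, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$space == "GRAY_OTSU")
    stop("use otsu_threshold() for GRAY_OTSU specs")
  ch <- convert_space(frame, spec$space)
  keep <- matrix(TRUE, dim(ch)[1], dim(ch)[2])
  for (i in 1:3) {
    lo <- spec$ranges[i, 1]; hi <- spec$ranges[i, 2]
    v <- ch[, , i]
    inside <- if (spec$space == "HSV" && i == 1L && lo > hi) {
      v >= lo | v <= hi  # circular hue interval
    } else {
      v >= lo & v <= hi
    }
    keep <- keep & inside
  }
  keep
}

#' Otsu threshold of an 8-bit single-channel raster
#'
#' Maximises the between-class variance of the 256-bin histogram; foreground
#' is the set of pixels strictly greater than the threshold. Ties are broken
#' by the smallest maximising threshold.
#'
#' @param gray Integer-valued matrix on `[0, 255]`.
#' @return List with `threshold` (integer in 0..254) and `mask` (logical).
#' @export
otsu_threshold <- function(gray) {
  stopifnot(is_gray_raster(gray))
  g <- as.integer(round(gray))
  h <- tabulate(g + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) stop("degenerate histogram: constant image has no valid split")
  lev <- 0:255
  w0 <- cumsum(h)
  s0 <- cumsum(h * lev)
  tot <- w0[256]; stot <- s0[256]
  t_cand <- 1:255  # threshold value t = lev[t_cand] = t_cand - 1, split <=t vs >t
  w0c <- w0[t_cand]; s0c <- s0[t_cand]
  w1c <- tot - w0c
  valid <- w0c > 0 & w1c > 0
  mu0 <- s0c / w0c
  mu1 <- (stot - s0c) / w1c
  sb <- w0c * w1c * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  thr <- which.max(sb) - 1L  # smallest maximiser
  list(threshold = thr, mask = matrix(g > thr, nrow(gray), ncol(gray)))
}

#' Remove speckle and fill holes in a binary mask
#'
#' Connected components (8-connectivity) smaller than `min_area_px` are
#' removed; holes are filled when `fill_holes` is set. With `fill_holes =
#' FALSE` the output is a subset of the input.
#'
#' @param mask Logical matrix.
#' @param min_area_px Minimum component area kept, in pixels.
#' @param fill_holes Fill enclosed background regions?
#' @return Cleaned logical mask.
#' @export
clean_mask <- function(mask, min_area_px = 25, fill_holes = TRUE) {
  stopifnot(min_area_px >= 0)
  out <- mask
  if (min_area_px > 0 && any(out)) {
    lab <- label_components8(out)
    area <- tabulate(lab[lab > 0L])
    drop <- which(area < min_area_px)
    if (length(drop)) out[lab %in% drop] <- FALSE
  }
  if (fill_holes && any(out)) out <- fill_mask_holes(out)
  out
}

#' Per-channel histograms to guide threshold tuning
#'
#' Summarises the channel distributions of a VIS frame in a colour space, as a
#' tibble usable for plotting or for printing quantiles — a batch-friendly
#' stand-in for interactive range tuning.
#'
#' @param frame VIS frame or RGB array.
#' @param space Colour space to inspect.
#' @param bins Number of histogram bins per channel.
#' @return Tibble with `channel`, `mid` (bin midpoint) and `count`.
#' @export
channel_histograms <- function(frame, space = c("HSV", "RGB", "Lab"), bins = 64) {
  space <- match.arg(space)
  ch <- convert_space(frame, space)
  nm <- channel_names(space)
  purrr::map_dfr(1:3, function(i) {
    v <- as.vector(ch[, , i])
    hst <- graphics::hist(v, breaks = bins, plot = FALSE)
    tibble::tibble(channel = nm[i], mid = hst$mids, count = hst$counts)
  })
}
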