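#' Photon-count image with physical pixel size
#'
#' The common currency of all image operations in ermorph. A `pixel_image`
#' wraps a numeric matrix of non-negative intensities (photon counts or
#' arbitrary units) together with the lateral pixel edge length in
#' nanometres. Pixel coordinates are R's 1-based `(row, col)` matrix
#' indices; the physical position of the center of pixel `(i, j)` is
#' `((j - 0.5) * pixel_size_nm, (i - 0.5) * pixel_size_nm)` in `(x, y)`,
#' i.e. the image's physical origin is the outer corner of pixel `(1, 1)`.
#'
#' @param values numeric matrix, finite and >= 0.
#' @param pixel_size_nm lateral pixel edge length in nm (> 0). STED data in
#'   this package conventionally uses 18.9 nm.
#' @return an object of class `pixel_image`.
#' @export
pixel_image <- function(values, pixel_size_nm) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("'values' must be finite")
  if (any(values < 0))
    stop("'values' must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a single positive number")
  structure(
    list(values = values, pixel_size_nm = as.numeric(pixel_size_nm)),
    class = "pixel_image"
  )
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d px, %.4g nm/px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_nm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.pixel_image <- function(x) dim(x$values)

as_pixel_image <- function(x, pixel_size_nm) {
  if (inherits(x, "pixel_image")) return(x)
  pixel_image(x, pixel_size_nm)
}

#' Ordered stack of same-shape images (time-lapse video)
#'
#' @param frames list of [pixel_image] objects with identical dimensions and
#'   pixel size.
#' @param frame_interval_s time between consecutive frames in seconds;
#'   required (> 0) when there is more than one frame.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s = NA_real_) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of pixel_image objects")
  if (!all(vapply(frames, inherits, logical(1), "pixel_image")))
    stop("all frames must be pixel_image objects")
  d <- dim(frames[[1L]])
  ps <- frames[[1L]]$pixel_size_nm
  for (f in frames) {
    if (!identical(dim(f), d))
      stop("all frames must have identical dimensions")
    if (f$pixel_size_nm != ps)
      stop("all frames must share one pixel size")
  }
  if (length(frames) > 1L) {
    if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
      stop("'frame_interval_s' must be > 0 for multi-frame stacks")
  }
  structure(
    list(frames = frames, frame_interval_s = as.numeric(frame_interval_s)),
    class = "image_stack"
  )
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.4g nm/px, dt = %g s\n",
              length(x$frames), d[1L], d[2L],
              x$frames[[1L]]$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Read a grayscale TIFF as a pixel_image or image_stack
#'
#' Single-page files return a [pixel_image]; multi-page files return an
#' [image_stack]. Integer sample data are preserved exactly. RGB or other
#' multi-channel data are rejected: single-channel grayscale is required.
#'
#' If the TIFF carries pixel-resolution metadata in a physical unit, it is
#' checked against `pixel_size_nm` and a mismatch beyond 1% is an error;
#' absent metadata, the supplied value is used as-is.
#'
#' @param path path to a readable single-channel grayscale TIFF (8/16/32-bit).
#' @param pixel_size_nm lateral pixel size in nm.
#' @param frame_interval_s frame interval in seconds for multi-page files.
#' @return [pixel_image] or [image_stack].
#' @export
read_image <- function(path, pixel_size_nm, frame_interval_s = NA_real_) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  check_tiff_pixel_size(pages[[1L]], pixel_size_nm, path)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) p <- p[, , 1L]
      else stop("single-channel grayscale required: ", path,
                " has ", dim(p)[3L], " channels")
    }
    pixel_image(matrix(as.numeric(p), nrow(p), ncol(p)), pixel_size_nm)
  })
  if (length(frames) == 1L) frames[[1L]]
  else image_stack(frames, frame_interval_s)
}

# TIFF resolution tags are pixels per unit; compare nm/px when the unit is
# physical (inch or cm). Unknown/absent units are ignored.
check_tiff_pixel_size <- function(page, pixel_size_nm, path) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(invisible())
  nm_per_unit <- switch(as.character(unit %||% ""),
                        inch = 2.54e7, cm = 1e7, NULL)
  if (is.null(nm_per_unit)) return(invisible())
  meta_nm <- nm_per_unit / xres
  if (abs(meta_nm - pixel_size_nm) / pixel_size_nm > 0.01)
    stop(sprintf(
      "TIFF metadata pixel size (%.4g nm) disagrees with supplied %.4g nm (> 1%%): %s",
      meta_nm, pixel_size_nm, path))
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pixel_image or image_stack to TIFF
#'
#' Integer-valued images with maximum below 65536 are written as 16-bit
#' (lossless round trip through [read_image]); other images are written as
#' 32-bit float scaled into `[0, 1]` by `scale_max`.
#'
#' @param image [pixel_image] or [image_stack].
#' @param path output path.
#' @param scale_max divisor used for non-integer data (default: image max).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, scale_max = NULL) {
  frames <- if (inherits(image, "image_stack")) image$frames else list(image)
  mats <- lapply(frames, function(f) f$values)
  mx <- max(vapply(mats, max, numeric(1)), 1)
  integerish <- all(vapply(mats, function(m) all(m == round(m)), logical(1)))
  if (integerish && mx <= 65535) {
    what <- lapply(mats, function(m) m / 65535)
    tiff::writeTIFF(what, path, bits.per.sample = 16L)
  } else {
    sm <- scale_max %||% mx
    what <- lapply(mats, function(m) pmin(m / sm, 1))
    tiff::writeTIFF(what, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Gaussian smoothing with mirror boundary handling
#'
#' Separable Gaussian filter with kernel truncated at 4 sigma and
#' renormalized. Boundaries are handled by mirror reflection (edge pixel
#' duplicated), which avoids the dark-edge artifacts that would otherwise
#' create spurious local minima at image borders. `sigma_px = 0` is the
#' identity.
#'
#' @param image [pixel_image].
#' @param sigma_px Gaussian sigma in pixels (>= 0). The hole-analysis chain
#'   uses sigma = 1 px.
#' @return smoothed [pixel_image] (pixel size preserved).
#' @export
gaussian_smooth <- function(image, sigma_px) {
  stopifnot(inherits(image, "pixel_image"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || !is.finite(sigma_px))
    stop("'sigma_px' must be a single finite number")
  if (sigma_px < 0) stop("'sigma_px' must be >= 0")
  if (sigma_px == 0) return(image)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  v <- sep_filter_mirror(image$values, k)
  pixel_image(pmax(v, 0), image$pixel_size_nm)
}

# Separable correlation with a symmetric 1D kernel, mirror (edge-duplicated)
# padding on both axes.
sep_filter_mirror <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  tmp <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(k))
    tmp <- tmp + k[s] * mp[s:(s + nrow(m) - 1L), , drop = FALSE]
  tp <- tmp[, pad_idx(ncol(m)), drop = FALSE]
  for (s in seq_along(k))
    out <- out + k[s] * tp[, s:(s + ncol(m) - 1L), drop = FALSE]
  out
}

#' Bleach correction by histogram matching
#'
#' Maps every frame's intensity histogram onto the histogram of a reference
#' frame by monotone empirical quantile matching with linear interpolation
#' between quantiles. The reference frame is returned unchanged. Applying
#' the correction twice with the same reference changes nothing beyond the
#' discrete quantization of the matching.
#'
#' @param stack [image_stack] with at least 2 frames (a single frame is
#'   returned unchanged with a warning).
#' @param reference_frame_index 1-based index of the reference frame
#'   (default 1).
#' @return corrected [image_stack].
#' @export
bleach_correct <- function(stack, reference_frame_index = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- length(stack$frames)
  if (reference_frame_index < 1L || reference_frame_index > nf)
    stop("'reference_frame_index' out of range")
  if (nf < 2L) {
    warning("single-frame stack: bleach correction is the identity")
    return(stack)
  }
  ref <- stack$frames[[reference_frame_index]]
  ref_sorted <- sort(as.vector(ref$values))
  n <- length(ref_sorted)
  probs <- (seq_len(n) - 0.5) / n
  frames <- lapply(seq_len(nf), function(i) {
    if (i == reference_frame_index) return(ref)
    v <- stack$frames[[i]]$values
    p <- (rank(as.vector(v), ties.method = "average") - 0.5) / length(v)
    matched <- stats::approx(probs, ref_sorted, xout = p, rule = 2)$y
    pixel_image(matrix(pmax(matched, 0), nrow(v), ncol(v)), ref$pixel_size_nm)
  })
  image_stack(frames, stack$frame_interval_s)
}
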