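#' Binary ER footprint mask
#'
#' Max-normalizes the image, median-filters it with a square kernel
#' (default 15 x 15 px, mirror boundary), and thresholds at a fraction of
#' the maximum (default 5%). The result marks the footprint of ER signal on
#' which hole candidates are considered.
#'
#' @param image [pixel_image] (raw or smoothed); must have a positive
#'   maximum.
#' @param median_kernel_px odd kernel edge length in pixels (default 15).
#' @param threshold_fraction threshold as a fraction of the normalized
#'   maximum (default 0.05).
#' @return logical matrix of the image's dimensions (class `er_mask`).
#' @export
er_mask <- function(image, median_kernel_px = 15L, threshold_fraction = 0.05) {
  stopifnot(inherits(image, "pixel_image"))
  mx <- max(image$values)
  if (mx <= 0) stop("no signal: image maximum is not positive")
  r <- as.integer(median_kernel_px) %/% 2L
  norm <- image$values / mx
  pad_idx <- function(n) c(pmin(r:1, n), 1:n, pmax(n - seq_len(r) + 1L, 1L))
  padded <- norm[pad_idx(nrow(norm)), pad_idx(ncol(norm)), drop = FALSE]
  med <- EBImage::medianFilter(padded, size = r)
  med <- med[r + seq_len(nrow(norm)), r + seq_len(ncol(norm)), drop = FALSE]
  m <- med >= threshold_fraction
  class(m) <- c("er_mask", class(m))
  m
}

# Minimum over the in-bounds 8-neighborhood of each pixel (Inf outside).
neighbor_min8 <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  p <- matrix(Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- v
  out <- matrix(Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- pmin(out, p[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
  }
  out
}

#' Find local intensity minima to seed the watershed
#'
#' Regional minima of the smoothed image inside the mask, with a minimum
#' mutual separation. A connected equal-valued plateau that is a regional
#' minimum contributes a single seed at its centroid (rounded to the
#' nearest pixel). When two minima fall closer than `min_separation_px`
#' (Euclidean, pixel units), the deeper (lower-valued) one is kept. The
#' returned seeds are ordered row-major.
#'
#' @param smoothed [pixel_image], conventionally the sigma = 1 px
#'   Gaussian-smoothed image.
#' @param min_separation_px minimum Euclidean seed separation (default 4).
#' @param mask logical matrix from [er_mask] (same shape).
#' @return data.frame with 1-based `row`, `col`, the minimum `value`, and
#'   `source = "auto_minimum"`.
#' @export
find_local_minima <- function(smoothed, min_separation_px = 4, mask = NULL) {
  stopifnot(inherits(smoothed, "pixel_image"))
  v <- smoothed$values
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  if (!all(dim(mask) == dim(v))) stop("mask shape must match image")
  empty <- data.frame(row = integer(), col = integer(),
                      value = numeric(), source = character())
  if (!any(mask)) return(empty)
  nmin <- neighbor_min8(v)
  cand <- (v <= nmin) & mask
  if (!any(cand)) return(empty)

  nr <- nrow(v); nc <- ncol(v)
  # strict minima need no plateau handling; equal-valued plateaus (rare on
  # continuous-valued smoothed data) are flooded and contribute their
  # centroid when the whole plateau is a regional minimum
  strict <- cand & (v < nmin)
  sidx <- which(strict, arr.ind = TRUE)
  seeds <- cbind(sidx[, 1L], sidx[, 2L], v[strict])
  plateau <- cand & !strict
  if (any(plateau)) {
    seen <- matrix(FALSE, nr, nc)
    pidx <- which(plateau, arr.ind = TRUE)
    pidx <- pidx[order(pidx[, 1L], pidx[, 2L]), , drop = FALSE]
    extra <- list()
    for (s in seq_len(nrow(pidx))) {
      i0 <- pidx[s, 1L]; j0 <- pidx[s, 2L]
      if (seen[i0, j0]) next
      val <- v[i0, j0]
      comp <- matrix(c(i0, j0), 1L)
      seen[i0, j0] <- TRUE
      queue <- list(c(i0, j0))
      ok <- TRUE
      while (length(queue)) {
        pt <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          ii <- pt[1L] + di; jj <- pt[2L] + dj
          if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
          if (v[ii, jj] == val) {
            if (!cand[ii, jj]) ok <- FALSE  # plateau leaks to a non-minimum
            else if (!seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              comp <- rbind(comp, c(ii, jj))
              queue[[length(queue) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
      if (ok)
        extra[[length(extra) + 1L]] <-
          c(round(mean(comp[, 1L])), round(mean(comp[, 2L])), val)
    }
    if (length(extra)) seeds <- rbind(seeds, do.call(rbind, extra))
  }
  if (!nrow(seeds)) return(empty)
  m <- seeds
  # keep-deeper rule: accept in order of increasing value (row-major
  # ties); a spatial bucket grid keeps the separation check local
  ord <- order(m[, 3L], m[, 1L], m[, 2L])
  cell <- max(1L, ceiling(min_separation_px))
  nci <- nr %/% cell + 2L; ncj <- nc %/% cell + 2L
  bucket <- vector("list", nci * ncj)
  keep <- logical(nrow(m))
  for (s in ord) {
    bi <- m[s, 1L] %/% cell + 1L; bj <- m[s, 2L] %/% cell + 1L
    ok <- TRUE
    for (di in -1:1) {
      for (dj in -1:1) {
        if (bi + di < 1L || bi + di > nci || bj + dj < 1L || bj + dj > ncj)
          next
        nb <- bucket[[(bi + di) + nci * (bj + dj - 1L)]]
        if (is.null(nb)) next
        d2 <- (m[nb, 1L] - m[s, 1L])^2 + (m[nb, 2L] - m[s, 2L])^2
        if (any(d2 < min_separation_px^2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      keep[s] <- TRUE
      key <- bi + nci * (bj - 1L)
      bucket[[key]] <- c(bucket[[key]], s)
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  data.frame(row = as.integer(m[, 1L]), col = as.integer(m[, 2L]),
             value = m[, 3L], source = "auto_minimum")
}

#' Marker-controlled watershed segmentation
#'
#' Floods the smoothed intensity landscape from the seed points by
#' ascending intensity with 8-connectivity, restricted to the mask. Every
#' reachable masked pixel is assigned to exactly one seed's catchment
#' basin; unmasked pixels stay unlabeled (0). Label ids are the row indices
#' of `seeds` (row-major when seeds come from [find_local_minima]), and
#' equal-intensity ties are resolved deterministically in favor of the
#' earlier seed.
#'
#' @param smoothed [pixel_image].
#' @param seeds data.frame with 1-based `row`, `col` (e.g. from
#'   [find_local_minima]); seeds outside the mask are dropped with a
#'   warning.
#' @param mask logical matrix; default all-true.
#' @return object of class `watershed_labels`: list with `labels` (integer
#'   matrix), `seeds`, `mask`.
#' @export
watershed_segment <- function(smoothed, seeds, mask = NULL) {
  stopifnot(inherits(smoothed, "pixel_image"))
  v <- smoothed$values
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  if (nrow(seeds) < 1L) stop("at least one seed is required")
  inside <- mask[cbind(seeds$row, seeds$col)]
  if (!all(inside)) {
    warning(sum(!inside), " seed(s) outside the mask dropped")
    seeds <- seeds[inside, , drop = FALSE]
  }
  if (nrow(seeds) < 1L) stop("no seeds inside the mask")
  seed_m <- matrix(0L, nrow(v), ncol(v))
  seed_m[cbind(seeds$row, seeds$col)] <- seq_len(nrow(seeds))
  lab <- .ws_flood(v, seed_m, matrix(as.logical(mask), nrow(v), ncol(v)))
  structure(list(labels = lab, seeds = seeds, mask = mask),
            class = "watershed_labels")
}

#' @export
print.watershed_labels <- function(x, ...) {
  cat(sprintf("<watershed_labels> %d regions over %d masked px\n",
              nrow(x$seeds), sum(x$mask)))
  invisible(x)
}

# region membership -> edge pixels: region pixels 8-adjacent to a pixel
# outside the region (the image border counts as outside).
region_edge <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- member
  all_in <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    all_in <- all_in & p[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  member & !all_in
}

#' Delimit the hole inside one watershed region
#'
#' The hole depth is the mean smoothed intensity over the region's edge
#' pixels (its inner boundary) minus the minimum smoothed intensity in the
#' region. Pixels strictly below `min + depth_fraction * depth` form the
#' hole; the raw-image values at those pixels are carried along for
#' downstream quantification. A region with non-positive depth is flagged
#' unmeasurable.
#'
#' @param ws [watershed_segment] result.
#' @param label_id region id to delimit.
#' @param smoothed [pixel_image] used for the depth rule.
#' @param raw optional [pixel_image] with raw counts (defaults to
#'   `smoothed`).
#' @param depth_fraction border level as a fraction of hole depth
#'   (default 0.4).
#' @param edge `"inner"` (default) measures the region's own boundary
#'   pixels; `"outer"` the exterior ring of non-region pixels 8-adjacent to
#'   the region.
#' @return object of class `hole_region`.
#' @export
delimit_hole <- function(ws, label_id, smoothed, raw = NULL,
                         depth_fraction = 0.4,
                         edge = c("inner", "outer")) {
  stopifnot(inherits(ws, "watershed_labels"), inherits(smoothed, "pixel_image"))
  edge <- match.arg(edge)
  if (is.null(raw)) raw <- smoothed
  v <- smoothed$values
  member <- ws$labels == label_id
  if (!any(member)) stop("region ", label_id, " is empty")
  if (edge == "inner") {
    edge_m <- region_edge(member)
  } else {
    edge_m <- region_edge(!member) & !member
  }
  pix <- which(member, arr.ind = TRUE)
  min_value <- min(v[member])
  edge_mean <- mean(v[edge_m])
  depth <- edge_mean - min_value
  measurable <- depth > 0
  border_threshold <- min_value + depth_fraction * depth
  hole_m <- member & (v < border_threshold)
  if (!measurable) hole_m[] <- FALSE
  hole_pix <- which(hole_m, arr.ind = TRUE)
  structure(list(
    label_id = label_id,
    pixels = unname(pix),
    edge_pixels = unname(which(edge_m, arr.ind = TRUE)),
    min_value = min_value,
    edge_mean = edge_mean,
    depth = depth,
    border_threshold = border_threshold,
    hole_pixels = unname(hole_pix),
    hole_values_raw = raw$values[hole_m],
    pixel_size_nm = smoothed$pixel_size_nm,
    measurable = measurable,
    touches_border = any(pix[, 1L] %in% c(1L, nrow(v))) ||
      any(pix[, 2L] %in% c(1L, ncol(v)))
  ), class = "hole_region")
}

#' @export
print.hole_region <- function(x, ...) {
  cat(sprintf(
    "<hole_region> id %d: %d region px, %d hole px, depth %.3g%s\n",
    x$label_id, nrow(x$pixels), nrow(x$hole_pixels), x$depth,
    if (x$measurable) "" else " (unmeasurable)"))
  invisible(x)
}

#' Select user-identified holes and apply rejection rules
#'
#' Keeps only watershed regions that contain a user-supplied point, then
#' applies the automatic rejection rules (region touches the image border;
#' fewer hole pixels than `min_hole_px`; non-positive depth) and an
#' optional manual-rejection list. User points that fall outside every
#' labeled region are reported and skipped.
#'
#' @param ws [watershed_segment] result.
#' @param smoothed,raw images passed to [delimit_hole].
#' @param user_points data.frame with 1-based `row`, `col` (e.g. read with
#'   [read_seed_csv]).
#' @param min_hole_px minimum number of hole pixels (default 3).
#' @param depth_fraction see [delimit_hole].
#' @param manual_reject integer vector of region ids to reject manually.
#' @return list of [delimit_hole] results, each with `accepted` (logical)
#'   and `reason` (`NA` when accepted); skipped user points are attached as
#'   the `skipped_points` attribute.
#' @export
select_and_reject <- function(ws, smoothed, user_points, raw = NULL,
                              min_hole_px = 3L, depth_fraction = 0.4,
                              manual_reject = integer()) {
  stopifnot(inherits(ws, "watershed_labels"))
  ids <- ws$labels[cbind(user_points$row, user_points$col)]
  skipped <- user_points[ids == 0L, , drop = FALSE]
  if (nrow(skipped))
    warning(nrow(skipped), " user point(s) outside any region skipped")
  ids <- sort(unique(ids[ids > 0L]))
  holes <- lapply(ids, function(k) {
    h <- delimit_hole(ws, k, smoothed, raw = raw,
                      depth_fraction = depth_fraction)
    reason <- NA_character_
    if (k %in% manual_reject) reason <- "manual"
    else if (h$touches_border) reason <- "border"
    else if (!h$measurable) reason <- "flat"
    else if (nrow(h$hole_pixels) < min_hole_px) reason <- "too_small"
    h$accepted <- is.na(reason)
    h$reason <- reason
    h
  })
  attr(holes, "skipped_points") <- skipped
  holes
}

#' Full semiautomated hole-measurement chain on one image
#'
#' Convenience wrapper running the analysis chain: sigma = 1 px Gaussian
#' smoothing, ER footprint mask, local-minimum seeding, marker-controlled
#' watershed, user-point selection with rejection rules, and per-hole shape
#' statistics on the depth-fraction hole pixels.
#'
#' @param image raw [pixel_image].
#' @param user_points data.frame of approximate hole centers (`row`,
#'   `col`, 1-based).
#' @param sigma_px smoothing sigma (default 1).
#' @param min_separation_px seed separation (default 4).
#' @param median_kernel_px,threshold_fraction see [er_mask].
#' @param depth_fraction,min_hole_px,manual_reject see [select_and_reject].
#' @return data.frame from [hole_table] (one row per selected region,
#'   accepted or not), with the hole list as attribute `holes`.
#' @export
segment_holes <- function(image, user_points, sigma_px = 1,
                          min_separation_px = 4, median_kernel_px = 15L,
                          threshold_fraction = 0.05, depth_fraction = 0.4,
                          min_hole_px = 3L, manual_reject = integer()) {
  sm <- gaussian_smooth(image, sigma_px)
  mask <- er_mask(image, median_kernel_px, threshold_fraction)
  seeds <- find_local_minima(sm, min_separation_px, mask)
  ws <- watershed_segment(sm, seeds, mask)
  holes <- select_and_reject(ws, sm, user_points, raw = image,
                             min_hole_px = min_hole_px,
                             depth_fraction = depth_fraction,
                             manual_reject = manual_reject)
  tab <- hole_table(holes, image$pixel_size_nm)
  attr(tab, "holes") <- holes
  attr(tab, "watershed") <- ws
  tab
}

#' Read / write seed or user-point CSV (frame, row, col; 1-based)
#' @param path CSV path.
#' @return data.frame with columns `frame`, `row`, `col`.
#' @export
read_seed_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("seed CSV must have columns row, col (and optionally frame)")
  if (is.null(df$frame)) df$frame <- 1L
  df[c("frame", "row", "col")]
}

#' @rdname read_seed_csv
#' @param points data.frame with `row`, `col` and optionally `frame`.
#' @export
write_seed_csv <- function(points, path) {
  if (is.null(points$frame)) points$frame <- 1L
  utils::write.csv(points[c("frame", "row", "col")], path, row.names = FALSE)
  invisible(path)
}

#' Export a watershed label map as 16-bit TIFF
#' @param ws [watershed_segment] result.
#' @param path output path.
#' @export
write_label_tiff <- function(ws, path) {
  tiff::writeTIFF(ws$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
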