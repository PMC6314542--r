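#' Prepare a video stack for hole tracking
#'
#' Applies the analysis chain preprocessing: bleach correction by
#' histogram matching against a reference frame, then per-frame Gaussian
#' smoothing (sigma = 1 px by default).
#'
#' @param stack raw [image_stack].
#' @param reference_frame_index reference for [bleach_correct].
#' @param sigma_px smoothing sigma (default 1).
#' @return preprocessed [image_stack].
#' @export
prepare_stack <- function(stack, reference_frame_index = 1L, sigma_px = 1) {
  if (length(stack$frames) > 1L)
    stack <- bleach_correct(stack, reference_frame_index)
  image_stack(lapply(stack$frames, gaussian_smooth, sigma_px = sigma_px),
              stack$frame_interval_s)
}

# deepest qualifying local minimum within a search disk of the smoothed
# frame; returns c(row, col, value, depth) or NULL. Depth is the mean of
# the ring at the disk's edge minus the minimum value.
local_minimum_near <- function(v, center, radius_px) {
  nr <- nrow(v); nc <- ncol(v)
  ii <- max(1L, center[1L] - radius_px):min(nr, center[1L] + radius_px)
  jj <- max(1L, center[2L] - radius_px):min(nc, center[2L] + radius_px)
  d2 <- outer((ii - center[1L])^2, (jj - center[2L])^2, `+`)
  disk <- d2 <= radius_px^2
  block <- v[ii, jj, drop = FALSE]
  nm <- neighbor_min8(v)[ii, jj, drop = FALSE]
  cand <- disk & (block <= nm)
  if (!any(cand)) return(NULL)
  ring <- d2 > radius_px^2 & d2 <= (radius_px + 2)^2
  ring_ii <- max(1L, center[1L] - radius_px - 2L):min(nr, center[1L] + radius_px + 2L)
  ring_jj <- max(1L, center[2L] - radius_px - 2L):min(nc, center[2L] + radius_px + 2L)
  rd2 <- outer((ring_ii - center[1L])^2, (ring_jj - center[2L])^2, `+`)
  ring_m <- rd2 > radius_px^2 & rd2 <= (radius_px + 2L)^2
  surround <- mean(v[ring_ii, ring_jj][ring_m])
  k <- which(cand, arr.ind = TRUE)
  vals <- block[cand]
  best <- order(vals, k[, 1L], k[, 2L])[1L]
  c(row = ii[k[best, 1L]], col = jj[k[best, 2L]], value = vals[best],
    depth = surround - vals[best])
}

#' Track one seeded nanohole through a video
#'
#' Frame by frame, the hole position snaps to the deepest local minimum of
#' the smoothed frame within `search_radius_px` of the previous position
#' (local-minimum center correction). A frame with no qualifying minimum
#' (depth below `depth_min_frac` of the start-frame contrast) marks the
#' hole absent; tracking resumes if a qualifying minimum reappears within
#' `gap_frames` frames of the last presence, else the track ends.
#'
#' @param stack preprocessed [image_stack] (see [prepare_stack]).
#' @param seed list or data.frame row with `row`, `col` (1-based) and
#'   optionally `frame` (start frame, default 1).
#' @param search_radius_px snap radius in pixels (default 5).
#' @param depth_min_frac presence threshold as a fraction of the
#'   start-frame local contrast (default 0.2).
#' @param gap_frames tolerated absence run before the track ends
#'   (default 1).
#' @return object of class `hole_track`: data.frame `positions` (frame,
#'   row, col, present) covering all video frames, plus `seed` and
#'   parameters.
#' @export
track_hole <- function(stack, seed, search_radius_px = 5L,
                       depth_min_frac = 0.2, gap_frames = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  start <- if (!is.null(seed$frame)) as.integer(seed$frame) else 1L
  nf <- length(stack$frames)
  if (start < 1L || start > nf) stop("seed frame outside the video")
  pos0 <- c(as.integer(seed$row), as.integer(seed$col))
  v0 <- stack$frames[[start]]$values
  if (pos0[1L] < 1L || pos0[1L] > nrow(v0) ||
      pos0[2L] < 1L || pos0[2L] > ncol(v0))
    stop("seed outside image bounds")
  first <- local_minimum_near(v0, pos0, search_radius_px)
  if (is.null(first) || first[["depth"]] <= 0)
    stop("no hole at seed: no local minimum near the seed in its start frame")
  ref_depth <- first[["depth"]]

  frames <- seq_len(nf)
  res <- data.frame(frame = frames, row = NA_integer_, col = NA_integer_,
                    present = FALSE)
  res[start, c("row", "col")] <- first[c("row", "col")]
  res$present[start] <- TRUE
  last_pos <- first[c("row", "col")]
  miss_run <- 0L
  if (start < nf) for (f in (start + 1L):nf) {
    m <- local_minimum_near(stack$frames[[f]]$values,
                            as.integer(last_pos), search_radius_px)
    ok <- !is.null(m) && m[["depth"]] >= depth_min_frac * ref_depth
    if (ok) {
      res[f, c("row", "col")] <- m[c("row", "col")]
      res$present[f] <- TRUE
      last_pos <- m[c("row", "col")]
      miss_run <- 0L
    } else {
      miss_run <- miss_run + 1L
      if (miss_run > gap_frames) break
    }
  }
  structure(list(positions = res, seed = list(row = pos0[1L], col = pos0[2L],
                                              frame = start),
                 search_radius_px = search_radius_px,
                 depth_min_frac = depth_min_frac,
                 gap_frames = gap_frames),
            class = "hole_track")
}

#' @export
print.hole_track <- function(x, ...) {
  pr <- x$positions$present
  cat(sprintf("<hole_track> present %d/%d frames (first %s, last %s)\n",
              sum(pr), length(pr),
              if (any(pr)) min(which(pr)) else NA,
              if (any(pr)) max(which(pr)) else NA))
  invisible(x)
}

#' Classify track persistence over the video
#'
#' Each track is classified by its presence at the video bounds:
#' `persisted` (present in first and last frame), `appeared` (absent at
#' start, present at end), `disappeared` (present at start, absent at
#' end), `appeared_and_disappeared` (absent at both ends with an interior
#' presence run). The cohort summary reports the fraction in each class
#' (fractions sum to 1).
#'
#' @param tracks list of [track_hole] results (same stack).
#' @param n_frames number of frames in the video.
#' @return list with `status` (character per track) and `summary` (named
#'   fractions).
#' @export
classify_persistence <- function(tracks, n_frames) {
  if (!length(tracks)) stop("no tracks to classify")
  status <- vapply(tracks, function(tr) {
    pr <- tr$positions$present
    if (length(pr) != n_frames)
      stop("track does not span the stated number of frames")
    at_start <- pr[1L]; at_end <- pr[n_frames]
    if (at_start && at_end) "persisted"
    else if (!at_start && at_end) "appeared"
    else if (at_start && !at_end) "disappeared"
    else "appeared_and_disappeared"
  }, character(1))
  lev <- c("persisted", "appeared", "disappeared",
           "appeared_and_disappeared")
  counts <- table(factor(status, levels = lev))
  frac <- as.numeric(counts) / length(status)
  names(frac) <- lev
  list(status = status, summary = frac)
}

#' Write tracks to CSV (track id, frame, row, col, present, status)
#' @param tracks list of [track_hole] results.
#' @param n_frames frames in the video (for status classification).
#' @param path output CSV path.
#' @export
write_track_csv <- function(tracks, n_frames, path) {
  cls <- classify_persistence(tracks, n_frames)
  rows <- lapply(seq_along(tracks), function(i) {
    df <- tracks[[i]]$positions
    df$track <- i
    df$status <- cls$status[i]
    df[c("track", "frame", "row", "col", "present", "status")]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
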