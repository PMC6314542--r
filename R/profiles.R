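#' Specification of an averaged line profile
#'
#' Endpoints are physical `(x, y)` positions in nm (see [pixel_image] for the
#' pixel-center convention). `width_px` perpendicular samples, spaced one
#' pixel apart and centered on the line, are averaged at every position
#' along the line. Tubule-diameter profiles conventionally use a 10-pixel
#' width and at least 700 nm of length.
#'
#' @param from,to numeric length-2 `(x, y)` endpoints in nm; must differ.
#' @param width_px integer averaging width perpendicular to the line (>= 1).
#' @param min_length_nm minimum recommended length; shorter lines are only
#'   flagged, not rejected (default 700).
#' @return an object of class `line_spec`.
#' @export
line_spec <- function(from, to, width_px = 10L, min_length_nm = 700) {
  from <- as.numeric(from); to <- as.numeric(to)
  if (length(from) != 2L || length(to) != 2L || any(!is.finite(c(from, to))))
    stop("'from' and 'to' must be finite (x, y) positions in nm")
  if (all(from == to)) stop("line endpoints must be distinct")
  width_px <- as.integer(width_px)
  if (width_px < 1L) stop("'width_px' must be >= 1")
  structure(list(from = from, to = to, width_px = width_px,
                 min_length_nm = min_length_nm),
            class = "line_spec")
}

# Bilinear interpolation of image values at physical (x, y) nm positions.
# Positions must lie within the outer pixel-center hull.
bilinear_at <- function(image, x_nm, y_nm) {
  p <- image$pixel_size_nm
  # fractional 0-based pixel-center coordinates
  cj <- x_nm / p - 0.5
  ci <- y_nm / p - 0.5
  nr <- nrow(image$values); nc <- ncol(image$values)
  if (any(ci < 0 | ci > nr - 1 | cj < 0 | cj > nc - 1))
    stop("line (after widening) exits the image bounds")
  i0 <- pmin(floor(ci), nr - 2); j0 <- pmin(floor(cj), nc - 2)
  fi <- ci - i0; fj <- cj - j0
  v <- image$values
  idx <- function(i, j) v[cbind(i + 1L, j + 1L)]
  (1 - fi) * (1 - fj) * idx(i0, j0) +
    (1 - fi) * fj * idx(i0, j0 + 1) +
    fi * (1 - fj) * idx(i0 + 1, j0) +
    fi * fj * idx(i0 + 1, j0 + 1)
}

#' Extract a width-averaged intensity line profile
#'
#' Samples at pixel-size spacing along the line from the first endpoint;
#' each sample is the mean of `width_px` bilinearly interpolated values
#' taken perpendicular to the line at one-pixel spacing. Positions are
#' distances (nm) from the first endpoint.
#'
#' @param image [pixel_image].
#' @param line [line_spec].
#' @return data.frame with columns `position_nm`, `intensity`, plus
#'   attributes `pixel_size_nm` and `short` (TRUE when the line is shorter
#'   than the configured minimum, with a warning).
#' @export
extract_profile <- function(image, line) {
  stopifnot(inherits(image, "pixel_image"), inherits(line, "line_spec"))
  p <- image$pixel_size_nm
  d <- line$to - line$from
  len <- sqrt(sum(d^2))
  u <- d / len                       # unit vector along the line
  v <- c(-u[2L], u[1L])              # unit normal
  short <- len < line$min_length_nm
  if (short)
    warning(sprintf("profile length %.0f nm is below the %.0f nm minimum",
                    len, line$min_length_nm))
  pos <- seq(0, len, by = p)
  offs <- (seq_len(line$width_px) - (line$width_px + 1) / 2) * p
  acc <- numeric(length(pos))
  for (o in offs) {
    x <- line$from[1L] + pos * u[1L] + o * v[1L]
    y <- line$from[2L] + pos * u[2L] + o * v[2L]
    acc <- acc + bilinear_at(image, x, y)
  }
  out <- data.frame(position_nm = pos, intensity = acc / line$width_px)
  attr(out, "pixel_size_nm") <- p
  attr(out, "short") <- short
  out
}

#' Read / write profile CSV (columns position_nm, intensity)
#' @param path CSV path.
#' @return data.frame with columns `position_nm`, `intensity`.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_nm", "intensity") %in% names(df)))
    stop("profile CSV must have columns position_nm, intensity")
  df
}

#' @rdname read_profile_csv
#' @param profile data.frame as returned by [extract_profile].
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile[c("position_nm", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}
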