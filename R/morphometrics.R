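#' Circle-equivalent hole diameter
#'
#' With `A = n_pixels * pixel_size_nm^2` the hole area, the equivalent
#' diameter is the diameter of the circle of that area,
#' `d = 2 * sqrt(A / pi)`.
#'
#' @param hole_pixels two-column matrix of pixel `(row, col)` indices, or a
#'   single pixel count.
#' @param pixel_size_nm lateral pixel size in nm.
#' @return diameter in nm.
#' @export
equivalent_diameter <- function(hole_pixels, pixel_size_nm) {
  n <- if (is.matrix(hole_pixels)) nrow(hole_pixels) else as.integer(hole_pixels)
  if (is.na(n) || n < 1L) stop("at least one hole pixel is required")
  2 * sqrt(n * pixel_size_nm^2 / pi)
}

# 2x2 covariance eigenvalues in closed form (population normalization).
cov_eigen2 <- function(pts) {
  mu <- colMeans(pts)
  dx <- pts[, 1L] - mu[1L]; dy <- pts[, 2L] - mu[2L]
  sxx <- mean(dx * dx); syy <- mean(dy * dy); sxy <- mean(dx * dy)
  tr <- sxx + syy
  disc <- sqrt(max((sxx - syy)^2 / 4 + sxy^2, 0))
  c(lambda1 = tr / 2 + disc, lambda2 = max(tr / 2 - disc, 0))
}

#' Covariance-eigenvalue hole symmetry
#'
#' Builds the 2 x 2 covariance matrix of the hole-pixel center coordinates
#' (population normalization: pixel sets are complete enumerations, not
#' samples). With eigenvalues `lambda1 >= lambda2`, the symmetry is the
#' ratio of standard deviations along the minor and major principal axes,
#' `s = sqrt(lambda2 / lambda1)`; `s = 1` for shapes with two equal
#' principal variances (e.g. anything invariant under a 90-degree
#' rotation), and `s = 0` (flagged degenerate) for collinear pixel sets.
#' `ratio = "variance"` returns `lambda2 / lambda1` instead.
#'
#' @param hole_pixels two-column matrix of pixel coordinates (any units;
#'   the ratio is scale-free).
#' @param ratio `"sd"` (default) or `"variance"`.
#' @return list with `s`, `lambda1`, `lambda2`, `degenerate`.
#' @export
hole_symmetry <- function(hole_pixels, ratio = c("sd", "variance")) {
  ratio <- match.arg(ratio)
  if (!is.matrix(hole_pixels) || ncol(hole_pixels) != 2L)
    stop("'hole_pixels' must be a two-column matrix")
  if (nrow(hole_pixels) < 2L)
    return(list(s = NA_real_, lambda1 = 0, lambda2 = 0, degenerate = TRUE))
  ev <- cov_eigen2(hole_pixels)
  if (ev[1L] <= 0)
    return(list(s = NA_real_, lambda1 = 0, lambda2 = 0, degenerate = TRUE))
  r <- ev[2L] / ev[1L]
  s <- if (ratio == "sd") sqrt(r) else r
  list(s = unname(s), lambda1 = unname(ev[1L]), lambda2 = unname(ev[2L]),
       degenerate = ev[2L] == 0)
}

#' Shape statistics for one segmented hole
#'
#' @param hole [delimit_hole] result.
#' @param ratio passed to [hole_symmetry].
#' @return list of class `hole_shape` with `n_pixels`, `area_nm2`,
#'   `equivalent_diameter_nm`, `symmetry`, `lambda1`, `lambda2`.
#' @export
hole_shape <- function(hole, ratio = c("sd", "variance")) {
  stopifnot(inherits(hole, "hole_region"))
  n <- nrow(hole$hole_pixels)
  p <- hole$pixel_size_nm
  if (n < 1L)
    return(structure(list(n_pixels = 0L, area_nm2 = 0,
                          equivalent_diameter_nm = NA_real_, symmetry = NA_real_,
                          lambda1 = NA_real_, lambda2 = NA_real_),
                     class = "hole_shape"))
  sym <- hole_symmetry(hole$hole_pixels, ratio)
  structure(list(
    n_pixels = n,
    area_nm2 = n * p^2,
    equivalent_diameter_nm = equivalent_diameter(hole$hole_pixels, p),
    symmetry = sym$s, lambda1 = sym$lambda1, lambda2 = sym$lambda2
  ), class = "hole_shape")
}

#' Tabulate per-hole measurements
#'
#' @param holes list of [delimit_hole] results (e.g. from
#'   [select_and_reject]).
#' @param pixel_size_nm lateral pixel size in nm.
#' @param ratio passed to [hole_symmetry].
#' @return data.frame with one row per hole: `label_id`, `n_pixels`,
#'   `area_nm2`, `equivalent_diameter_nm`, `symmetry`, `lambda1`,
#'   `lambda2`, `accepted`, `reason`.
#' @export
hole_table <- function(holes, pixel_size_nm, ratio = c("sd", "variance")) {
  rows <- lapply(holes, function(h) {
    s <- hole_shape(h, ratio)
    data.frame(label_id = h$label_id, n_pixels = s$n_pixels,
               area_nm2 = s$area_nm2,
               equivalent_diameter_nm = s$equivalent_diameter_nm,
               symmetry = s$symmetry, lambda1 = s$lambda1,
               lambda2 = s$lambda2,
               accepted = isTRUE(h$accepted),
               reason = if (is.null(h$reason)) NA_character_ else h$reason)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Dunn's pairwise z-tests on the joint ranks, with the standard tie
# correction; two-sided p-values adjusted over all pairs.
dunn_pairwise <- function(values, groups, p_adjust_method = "bonferroni") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[k] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_raw = p_raw,
             p_adjusted = pmin(stats::p.adjust(p_raw, p_adjust_method), 1))
}

#' Compare hole measurements between conditions
#'
#' Nonparametric omnibus comparison (Kruskal-Wallis on joint ranks)
#' followed by Dunn's pairwise z-tests with a multiplicity adjustment over
#' all condition pairs (Bonferroni by default). Per-condition medians and
#' interquartile ranges are reported alongside. Conditions with fewer than
#' two values are excluded with a warning.
#'
#' @param measurements_by_condition named list of numeric vectors, one per
#'   condition.
#' @param p_adjust_method adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return object of class `group_comparison`: list with `omnibus`
#'   (statistic, df, p_value), `pairwise` (data.frame), `summary`
#'   (condition, n, median, iqr).
#' @export
compare_groups <- function(measurements_by_condition,
                           p_adjust_method = "bonferroni") {
  x <- measurements_by_condition
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("group", seq_along(x))
  sizes <- lengths(x)
  if (any(sizes < 2L)) {
    warning("condition(s) with < 2 values excluded: ",
            paste(names(x)[sizes < 2L], collapse = ", "))
    x <- x[sizes >= 2L]
  }
  if (length(x) < 2L) stop("at least two conditions with >= 2 values required")
  values <- unlist(x, use.names = FALSE)
  groups <- factor(rep(names(x), lengths(x)), levels = names(x))
  kw <- stats::kruskal.test(values, groups)
  smry <- data.frame(
    condition = names(x),
    n = lengths(x),
    median = vapply(x, stats::median, numeric(1)),
    iqr = vapply(x, stats::IQR, numeric(1)),
    row.names = NULL
  )
  structure(list(
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value),
    pairwise = dunn_pairwise(values, groups, p_adjust_method),
    summary = smry
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: median %.3g, IQR %.3g (n = %d)\n",
                x$summary$condition[i], x$summary$median[i],
                x$summary$iqr[i], x$summary$n[i]))
  cat("Dunn pairwise (adjusted):\n")
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Swarm-style plot of per-hole measurements by condition
#'
#' Requires ggplot2 (Suggests). Jittered points with median and IQR bars,
#' mirroring the usual presentation of hole symmetry / diameter
#' distributions.
#'
#' @param measurements_by_condition named list of numeric vectors.
#' @param ylab axis label.
#' @return a ggplot object.
#' @export
plot_hole_measurements <- function(measurements_by_condition,
                                   ylab = "measurement") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(
    condition = rep(names(measurements_by_condition),
                    lengths(measurements_by_condition)),
    value = unlist(measurements_by_condition, use.names = FALSE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = condition, y = value)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}
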