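#' Configuration of the synthetic nanohole / sheet / tubule imaging model
#'
#' Parameterizes a STED-like image of a fluorescently labeled ER sheet
#' perforated by torus-edged nanoholes. The membrane geometry is a slab of
#' thickness `sheet_thickness_nm` whose holes are central cylinders of
#' `hole_inner_diameter_nm` rimmed by the inner half of a torus with tube
#' radius `t/2` (so the rim is tangent to both slab faces); the lumen's
#' edge follows the torus. The model is voxelized at `axial_voxel_nm`
#' axially and at a lateral supersampling of the detector pixel, filled
#' with `alpha` per luminal voxel, projected, downsampled to
#' `lateral_px_nm` pixels, convolved with a Lorentzian PSF of FWHM
#' `psf_fwhm_nm`, offset by `background`, and Poisson-sampled.
#'
#' Defaults reproduce the reference simulation conditions: 50-nm sheet,
#' 25 holes spaced 105 px curved-edge-to-curved-edge, 18.9-nm pixels,
#' 1-nm axial voxels, 50-nm-FWHM PSF, `alpha = 10`, `background = 1`, and
#' uniform sub-pixel center jitter.
#'
#' @param sheet_thickness_nm slab thickness t in nm (default 50).
#' @param hole_inner_diameter_nm hole diameter at the torus equator, nm
#'   (default 100; the reference sweep uses 30--200).
#' @param n_holes holes per image (default 25, laid out on a square grid).
#' @param hole_spacing_px gap between adjacent holes' curved (outer torus)
#'   edges, in pixels (default 105).
#' @param lateral_px_nm detector pixel size, nm (default 18.9).
#' @param axial_voxel_nm axial voxel size, nm (default 1).
#' @param supersample lateral subpixels per pixel edge used before
#'   downsampling (default 9, i.e. 2.1-nm subpixels).
#' @param psf_fwhm_nm Lorentzian PSF FWHM, nm (default 50).
#' @param alpha expected intensity per luminal voxel (default 10).
#' @param background constant expected background counts (default 1).
#' @param jitter logical: jitter hole centers uniformly within +/- 0.5
#'   pixel per axis (default TRUE).
#' @param trunc_fwhm PSF truncation radius in FWHM units (default 20; the
#'   kernel is renormalized after truncation).
#' @param rng_seed integer seed governing jitter and shot noise.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(sheet_thickness_nm = 50,
                              hole_inner_diameter_nm = 100,
                              n_holes = 25,
                              hole_spacing_px = 105,
                              lateral_px_nm = 18.9,
                              axial_voxel_nm = 1,
                              supersample = 9L,
                              psf_fwhm_nm = 50,
                              alpha = 10,
                              background = 1,
                              jitter = TRUE,
                              trunc_fwhm = 20,
                              rng_seed = 1L) {
  stopifnot(sheet_thickness_nm > 0, hole_inner_diameter_nm > 0,
            n_holes >= 0, hole_spacing_px > 0, lateral_px_nm > 0,
            axial_voxel_nm > 0, supersample >= 1, psf_fwhm_nm > 0,
            alpha > 0, background >= 0, trunc_fwhm > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> t = %g nm, %d holes of %g nm, %g nm/px, PSF %g nm, alpha %g, bg %g\n",
    x$sheet_thickness_nm, x$n_holes, x$hole_inner_diameter_nm,
    x$lateral_px_nm, x$psf_fwhm_nm, x$alpha, x$background))
  invisible(x)
}

# evaluate code under a temporary RNG seed, restoring the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# number of axial voxel centers (spacing ax, covering [0, t]) whose center
# z lies within |z - zc| <= h
lens_voxel_count <- function(h, zc, ax, t) {
  n_total <- round(t / ax)
  lo <- pmax((zc - h) / ax + 0.5, 1)
  hi <- pmin((zc + h) / ax + 0.5, n_total)
  pmax(floor(hi + 1e-9) - ceiling(lo - 1e-9) + 1, 0)
}

#' Build the luminal occupancy of a nanohole field
#'
#' Voxelizes the slab-with-holes geometry: 1-nm (configurable) axial
#' voxels, lateral subpixels of `lateral_px_nm / supersample`. Because the
#' lumen is axially contiguous in every lateral column, the occupancy is
#' stored as a per-column count of luminal voxels (exactly equivalent to
#' the full 3D grid summed along z, without materializing ~1e9 voxels).
#' A column at lateral distance `r` from a hole axis has luminal height 0
#' for `r <= a_i` (inner radius), `2 sqrt((t/2)^2 - (R_h - r)^2)` for
#' `a_i < r < R_h` (torus cross-section, centerline radius
#' `R_h = a_i + t/2`), and `t` beyond the rim.
#'
#' Holes are laid out on a square grid whose center-to-center spacing is
#' `hole_spacing_px * lateral_px_nm + 2 R_h` (the configured gap between
#' curved edges), with uniform +/- 0.5 px jitter per axis.
#'
#' @param config [simulation_config].
#' @param seed optional seed for the jitter draw (default: the config's
#'   `rng_seed`; `NULL` uses the current RNG state).
#' @return object of class `hole_volume`: `counts` (integer matrix of
#'   luminal voxels per subpixel column), `subpixel_nm`, `field_px`,
#'   `ground_truth` (data.frame: `hole`, `x_nm`, `y_nm`, `row_px`,
#'   `col_px`, `inner_diameter_nm`), `config`.
#' @export
build_hole_volume <- function(config, seed = config$rng_seed) {
  cf <- config
  t <- cf$sheet_thickness_nm
  ax <- cf$axial_voxel_nm
  rt <- t / 2
  ai <- cf$hole_inner_diameter_nm / 2
  Rh <- ai + rt
  px <- cf$lateral_px_nm
  ss <- as.integer(cf$supersample)
  sub <- px / ss
  k <- max(1L, ceiling(sqrt(cf$n_holes)))
  spacing <- cf$hole_spacing_px * px + 2 * Rh
  if (cf$n_holes > 0 && spacing < 2 * Rh + sub)
    stop("holes overlap at the requested spacing")
  field_nm <- k * spacing
  field_px <- ceiling(field_nm / px)
  nsub <- field_px * ss
  base <- round(t / ax)
  counts <- matrix(as.integer(base), nsub, nsub)

  centers <- NULL
  if (cf$n_holes > 0) {
    gx <- (rep(seq_len(k), k) - 0.5) * spacing
    gy <- (rep(seq_len(k), each = k) - 0.5) * spacing
    gx <- gx[seq_len(cf$n_holes)]
    gy <- gy[seq_len(cf$n_holes)]
    jit <- with_seed(seed, {
      if (cf$jitter) matrix(stats::runif(2L * cf$n_holes, -0.5, 0.5) * px,
                            ncol = 2L)
      else matrix(0, cf$n_holes, 2L)
    })
    cx <- gx + jit[, 1L]
    cy <- gy + jit[, 2L]
    win <- ceiling(Rh / sub) + 1L
    sub_center <- function(i) (i - 0.5) * sub
    for (h in seq_len(cf$n_holes)) {
      i0 <- round(cy[h] / sub); j0 <- round(cx[h] / sub)
      ii <- max(1L, i0 - win):min(nsub, i0 + win)
      jj <- max(1L, j0 - win):min(nsub, j0 + win)
      dy <- sub_center(ii) - cy[h]
      dx <- sub_center(jj) - cx[h]
      r <- sqrt(outer(dy^2, dx^2, `+`))
      inside <- r < Rh
      if (!any(inside)) next
      hgt <- matrix(0, length(ii), length(jj))
      rim <- inside & r > ai
      hgt[rim] <- 2 * sqrt(pmax(rt^2 - (Rh - r[rim])^2, 0))
      blk <- counts[ii, jj]
      newc <- as.integer(lens_voxel_count(hgt[inside] / 2, t / 2, ax, t))
      blk[inside] <- newc
      counts[ii, jj] <- blk
    }
    centers <- data.frame(hole = seq_len(cf$n_holes), x_nm = cx, y_nm = cy,
                          row_px = cy / px + 0.5, col_px = cx / px + 0.5,
                          inner_diameter_nm = cf$hole_inner_diameter_nm)
  } else {
    centers <- data.frame(hole = integer(), x_nm = numeric(),
                          y_nm = numeric(), row_px = numeric(),
                          col_px = numeric(), inner_diameter_nm = numeric())
  }
  structure(list(counts = counts, subpixel_nm = sub, field_px = field_px,
                 ground_truth = centers, config = cf),
            class = "hole_volume")
}

#' Build the luminal / dye occupancy of a straight tubule
#'
#' Tubule axis runs along image rows (vertical); the cylinder rests on the
#' axial origin. Lumen labeling fills a disk of radius `d/2` (inner-leaflet
#' convention); surface labeling fills an annulus shell of the geometry's
#' thickness inside the outer-leaflet diameter `d`.
#'
#' @param diameter_nm tubule diameter (> 0), per the labeling convention.
#' @param geometry [tubule_geometry].
#' @param config [simulation_config] (field size follows `n_holes`
#'   layout; only the rendering parameters are used).
#' @param field_px optional field edge length in pixels (default 64).
#' @return `hole_volume`-like object of class `tubule_volume` with the
#'   tubule axis position in the ground truth.
#' @export
build_tubule_volume <- function(diameter_nm, geometry, config,
                                field_px = 64L) {
  if (!is.finite(diameter_nm) || diameter_nm <= 0)
    stop("'diameter_nm' must be > 0")
  cf <- config
  ax <- cf$axial_voxel_nm
  ss <- as.integer(cf$supersample)
  sub <- cf$lateral_px_nm / ss
  nsub <- as.integer(field_px) * ss
  x <- (seq_len(nsub) - 0.5) * sub
  x0 <- field_px * cf$lateral_px_nm / 2
  a <- diameter_nm / 2
  dx <- x - x0
  # per-column luminal/dye height, then discrete voxel count centered at a
  t_span <- diameter_nm
  if (geometry$labeling == "lumen") {
    h <- sqrt(pmax(a^2 - dx^2, 0))
    col_counts <- lens_voxel_count(h, a, ax, t_span)
  } else {
    ai <- a - geometry$annulus_thickness_nm
    if (ai < 0) stop("annulus thicker than the tubule radius")
    ho <- sqrt(pmax(a^2 - dx^2, 0))
    hi <- sqrt(pmax(ai^2 - dx^2, 0))
    col_counts <- lens_voxel_count(ho, a, ax, t_span) -
      lens_voxel_count(hi, a, ax, t_span)
  }
  counts <- matrix(as.integer(col_counts), nsub, nsub, byrow = TRUE)
  structure(list(counts = counts, subpixel_nm = sub,
                 field_px = as.integer(field_px),
                 ground_truth = data.frame(axis_x_nm = x0,
                                           diameter_nm = diameter_nm,
                                           labeling = geometry$labeling),
                 config = cf),
            class = c("tubule_volume", "hole_volume"))
}

# mean over ss x ss blocks (downsample supersampled grid to pixels)
block_mean <- function(m, ss) {
  ss <- as.integer(ss)
  if (ss == 1L) return(m)
  n1 <- nrow(m) %/% ss; n2 <- ncol(m) %/% ss
  if (nrow(m) != n1 * ss || ncol(m) != n2 * ss)
    m <- m[seq_len(n1 * ss), seq_len(n2 * ss), drop = FALSE]
  dim(m) <- c(ss, n1, ss, n2)
  s <- colSums(m)                 # sum over row-subpixels -> (n1, ss, n2)
  out <- colSums(aperm(s, c(2L, 1L, 3L)))
  out / (ss * ss)
}

# radially symmetric 2D Lorentzian whose line projection is the 1D
# Lorentzian of the same FWHM: L(rho) = (b / 2 pi) (b^2 + rho^2)^(-3/2)
lorentz2_kernel <- function(fwhm_nm, px_nm, trunc_fwhm = 20) {
  b <- fwhm_nm / 2
  rk <- max(1L, ceiling(trunc_fwhm * fwhm_nm / px_nm))
  g <- (-rk:rk) * px_nm
  rho2 <- outer(g^2, g^2, `+`)
  k <- (b / (2 * pi)) * (b^2 + rho2)^(-1.5)
  k / sum(k)   # renormalize after truncation
}

# same-size 2D convolution with mirror padding, via FFT
conv2_mirror <- function(m, kern) {
  rk <- (nrow(kern) - 1L) %/% 2L
  pad_idx <- function(n) c(pmin(rk:1, n), 1:n, pmax(n - seq_len(rk) + 1L, 1L))
  P <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
  np <- dim(P)
  Kb <- matrix(0, np[1L], np[2L])
  Kb[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  C <- Re(stats::fft(stats::fft(P) * stats::fft(Kb), inverse = TRUE)) /
    prod(np)
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  C[wrap((seq_len(nrow(m))) + 2L * rk, np[1L]),
    wrap((seq_len(ncol(m))) + 2L * rk, np[2L]), drop = FALSE]
}

#' Render the noise-free expected image of a simulated volume
#'
#' Axial projection (luminal voxel count times `alpha`), area-average
#' downsampling to the detector pixel size, convolution with the unit-area
#' radially symmetric Lorentzian PSF (FWHM `psf_fwhm_nm`, truncated at
#' `trunc_fwhm` FWHM and renormalized; mirror boundary), plus the constant
#' background. The result contains the Poisson means for shot-noise
#' sampling.
#'
#' @param volume [build_hole_volume] or [build_tubule_volume] result.
#' @param config [simulation_config] (defaults to the volume's).
#' @return [pixel_image] of expected counts.
#' @export
render_image <- function(volume, config = volume$config) {
  cf <- config
  ss <- as.integer(cf$supersample)
  proj <- block_mean(volume$counts, ss) * cf$alpha
  kern <- lorentz2_kernel(cf$psf_fwhm_nm, cf$lateral_px_nm, cf$trunc_fwhm)
  out <- conv2_mirror(proj, kern) + cf$background
  pixel_image(pmax(out, 0), cf$lateral_px_nm)
}

#' Add Poisson shot noise to an expected image
#'
#' Independent Poisson draw per pixel with the expected image as the mean;
#' reproducible under a fixed seed.
#'
#' @param expected [pixel_image] of non-negative Poisson means.
#' @param rng_seed integer seed (`NULL` uses the current RNG state).
#' @return noisy [pixel_image] of integer counts.
#' @export
add_shot_noise <- function(expected, rng_seed = NULL) {
  stopifnot(inherits(expected, "pixel_image"))
  if (any(expected$values < 0)) stop("expected values must be >= 0")
  v <- with_seed(rng_seed,
                 stats::rpois(length(expected$values), expected$values))
  pixel_image(matrix(as.numeric(v), nrow(expected$values)),
              expected$pixel_size_nm)
}

#' Simulate one noisy nanohole-field image with ground truth
#'
#' Composition of [build_hole_volume], [render_image] and
#' [add_shot_noise]. The jitter and noise draws are both governed by one
#' seed derived deterministically from the config's `rng_seed` and
#' `image_index`, so a fixed config reproduces bit-identical images.
#'
#' @param config [simulation_config].
#' @param image_index index of the image within a batch (default 1).
#' @return list with `image` (noisy [pixel_image]), `expected`
#'   ([pixel_image]), `ground_truth` (data.frame), `config`.
#' @export
simulate_hole_field <- function(config, image_index = 1L) {
  sub_seed <- if (is.null(config$rng_seed)) NULL
  else (as.numeric(config$rng_seed) * 131L + as.numeric(image_index) * 7919) %%
    2147483647
  res <- with_seed(sub_seed, {
    vol <- build_hole_volume(config, seed = NULL)
    expected <- render_image(vol)
    noisy <- add_shot_noise(expected, rng_seed = NULL)
    list(image = noisy, expected = expected,
         ground_truth = vol$ground_truth, config = config)
  })
  res
}

#' Simulate the reference nanohole sweep
#'
#' Batch mode: `n_images` fields of `config$n_holes` holes for each inner
#' diameter (default: the 30--200 nm reference sweep, four images each).
#'
#' @param config base [simulation_config].
#' @param diameters_nm inner diameters to sweep.
#' @param n_images images per diameter (default 4).
#' @return list of [simulate_hole_field] results with elements named
#'   `d<diameter>_<index>`.
#' @export
simulate_hole_sweep <- function(config = simulation_config(),
                                diameters_nm = c(30, 50, 75, 100, 125,
                                                 150, 200),
                                n_images = 4L) {
  out <- list()
  for (di in seq_along(diameters_nm)) {
    cf <- config
    cf$hole_inner_diameter_nm <- diameters_nm[di]
    for (ii in seq_len(n_images)) {
      idx <- (di - 1L) * n_images + ii
      out[[sprintf("d%g_%d", diameters_nm[di], ii)]] <-
        simulate_hole_field(cf, image_index = idx)
    }
  }
  out
}

#' Simulate a noisy straight-tubule image with ground truth
#'
#' @param diameter_nm tubule diameter (> 0).
#' @param geometry [tubule_geometry].
#' @param config [simulation_config].
#' @param field_px field edge length in pixels (default 64).
#' @return list with `image`, `expected`, `ground_truth`, `config`.
#' @export
simulate_tubule_image <- function(diameter_nm, geometry,
                                  config = simulation_config(),
                                  field_px = 64L) {
  vol <- build_tubule_volume(diameter_nm, geometry, config, field_px)
  expected <- render_image(vol)
  noisy <- add_shot_noise(expected, rng_seed = config$rng_seed)
  list(image = noisy, expected = expected,
       ground_truth = vol$ground_truth, config = config)
}

#' Expected sheet-to-tubule intensity ratio
#'
#' Ratio of the background-subtracted expected interior intensity of a
#' uniform sheet of the given thickness to the background-subtracted
#' expected peak intensity of a lumen-labeled tubule, both rendered under
#' the same configuration. Because the axial extent of the luminal volume
#' is far below the microscope's axial resolution, this ratio is a
#' monotone readout of sheet thickness; [sheet_thickness_from_ratio]
#' inverts it by lookup.
#'
#' @param thickness_nm sheet thickness, nm (>= 0).
#' @param tubule_diameter_nm lumen diameter of the reference tubule.
#' @param config [simulation_config].
#' @return expected intensity ratio (0 for zero thickness).
#' @export
sheet_intensity_ratio <- function(thickness_nm, tubule_diameter_nm = 100,
                                  config = simulation_config()) {
  stopifnot(thickness_nm >= 0)
  cf <- config
  cf$n_holes <- 0L
  tub <- simulate_tubule_expected(tubule_diameter_nm, cf)
  if (thickness_nm == 0) return(0)
  cf$sheet_thickness_nm <- thickness_nm
  vol <- build_hole_volume(cf, seed = NULL)
  sheet <- render_image(vol)
  ctr <- dim(sheet$values) %/% 2L
  sheet_val <- sheet$values[ctr[1L], ctr[2L]] - cf$background
  sheet_val / tub
}

# background-subtracted expected peak of a lumen-labeled tubule
simulate_tubule_expected <- function(tubule_diameter_nm, cf) {
  vol <- build_tubule_volume(tubule_diameter_nm, tubule_geometry("lumen"),
                             cf, field_px = 64L)
  img <- render_image(vol)
  max(img$values) - cf$background
}

#' Invert the sheet/tubule intensity ratio to a thickness estimate
#'
#' @param ratio observed background-subtracted sheet-to-tubule peak ratio.
#' @param tubule_diameter_nm reference tubule diameter.
#' @param config [simulation_config].
#' @param thickness_grid_nm thicknesses tabulated for the monotone lookup.
#' @return estimated sheet thickness in nm.
#' @export
sheet_thickness_from_ratio <- function(ratio, tubule_diameter_nm = 100,
                                       config = simulation_config(),
                                       thickness_grid_nm = seq(10, 150, 10)) {
  r <- vapply(thickness_grid_nm, sheet_intensity_ratio, numeric(1),
              tubule_diameter_nm = tubule_diameter_nm, config = config)
  stats::approx(r, thickness_grid_nm, xout = ratio, rule = 2)$y
}

#' Read / write a simulation config as YAML
#' @param path YAML path.
#' @return [simulation_config].
#' @export
read_sim_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @param config [simulation_config].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
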