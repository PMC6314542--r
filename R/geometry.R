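#' Fixed-area geometric model of a sheet with nanoholes and a tubule
#'
#' A single disk-shaped sheet of thickness `t` (rim modeled as the outer
#' half of a torus with tube radius `r = t/2`), perforated by `n_holes`
#' torus-rimmed nanoholes, with a cylindrical tubule of variable length
#' extending from it. Total membrane surface area is held constant at that
#' of the bare reference sheet (`initial_sheet_diameter_nm`, default 5 um):
#' any area change from holes or tubule is compensated by adjusting the
#' sheet disk diameter.
#'
#' @param initial_sheet_diameter_nm reference sheet diameter (default
#'   5000 nm).
#' @param sheet_thickness_nm sheet thickness t, nm (30, 50 or 100 in the
#'   modeled range; any positive value is accepted).
#' @param hole_inner_diameter_nm hole diameter at the torus equator
#'   (default 100 nm).
#' @param tubule_diameter_nm tubule diameter (default 100 nm).
#' @param n_holes number of nanoholes (>= 0).
#' @param tubule_length_nm tubule length (>= 0).
#' @return object of class `er_geometry_config`.
#' @export
er_geometry_config <- function(initial_sheet_diameter_nm = 5000,
                               sheet_thickness_nm = 50,
                               hole_inner_diameter_nm = 100,
                               tubule_diameter_nm = 100,
                               n_holes = 0L,
                               tubule_length_nm = 0) {
  stopifnot(initial_sheet_diameter_nm > 0, sheet_thickness_nm > 0,
            hole_inner_diameter_nm > 0, tubule_diameter_nm > 0,
            n_holes >= 0, tubule_length_nm >= 0)
  structure(as.list(environment()), class = "er_geometry_config")
}

#' Curved and flat area exchanged by one nanohole
#'
#' The hole rim is the inner half of a torus with tube radius `r = t/2`
#' and centerline radius `R_h = inner radius + r` (the only reading under
#' which the rim is tangent to both slab faces). Inserting one hole adds
#' the inner-half-torus area `2 pi^2 R_h r - 4 pi r^2` of curved membrane
#' and removes the flat annuli of both faces out to the torus centerline,
#' `2 pi R_h^2`.
#'
#' @param sheet_thickness_nm sheet thickness t (> 0), nm.
#' @param hole_inner_diameter_nm hole inner (equator) diameter (> 0), nm.
#' @return list with `curved_added_nm2`, `flat_removed_nm2`.
#' @export
hole_curved_area <- function(sheet_thickness_nm, hole_inner_diameter_nm) {
  stopifnot(sheet_thickness_nm > 0, hole_inner_diameter_nm > 0)
  r <- sheet_thickness_nm / 2
  Rh <- hole_inner_diameter_nm / 2 + r
  list(curved_added_nm2 = 2 * pi^2 * Rh * r - 4 * pi * r^2,
       flat_removed_nm2 = 2 * pi * Rh^2)
}

#' Lateral curved area of a cylindrical tubule
#'
#' `pi * d * L`; no end cap (the tubule is open where it joins the sheet
#' and its far end is taken as continuing membrane).
#'
#' @param tubule_diameter_nm diameter, nm.
#' @param length_nm length, nm (>= 0).
#' @return area in nm^2.
#' @export
tubule_curved_area <- function(tubule_diameter_nm, length_nm) {
  stopifnot(tubule_diameter_nm > 0, length_nm >= 0)
  pi * tubule_diameter_nm * length_nm
}

# area of a bare disk sheet with outer-half-torus rim, as a function of
# the rim centerline radius R (disk outer extent R + r):
#   flat: two faces of radius R; curved: outer half torus 2 pi^2 R r + 4 pi r^2
sheet_area_parts <- function(R, r) {
  list(flat = 2 * pi * R^2, curved = 2 * pi^2 * R * r + 4 * pi * r^2)
}

#' Curvature budget at constant total surface area
#'
#' Computes the flat/curved decomposition of the model's surface area. The
#' total is fixed at the reference sheet's area; inserting holes converts
#' flat face area into curved rim area, extending the tubule adds curved
#' wall area (its junction removes a sheet-rim patch equal to the tubule
#' cross-section), and the sheet disk radius is adjusted in closed form
#' (positive root of the area quadratic) to restore the total. Curved area
#' is reported without sign decomposition: saddle regions (hole rims)
#' count by their total curved area.
#'
#' @param config [er_geometry_config].
#' @return object of class `curvature_budget`: `total_area_nm2`,
#'   `flat_area_nm2`, `curved_area_nm2`, `curved_fraction`,
#'   `adjusted_sheet_diameter_nm`.
#' @export
curvature_budget <- function(config) {
  cf <- config
  r <- cf$sheet_thickness_nm / 2
  R0 <- cf$initial_sheet_diameter_nm / 2 - r
  if (R0 <= 0) stop("sheet diameter below its rim thickness")
  ref <- sheet_area_parts(R0, r)
  total <- ref$flat + ref$curved

  hole <- hole_curved_area(cf$sheet_thickness_nm, cf$hole_inner_diameter_nm)
  tub <- tubule_curved_area(cf$tubule_diameter_nm, cf$tubule_length_nm)
  junction <- if (cf$tubule_length_nm > 0)
    pi * (cf$tubule_diameter_nm / 2)^2 else 0
  # fixed (R-independent) area contributions
  fixed <- cf$n_holes * (hole$curved_added_nm2 - hole$flat_removed_nm2) +
    tub - junction + 4 * pi * r^2
  # solve 2 pi R^2 + 2 pi^2 r R + fixed = total for R > 0
  a <- 2 * pi; b <- 2 * pi^2 * r; cc <- fixed - total
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) stop("infeasible configuration: no positive sheet radius")
  R <- (-b + sqrt(disc)) / (2 * a)
  if (R <= 0) stop("infeasible configuration: sheet radius collapses")
  Rh <- cf$hole_inner_diameter_nm / 2 + r
  if (cf$n_holes * (2 * Rh)^2 > pi * R^2)
    stop("infeasible configuration: sheet too small to host the holes")
  parts <- sheet_area_parts(R, r)
  flat <- parts$flat - cf$n_holes * hole$flat_removed_nm2
  curved <- parts$curved - junction +
    cf$n_holes * hole$curved_added_nm2 + tub
  if (flat < 0) stop("infeasible configuration: negative flat area")
  structure(list(total_area_nm2 = flat + curved,
                 flat_area_nm2 = flat,
                 curved_area_nm2 = curved,
                 curved_fraction = curved / (flat + curved),
                 adjusted_sheet_diameter_nm = 2 * (R + r),
                 reference_total_nm2 = total),
            class = "curvature_budget")
}

#' @export
print.curvature_budget <- function(x, ...) {
  cat(sprintf(
    "<curvature_budget> total %.4g nm^2, curved %.4g (%.1f%%), sheet d = %.3g um\n",
    x$total_area_nm2, x$curved_area_nm2, 100 * x$curved_fraction,
    x$adjusted_sheet_diameter_nm / 1000))
  invisible(x)
}

#' Tubule length storing the same curved area as n nanoholes
#'
#' `L = n * (inner-half-torus area per hole) / (pi * tubule diameter)`:
#' the length of tubule whose lateral wall area equals the total curved
#' rim area of the holes. Independent of the sheet disk size.
#'
#' @param n_holes number of holes.
#' @param sheet_thickness_nm sheet thickness, nm.
#' @param hole_inner_diameter_nm hole inner diameter, nm.
#' @param tubule_diameter_nm tubule diameter, nm.
#' @return equivalent tubule length in nm.
#' @export
equivalent_tubule_length <- function(n_holes, sheet_thickness_nm = 50,
                                     hole_inner_diameter_nm = 100,
                                     tubule_diameter_nm = 100) {
  stopifnot(n_holes >= 0)
  h <- hole_curved_area(sheet_thickness_nm, hole_inner_diameter_nm)
  n_holes * h$curved_added_nm2 / (pi * tubule_diameter_nm)
}

#' Isoclines of constant curved fraction in the (holes, tubule) plane
#'
#' Sweeps hole counts, solves for the tubule length reaching each target
#' curved fraction (1D monotone root), and fits a line through each level
#' set, reporting the fit and its residuals. The budget is affine in
#' `n_holes` and `L` up to the sheet-rim adjustment, so the isoclines are
#' nearly linear.
#'
#' @param config base [er_geometry_config] (its `n_holes` and
#'   `tubule_length_nm` are ignored).
#' @param targets curved-fraction levels.
#' @param n_holes_range integer hole counts to sweep (default 0:50).
#' @param max_length_nm largest tubule length searched (default 2e4).
#' @return data.frame per target: `target`, `slope_nm_per_hole`,
#'   `intercept_nm`, `r_squared`, `n_points`.
#' @export
isoclines <- function(config, targets,
                      n_holes_range = 0:50, max_length_nm = 2e4) {
  fit_one <- function(f) {
    pts <- lapply(n_holes_range, function(n) {
      cf <- config; cf$n_holes <- n
      g <- function(L) {
        cf$tubule_length_nm <- L
        curvature_budget(cf)$curved_fraction - f
      }
      lo <- tryCatch(g(0), error = function(e) NA_real_)
      hi <- tryCatch(g(max_length_nm), error = function(e) NA_real_)
      if (!is.finite(lo) || !is.finite(hi) || lo > 0 || hi < 0) return(NULL)
      L <- stats::uniroot(g, c(0, max_length_nm), tol = 1e-9)$root
      c(n = n, L = L)
    })
    pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
    if (is.null(pts) || nrow(pts) < 2L) return(NULL)
    fit <- stats::lm(L ~ n, data = as.data.frame(pts))
    data.frame(target = f,
               slope_nm_per_hole = unname(stats::coef(fit)[2L]),
               intercept_nm = unname(stats::coef(fit)[1L]),
               r_squared = summary(fit)$r.squared,
               n_points = nrow(pts))
  }
  out <- lapply(targets, fit_one)
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
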