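#' Digital NEMA IEC body phantom specification
#'
#' Declarative description of the digital phantom: six fillable spheres
#' (default diameters 10, 13, 17, 22, 28, 37 mm, i.e. 0.5, 1.2, 2.6, 5.6,
#' 11.5, 26.5 mL) on a coplanar ring of 114.4 mm diameter inside a simplified
#' elliptical-cylinder background compartment, filled at a
#' foreground-to-background concentration of 237:30 kBq/mL (ratio 7.9,
#' conventionally quoted as 8:1). Sphere centers may be overridden; by default
#' the largest sphere sits at ring angle 0 and diameters decrease every 60
#' degrees, and four background VOIs (radius 15 mm) are placed on the opposite
#' azimuthal side, 55 mm below the sphere plane, far from every insert.
#'
#' @param sphere_diameters_mm sphere diameters in mm.
#' @param sphere_centers_mm optional list of length-3 centers in mm relative to
#'   the body center; default NEMA ring arrangement.
#' @param ring_diameter_mm diameter of the default sphere ring.
#' @param body_semiaxes_mm in-plane semi-axes (x, y) of the elliptical-cylinder
#'   body compartment.
#' @param body_height_mm cylinder height (z extent).
#' @param fg_conc,bg_conc foreground / background activity concentration in
#'   kBq/mL.
#' @return An object of class `phantom_spec`.
#' @export
nema_phantom_spec <- function(sphere_diameters_mm = c(37, 28, 22, 17, 13, 10),
                              sphere_centers_mm = NULL,
                              ring_diameter_mm = 114.4,
                              body_semiaxes_mm = c(110, 90),
                              body_height_mm = 180,
                              fg_conc = 237, bg_conc = 30) {
  if (any(sphere_diameters_mm <= 0)) stop("sphere diameters must be > 0")
  if (fg_conc < 0 || bg_conc < 0) stop("concentrations must be >= 0")
  n <- length(sphere_diameters_mm)
  if (is.null(sphere_centers_mm)) {
    ang <- (seq_len(n) - 1) * 2 * pi / n
    r <- ring_diameter_mm / 2
    sphere_centers_mm <- lapply(seq_len(n), function(i)
      c(r * cos(ang[i]), r * sin(ang[i]), 0))
  }
  if (length(sphere_centers_mm) != n)
    stop("need one center per sphere")
  spec <- structure(list(sphere_diameters_mm = sphere_diameters_mm,
                         sphere_centers_mm = sphere_centers_mm,
                         body_semiaxes_mm = body_semiaxes_mm,
                         body_height_mm = body_height_mm,
                         fg_conc = fg_conc, bg_conc = bg_conc),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  n <- length(spec$sphere_diameters_mm)
  rad <- spec$sphere_diameters_mm / 2
  ctr <- spec$sphere_centers_mm
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((ctr[[i]] - ctr[[j]])^2))
      if (d < rad[i] + rad[j])
        stop(sprintf("spec error: spheres %d and %d overlap", i, j))
    }
  }
  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
  hz <- spec$body_height_mm / 2
  for (i in seq_len(n)) {
    c_i <- ctr[[i]]; r <- rad[i]
    # conservative inclusion check for the ellipse: shrink semi-axes by r
    if ((c_i[1] / (a - r))^2 + (c_i[2] / (b - r))^2 > 1 || abs(c_i[3]) + r > hz)
      stop(sprintf("spec error: sphere %d not inside the body compartment", i))
  }
  invisible(spec)
}

#' Analytic sphere volumes of a phantom spec, in mL
#' @param spec a [nema_phantom_spec].
#' @return Numeric vector of analytic volumes (4/3) pi r^3 in mL.
#' @export
phantom_sphere_volumes_ml <- function(spec) {
  (4 / 3) * pi * (spec$sphere_diameters_mm / 2)^3 / 1000
}

# fractional occupancy of the elliptical-cylinder body, supersampled
body_occupancy <- function(spec, grid, supersampling = 2L) {
  sp <- grid$spacing_mm
  ctr <- grid_center_mm(grid)
  a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
  hz <- spec$body_height_mm / 2
  s <- as.integer(supersampling)
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  cx <- axis_centers(grid, 1) - ctr[1]
  cy <- axis_centers(grid, 2) - ctr[2]
  cz <- axis_centers(grid, 3) - ctr[3]
  occ <- array(0, dim(grid))
  for (ox in off) for (oy in off) for (oz in off) {
    ex <- ((cx + ox * sp[1]) / a)^2
    ey <- ((cy + oy * sp[2]) / b)^2
    ez <- abs(cz + oz * sp[3]) <= hz
    inplane <- outer(ex, ey, "+") <= 1
    occ <- occ + outer(inplane, ez, "&")
  }
  occ / s^3
}

#' Generate the digital phantom ground truth
#'
#' Paints the phantom activity distribution on a voxel grid. With
#' `paint = "fractional"` (default) every voxel value is
#' `occ_sphere * fg + (1 - occ_sphere) * bg` inside the body (occupancies
#' supersampled sub-voxel), which conserves total activity against the
#' analytic volumes to < 0.5%. With `paint = "binary"` voxels take `fg`
#' exactly on the sphere hard masks and `bg` on the body hard mask, which
#' makes a hard-mask VOI mean of the unblurred image exactly `fg`.
#'
#' @param spec a [nema_phantom_spec].
#' @param grid an [image3d] template (see [image_grid]); the phantom is
#'   centered on the grid.
#' @param paint `"fractional"` or `"binary"` edge handling.
#' @param supersampling sub-voxel sampling per axis for occupancies.
#' @return A list with elements `truth` (an `image3d`, kBq/mL), `sphere_vois`
#'   (one [rasterize_sphere] VOI per sphere, largest first, labelled by
#'   nominal volume), `background_vois` (four spherical VOIs in the background
#'   compartment), `body_mask` (logical array) and `spec`.
#' @export
generate_phantom <- function(spec, grid = image_grid(),
                             paint = c("fractional", "binary"),
                             supersampling = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  paint <- match.arg(paint)
  grid <- image3d(grid$values * 0, grid$spacing_mm, "kBq/mL")
  ctr <- grid_center_mm(grid)

  bocc <- body_occupancy(spec, grid, supersampling = min(supersampling, 2L))
  body_mask <- bocc >= 0.5

  n <- length(spec$sphere_diameters_mm)
  vols <- phantom_sphere_volumes_ml(spec)
  sphere_vois <- vector("list", n)
  for (i in seq_len(n)) {
    sphere_vois[[i]] <- rasterize_sphere(ctr + spec$sphere_centers_mm[[i]],
                                         spec$sphere_diameters_mm[i] / 2,
                                         grid, supersampling = supersampling,
                                         label = sprintf("%.1f mL", vols[i]))
  }
  names(sphere_vois) <- vapply(sphere_vois, `[[`, "", "label")

  if (paint == "fractional") {
    vals <- bocc * spec$bg_conc
    for (v in sphere_vois)
      vals <- vals + v$frac * (spec$fg_conc - spec$bg_conc)
  } else {
    vals <- body_mask * spec$bg_conc
    for (v in sphere_vois)
      vals[v$mask] <- spec$fg_conc
  }
  truth <- image3d(vals, grid$spacing_mm, "kBq/mL")

  # background VOIs: azimuthally opposite the largest insert, below the
  # sphere plane (placement is an assumption of the digital phantom; the
  # physical measurement protocol does not specify it)
  bk_ang <- c(90, 150, 210, 270) * pi / 180
  bkg_vois <- lapply(seq_along(bk_ang), function(i) {
    rasterize_sphere(ctr + c(30 * cos(bk_ang[i]), 30 * sin(bk_ang[i]), -55),
                     15, grid, supersampling = supersampling,
                     label = sprintf("bkg%d", i))
  })
  names(bkg_vois) <- vapply(bkg_vois, `[[`, "", "label")

  list(truth = truth, sphere_vois = sphere_vois, background_vois = bkg_vois,
       body_mask = body_mask, spec = spec)
}
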