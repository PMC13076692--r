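#' Rasterize a spherical volume of interest
#'
#' Builds both a fractional-occupancy lattice (sub-voxel supersampled; used for
#' painting ground truth) and a hard boolean mask (occupancy >= 0.5; used for
#' measurements) for a sphere given in continuous mm coordinates. Occupancies
#' combine an exact chord integral along z with in-plane supersampling; at
#' the default supersampling of 4 per axis the fractional volume matches the
#' analytic (4/3) pi r^3 to within 0.5% for spheres of at least one voxel
#' radius.
#'
#' @param center_mm sphere center, length-3 mm vector (voxel centers at
#'   `(i - 0.5) * spacing`).
#' @param radius_mm sphere radius in mm, > 0.
#' @param reference an [image3d] defining the grid.
#' @param supersampling sub-voxel sampling points per axis (integer >= 1).
#' @param label optional VOI label.
#' @return An object of class `voi` with elements `mask` (logical array),
#'   `frac` (fractional-occupancy array), `volume_ml` (fractional volume),
#'   `mask_volume_ml`, `center_mm`, `radius_mm`, `label`.
#' @export
rasterize_sphere <- function(center_mm, radius_mm, reference, supersampling = 4L,
                             label = NULL) {
  stopifnot(inherits(reference, "image3d"))
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  s <- as.integer(supersampling)
  if (s < 1L) stop("`supersampling` must be >= 1")
  sp <- reference$spacing_mm
  d <- dim(reference)
  cx <- axis_centers(reference, 1); cy <- axis_centers(reference, 2)
  cz <- axis_centers(reference, 3)

  ix <- which(abs(cx - center_mm[1]) <= radius_mm + sp[1])
  iy <- which(abs(cy - center_mm[2]) <= radius_mm + sp[2])
  iz <- which(abs(cz - center_mm[3]) <= radius_mm + sp[3])
  if (!length(ix) || !length(iy) || !length(iz))
    stop("empty-VOI error: sphere lies fully outside the grid")

  # occupancy: exact chord overlap along z per (x, y) subcolumn, s^2
  # in-plane subsamples per voxel (sub-voxel centers at (j-0.5)/s - 0.5)
  off <- ((seq_len(s) - 0.5) / s - 0.5)
  frac_box <- array(0, c(length(ix), length(iy), length(iz)))
  zlo <- (iz - 1) * sp[3]
  zhi <- iz * sp[3]
  for (ox in off) for (oy in off) {
    dx2 <- (cx[ix] + ox * sp[1] - center_mm[1])^2
    dy2 <- (cy[iy] + oy * sp[2] - center_mm[2])^2
    h <- sqrt(pmax(radius_mm^2 - outer(dx2, dy2, "+"), 0))
    for (k in seq_along(iz)) {
      ov <- pmin(zhi[k], center_mm[3] + h) - pmax(zlo[k], center_mm[3] - h)
      frac_box[, , k] <- frac_box[, , k] + pmax(ov, 0) / sp[3]
    }
  }
  frac_box <- frac_box / s^2
  if (all(frac_box == 0))
    stop("empty-VOI error: sphere lies fully outside the grid")

  frac <- array(0, d)
  frac[ix, iy, iz] <- frac_box
  mask <- frac >= 0.5
  vv <- voxel_volume_ml(reference)
  structure(list(label = label, kind = "sphere", center_mm = center_mm,
                 radius_mm = radius_mm, mask = mask, frac = frac,
                 volume_ml = sum(frac) * vv,
                 mask_volume_ml = sum(mask) * vv),
            class = "voi")
}

#' Wrap an explicit boolean mask as a VOI
#'
#' @param mask logical 3D array congruent with the images it will measure.
#' @param reference an [image3d] supplying the voxel spacing.
#' @param label optional label.
#' @return A `voi` whose fractional lattice equals the mask.
#' @export
mask_voi <- function(mask, reference, label = NULL) {
  stopifnot(inherits(reference, "image3d"))
  if (!is.logical(mask) || !identical(dim(mask), dim(reference)))
    stop("`mask` must be a logical array congruent with `reference`")
  if (!any(mask)) stop("empty-VOI error: mask has no voxels")
  vv <- voxel_volume_ml(reference)
  structure(list(label = label, kind = "explicit-mask", center_mm = NULL,
                 radius_mm = NULL, mask = mask, frac = mask * 1,
                 volume_ml = sum(mask) * vv, mask_volume_ml = sum(mask) * vv),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("voi '%s' (%s): %d mask voxels, %.3f mL (fractional %.3f mL)\n",
              if (is.null(x$label)) "" else x$label, x$kind, sum(x$mask),
              x$mask_volume_ml, x$volume_ml))
  invisible(x)
}

voi_mask <- function(voi) {
  m <- if (inherits(voi, "voi")) voi$mask else voi
  if (!is.logical(m)) stop("expected a `voi` or logical mask")
  m
}

#' Mean and standard deviation within a VOI
#'
#' Arithmetic mean / population standard deviation (divisor n) of the image
#' values under the VOI's hard mask.
#'
#' @param img an [image3d].
#' @param voi a [rasterize_sphere]/[mask_voi] object or a logical mask array.
#' @return A scalar.
#' @export
mean_in_voi <- function(img, voi) {
  stopifnot(inherits(img, "image3d"))
  m <- voi_mask(voi)
  if (!identical(dim(m), dim(img)))
    stop("geometry error: mask not congruent with image")
  if (!any(m)) stop("empty mask: VOI contains no voxels")
  mean(img$values[m])
}

#' @rdname mean_in_voi
#' @export
sd_in_voi <- function(img, voi) {
  stopifnot(inherits(img, "image3d"))
  m <- voi_mask(voi)
  if (!identical(dim(m), dim(img)))
    stop("geometry error: mask not congruent with image")
  if (!any(m)) stop("empty mask: VOI contains no voxels")
  v <- img$values[m]
  sqrt(mean((v - mean(v))^2))
}
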