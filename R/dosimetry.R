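#' Threshold segmentation of a lesion
#'
#' Region-growing threshold segmentation: the value maximum within
#' `search_radius_mm` of the seed point is located, the threshold is either a
#' fixed fraction of that regional maximum (`method = "fraction"`, default
#' 0.4) or an absolute concentration (`method = "absolute"`), and the
#' 6-connected supra-threshold component containing the maximum is returned.
#'
#' @param img the [image3d] to segment (conventionally the uncorrected 24 h
#'   reconstruction).
#' @param seed_mm length-3 seed point in mm, inside the lesion.
#' @param method `"fraction"` (of the regional maximum) or `"absolute"`
#'   (concentration threshold in image units).
#' @param threshold the fraction (default 0.4) or the absolute value.
#' @param search_radius_mm radius of the ball around the seed searched for
#'   the regional maximum.
#' @return An object of class `lesion_seg`: `mask` (logical array),
#'   `volume_ml` (mask voxels x voxel volume), `method`, `threshold`,
#'   `max_value`, `seed_mm`.
#' @export
segment_lesion <- function(img, seed_mm, method = c("fraction", "absolute"),
                           threshold = 0.4, search_radius_mm = 15) {
  stopifnot(inherits(img, "image3d"))
  method <- match.arg(method)
  d <- dim(img)
  idx <- pmin(pmax(ceiling(seed_mm / img$spacing_mm), 1L), d)

  ball <- rasterize_sphere(seed_mm, search_radius_mm, img, supersampling = 1L)
  cand <- which(ball$frac > 0)
  if (!length(cand)) cand <- (idx[3] - 1) * d[1] * d[2] + (idx[2] - 1) * d[1] + idx[1]
  mx_i <- cand[which.max(img$values[cand])]
  mx <- img$values[mx_i]
  thr <- if (method == "fraction") threshold * mx else threshold
  if (thr > mx)
    stop("empty-segmentation error: threshold exceeds the regional maximum")

  supra <- img$values >= thr
  mask <- flood_fill_6(supra, mx_i, d)
  vv <- voxel_volume_ml(img)
  structure(list(mask = mask, volume_ml = sum(mask) * vv, method = method,
                 threshold = threshold, max_value = mx, seed_mm = seed_mm),
            class = "lesion_seg")
}

# 6-connected flood fill from a linear seed index over a logical array
flood_fill_6 <- function(supra, seed_idx, d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxy <- nx * ny
  out <- logical(length(supra))
  if (!supra[seed_idx]) return(array(out, d))
  stack <- integer(2048); stack[1] <- seed_idx; top <- 1L
  out[seed_idx] <- TRUE
  while (top > 0L) {
    i <- stack[top]; top <- top - 1L
    z <- (i - 1L) %/% nxy
    rem <- (i - 1L) %% nxy
    y <- rem %/% nx
    x <- rem %% nx
    nbrs <- c(if (x > 0L) i - 1L, if (x < nx - 1L) i + 1L,
              if (y > 0L) i - nx, if (y < ny - 1L) i + nx,
              if (z > 0L) i - nxy, if (z < nz - 1L) i + nxy)
    for (j in nbrs) {
      if (supra[j] && !out[j]) {
        out[j] <- TRUE
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, integer(length(stack)))
        stack[top] <- j
      }
    }
  }
  array(out, d)
}

#' Tumor-to-background ratio of a segmented lesion
#'
#' Places four copies of the lesion mask just outside the lesion boundary
#' (shifted along +x, -x, +y, -y by the lesion's bounding-box extent plus a
#' gap) and returns the lesion mean divided by the average of the four
#' background-copy means.
#'
#' @param img measured [image3d].
#' @param lesion a [segment_lesion] result (or `voi`/logical mask).
#' @param gap_voxels extra spacing between lesion and background copies.
#' @param body_mask optional logical array; if supplied, every background
#'   copy must lie inside it.
#' @return TBR as a scalar.
#' @export
measure_tbr <- function(img, lesion, gap_voxels = 1L, body_mask = NULL) {
  stopifnot(inherits(img, "image3d"))
  m <- if (inherits(lesion, "lesion_seg")) lesion$mask else voi_mask(lesion)
  if (!any(m)) stop("empty lesion mask")
  d <- dim(img)
  w <- which(m, arr.ind = TRUE)
  ext <- apply(w, 2, function(v) diff(range(v)) + 1L)
  shifts <- list(c(ext[1] + gap_voxels, 0, 0), c(-(ext[1] + gap_voxels), 0, 0),
                 c(0, ext[2] + gap_voxels, 0), c(0, -(ext[2] + gap_voxels), 0))
  bk_means <- vapply(shifts, function(s) {
    wi <- sweep(w, 2, as.integer(s), "+")
    if (any(wi < 1L) || any(wi[, 1] > d[1]) || any(wi[, 2] > d[2]) ||
        any(wi[, 3] > d[3]))
      stop("placement error: background VOI exits the image grid")
    li <- (wi[, 3] - 1) * d[1] * d[2] + (wi[, 2] - 1) * d[1] + wi[, 1]
    if (!is.null(body_mask) && !all(body_mask[li]))
      stop("placement error: background VOI exits the body")
    mean(img$values[li])
  }, numeric(1))
  mean(img$values[m]) / mean(bk_means)
}

#' Voxel-wise monoexponential time-activity fit
#'
#' Fits `A(t) = A0 * exp(-lambda_eff * t)` per voxel by log-linear least
#' squares over the voxel's positive samples. Voxels whose fitted effective
#' decay constant falls at or below `lambda_floor`, or that have a
#' non-positive sample among at least two positive ones, are refitted with
#' `lambda_eff` fixed at the floor (`A0` from the floor-constrained log-mean)
#' and flagged `"fallback-physical"`; voxels with fewer than two positive
#' samples are flagged `"excluded"` (A0 = 0, zero time-integrated activity).
#' The default floor is the physical Lu-177 decay constant ln2 / (6.7 d).
#'
#' @param series list of congruent [image3d]s, one per timepoint (kBq/mL).
#' @param times_h strictly increasing acquisition times in h (>= 2).
#' @param lambda_floor lower bound on the effective decay constant (h^-1).
#' @return An object of class `tac_fit`: arrays `A0` (kBq/mL at t = 0) and
#'   `lambda` (h^-1), integer array `flag` (0 ok, 1 fallback-physical,
#'   2 excluded), plus `spacing_mm`, `times_h`, `lambda_floor`.
#' @export
fit_tac <- function(series, times_h, lambda_floor = LU177_LAMBDA_PHYS) {
  if (length(series) < 2) stop("need at least two timepoints")
  if (length(times_h) != length(series) || any(diff(times_h) <= 0))
    stop("`times_h` must be strictly increasing, one per image")
  if (lambda_floor <= 0) stop("`lambda_floor` must be > 0")
  ref <- series[[1]]
  for (im in series) stopifnot_same_grid(ref, im)

  nt <- length(series)
  V <- vapply(series, function(im) as.vector(im$values),
              numeric(length(ref$values)))     # n_voxels x nt
  if (is.null(dim(V))) dim(V) <- c(1L, nt)     # single-voxel grids
  pos <- V > 0
  npos <- rowSums(pos)

  n <- nrow(V)
  A0 <- numeric(n); lam <- rep(lambda_floor, n); flag <- rep(2L, n)

  # voxels positive at every timepoint: one shared closed-form regression
  full <- npos == nt
  if (any(full)) {
    Y <- log(V[full, , drop = FALSE])
    tbar <- mean(times_h); tc <- times_h - tbar
    slope <- (Y %*% tc) / sum(tc^2)
    icept <- rowMeans(Y) - slope * tbar
    l <- -as.vector(slope)
    ok <- l > lambda_floor
    A0[full] <- exp(as.vector(icept))
    lam[full] <- l
    flag[full] <- 0L
    # floor-constrained refit where the fitted decay is too slow (or negative)
    if (any(!ok)) {
      idx <- which(full)[!ok]
      lA0 <- rowMeans(sweep(log(V[idx, , drop = FALSE]), 2, lambda_floor * times_h,
                            "+"))
      A0[idx] <- exp(lA0)
      lam[idx] <- lambda_floor
      flag[idx] <- 1L
    }
  }

  # partially positive voxels: per-pattern regression on the positive subset
  part <- npos >= 2 & !full
  if (any(part)) {
    pat <- apply(pos[part, , drop = FALSE], 1, function(p)
      paste(as.integer(p), collapse = ""))
    for (p in unique(pat)) {
      sel <- which(part)[pat == p]
      use <- as.logical(as.integer(strsplit(p, "")[[1]]))
      ts <- times_h[use]
      lA0 <- rowMeans(sweep(log(V[sel, use, drop = FALSE]), 2,
                            lambda_floor * ts, "+"))
      A0[sel] <- exp(lA0)
      lam[sel] <- lambda_floor
      flag[sel] <- 1L
    }
  }

  structure(list(A0 = array(A0, dim(ref)), lambda = array(lam, dim(ref)),
                 flag = array(flag, dim(ref)), spacing_mm = ref$spacing_mm,
                 times_h = times_h, lambda_floor = lambda_floor),
            class = "tac_fit")
}

#' Time-integrated activity map from a fitted time-activity model
#'
#' Analytic 0-to-infinity integral of the monoexponential:
#' `TIA_voxel = A0 * voxel_volume / lambda_eff`, converted from kBq/mL to
#' Bq.h per voxel. Excluded voxels contribute 0.
#'
#' @param fit a [fit_tac] result.
#' @return An [image3d] in `Bq.h_per_voxel` units.
#' @export
integrate_tia <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  if (any(fit$lambda <= 0)) stop("non-positive decay constant in fit")  # guarded
  vv <- prod(fit$spacing_mm) / 1000                     # mL
  tia <- fit$A0 * 1000 * vv / fit$lambda                # kBq/mL -> Bq per voxel
  tia[fit$flag == 2L] <- 0
  image3d(tia, fit$spacing_mm, "Bq.h_per_voxel")
}

#' Voxel S-value dose kernel
#'
#' A cubic, odd-dimension lattice of absorbed dose to a target voxel (Gy) per
#' unit cumulated activity (Bq.h) in a source voxel, with its voxel spacing.
#'
#' @param values numeric 3D array, odd cubic dimensions, non-negative,
#'   central element > 0, symmetric under reflection.
#' @param spacing_mm voxel spacing in mm.
#' @param provenance free-text tag recording where the kernel came from.
#' @return An object of class `dose_kernel`.
#' @export
dose_kernel <- function(values, spacing_mm, provenance = "user") {
  if (!is.numeric(values) || length(dim(values)) != 3L)
    stop("kernel values must be a 3D array")
  d <- dim(values)
  if (any(d %% 2L == 0L)) stop("kernel dimensions must be odd")
  if (any(values < 0)) stop("kernel values must be >= 0")
  ctr <- (d + 1L) / 2L
  if (values[ctr[1], ctr[2], ctr[3]] <= 0) stop("central element must be > 0")
  for (ax in 1:3) {
    flipped <- do.call(`[`, c(list(values), lapply(seq_along(d), function(a)
      if (a == ax) rev(seq_len(d[a])) else seq_len(d[a]))))
    if (max(abs(flipped - values)) > 1e-12 * max(values))
      stop("kernel must be symmetric under reflection")
  }
  sp <- as.numeric(spacing_mm); if (length(sp) == 1L) sp <- rep(sp, 3L)
  structure(list(values = values, spacing_mm = sp, provenance = provenance),
            class = "dose_kernel")
}

#' Local-deposition Lu-177 voxel S-value kernel
#'
#' Default dose kernel: the full mean electron (beta + conversion + Auger)
#' energy per decay, 147.9 keV, is deposited in the source voxel; photon
#' cross-dose is omitted. The single central element is
#' `E_mean[J] * 3600 / m_voxel[kg]` Gy per Bq.h (unit-density water voxel),
#' so halving the voxel volume doubles the element. Published voxel S-value
#' tables can be substituted via [read_dose_kernel].
#'
#' @param spacing_mm voxel spacing in mm (> 0; scalar or length 3).
#' @return A 1 x 1 x 1 [dose_kernel].
#' @export
default_lu177_kernel <- function(spacing_mm) {
  sp <- as.numeric(spacing_mm); if (length(sp) == 1L) sp <- rep(sp, 3L)
  if (any(sp <= 0)) stop("spacing must be > 0")
  m_kg <- prod(sp) / 1000 * 1e-3          # mL of water -> kg
  s <- LU177_MEAN_ELECTRON_KEV * KEV_TO_J * 3600 / m_kg
  dose_kernel(array(s, c(1L, 1L, 1L)), sp,
              provenance = "local-deposition Lu-177 (147.9 keV/decay)")
}

#' Read / write a dose kernel as CSV
#'
#' Plain-text round-trip format: three header lines (`dim`, `spacing_mm`,
#' `units`) followed by one kernel value per line in row-major (C) order.
#'
#' @param path file path.
#' @param kernel a [dose_kernel] (for writing).
#' @return `read_dose_kernel` returns a `dose_kernel`.
#' @export
read_dose_kernel <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:3], ",")
  stopifnot(hdr[[1]][1] == "dim", hdr[[2]][1] == "spacing_mm",
            hdr[[3]][1] == "units")
  d <- as.integer(hdr[[1]][-1])
  sp <- as.numeric(hdr[[2]][-1])
  vals <- as.numeric(lines[-(1:3)])
  # row-major on disk -> column-major array
  arr <- aperm(array(vals, rev(d)), 3:1)
  dose_kernel(arr, sp, provenance = paste0("csv:", path))
}

#' @rdname read_dose_kernel
#' @export
write_dose_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "dose_kernel"))
  d <- dim(kernel$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("dim", d), collapse = ","),
               paste(c("spacing_mm", format(kernel$spacing_mm, digits = 17)),
                     collapse = ","),
               "units,Gy_per_Bq_h"), con)
  writeLines(format(as.vector(aperm(kernel$values, 3:1)), digits = 17), con)
  invisible(path)
}

#' Absorbed-dose map by voxel S-value convolution
#'
#' `dose = TIA (*) kernel`: linear shift-invariant convolution of the
#' time-integrated-activity map with the voxel S-value kernel.
#'
#' @param tia an [image3d] in `Bq.h_per_voxel` units.
#' @param kernel a [dose_kernel] whose spacing matches the image.
#' @return An [image3d] in Gy.
#' @export
convolve_dose <- function(tia, kernel) {
  stopifnot(inherits(tia, "image3d"), inherits(kernel, "dose_kernel"))
  if (any(abs(kernel$spacing_mm - tia$spacing_mm) > 1e-6))
    stop("geometry error: kernel spacing does not match the image")
  if (all(dim(kernel$values) == 1L)) {
    vals <- tia$values * kernel$values[1]
  } else {
    vals <- conv_fft_arrays(tia$values, kernel$values)
    vals[vals < 0] <- 0
  }
  image3d(vals, tia$spacing_mm, "Gy")
}

#' Compare lesion absorbed doses across correction strategies
#'
#' For each lesion mask (fixed, by convention defined on the uncorrected
#' reconstruction) the mean absorbed dose per unit injected activity (Gy/GBq)
#' is computed from the uncorrected dose map (`OR`), the deconvolved dose map
#' (`OR+LRD`), and by scaling the uncorrected value with the volume-derived
#' recovery correction `1 / f_RC(V)` (`OR+RC`). Percent differences are
#' `100 * |AD_x - AD_OR| / AD_OR`.
#'
#' @param dose_or,dose_lrd congruent absorbed-dose [image3d]s (Gy).
#' @param rc_curve a fitted [fit_rc_curve] recovery curve.
#' @param lesions list of [segment_lesion] results (or VOIs / logical masks).
#' @param injected_GBq injected activity in GBq.
#' @param tbr optional per-lesion tumor-to-background ratios to carry through.
#' @return A data.frame with one row per lesion: `lesion_id`, `volume_ml`,
#'   `tbr`, `ad_or`, `ad_lrd`, `ad_rc` (Gy/GBq), `pct_lrd`, `pct_rc`.
#' @export
compare_doses <- function(dose_or, dose_lrd, rc_curve, lesions, injected_GBq,
                          tbr = NULL) {
  stopifnot(inherits(dose_or, "image3d"), inherits(dose_lrd, "image3d"))
  stopifnot_same_grid(dose_or, dose_lrd)
  if (injected_GBq <= 0) stop("`injected_GBq` must be > 0")
  if (!length(lesions)) {
    return(data.frame(lesion_id = integer(), volume_ml = numeric(),
                      tbr = numeric(), ad_or = numeric(), ad_lrd = numeric(),
                      ad_rc = numeric(), pct_lrd = numeric(),
                      pct_rc = numeric()))
  }
  vv <- voxel_volume_ml(dose_or)
  rows <- lapply(seq_along(lesions), function(i) {
    les <- lesions[[i]]
    m <- if (inherits(les, "lesion_seg")) les$mask else voi_mask(les)
    vol <- sum(m) * vv
    ad_or <- mean(dose_or$values[m]) / injected_GBq
    ad_lrd <- mean(dose_lrd$values[m]) / injected_GBq
    ad_rc <- ad_or * rc_correction_factor(rc_curve, vol)
    data.frame(lesion_id = i, volume_ml = vol,
               tbr = if (is.null(tbr)) NA_real_ else tbr[i],
               ad_or = ad_or, ad_lrd = ad_lrd, ad_rc = ad_rc,
               pct_lrd = 100 * abs(ad_lrd - ad_or) / ad_or,
               pct_rc = 100 * abs(ad_rc - ad_or) / ad_or)
  })
  do.call(rbind, rows)
}
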