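#' Recovery coefficients of known-volume sphere VOIs
#'
#' RC = mean measured concentration in the pre-defined VOI / known true
#' foreground concentration. The VOIs come from ground-truth geometry (they
#' are not re-segmented from the image).
#'
#' @param img measured [image3d] (kBq/mL).
#' @param sphere_vois named list of sphere VOIs (see [generate_phantom]).
#' @param true_fg_conc known foreground concentration, > 0.
#' @return A data.frame with columns `label`, `volume_ml`, `mean_conc`, `rc`.
#' @export
compute_rc <- function(img, sphere_vois, true_fg_conc) {
  if (true_fg_conc <= 0) stop("`true_fg_conc` must be > 0")
  if (inherits(sphere_vois, "voi")) sphere_vois <- list(sphere_vois)
  means <- vapply(sphere_vois, function(v) mean_in_voi(img, v), numeric(1))
  data.frame(label = vapply(sphere_vois, function(v)
               if (is.null(v$label)) "" else v$label, ""),
             volume_ml = vapply(sphere_vois, `[[`, numeric(1), "volume_ml"),
             mean_conc = unname(means),
             rc = unname(means) / true_fg_conc,
             row.names = NULL)
}

#' Signal-to-noise ratio of a sphere against pooled background VOIs
#'
#' `SNR = (mean_sphere - mean_bkg) / SD_bkg`, where `mean_bkg` and `SD_bkg`
#' are the mean and population standard deviation over the voxels of all
#' background VOIs pooled. The background-subtracted numerator is a
#' documented choice (the alternative `mean_sphere / SD_bkg` is available via
#' `subtract_background = FALSE` for sensitivity analysis).
#'
#' @param img measured [image3d].
#' @param sphere_voi the sphere VOI.
#' @param background_vois list of at least two background VOIs.
#' @param subtract_background subtract the background mean in the numerator
#'   (default TRUE).
#' @return SNR as a scalar.
#' @export
compute_snr <- function(img, sphere_voi, background_vois,
                        subtract_background = TRUE) {
  if (inherits(background_vois, "voi")) background_vois <- list(background_vois)
  if (length(background_vois) < 2)
    stop("need at least two background VOIs")
  pooled <- unlist(lapply(background_vois, function(v)
    img$values[voi_mask(v)]))
  mb <- mean(pooled)
  sb <- sqrt(mean((pooled - mb)^2))
  if (sb == 0) stop("undefined-SNR error: zero background standard deviation")
  ms <- mean_in_voi(img, sphere_voi)
  if (subtract_background) (ms - mb) / sb else ms / sb
}

#' RC and SNR table for a set of spheres
#'
#' Convenience wrapper producing one row per sphere with both the recovery
#' coefficient and the SNR, mirroring a phantom results table.
#'
#' @inheritParams compute_rc
#' @inheritParams compute_snr
#' @param bkg_vois list of background VOIs.
#' @return A data.frame with columns `label`, `volume_ml`, `mean_conc`, `rc`,
#'   `snr`.
#' @export
rc_snr_table <- function(img, sphere_vois, bkg_vois, true_fg_conc) {
  tab <- compute_rc(img, sphere_vois, true_fg_conc)
  tab$snr <- vapply(sphere_vois, function(v)
    compute_snr(img, v, bkg_vois), numeric(1))
  tab
}

#' Volume-dependent recovery model f_RC(V) = 1 - (1 + (V/b)^y)^-1
#'
#' Least-squares fit of the two-parameter sigmoidal recovery curve to
#' measured (volume, RC) pairs, with positivity bounds on both parameters.
#' For b, y > 0 the curve rises strictly with volume from 0 toward 1 (slowly:
#' full recovery is approached only at very large volumes) and passes through
#' 0.5 exactly at V = b.
#'
#' @param volumes_ml sphere volumes in mL (> 0, at least 3).
#' @param rcs measured recovery coefficients (0 < rc <= 1.2).
#' @return An object of class `rc_curve` with elements `b`, `y`, `residuals`,
#'   `fitted`, `data`.
#' @export
fit_rc_curve <- function(volumes_ml, rcs) {
  if (length(volumes_ml) < 3 || length(rcs) != length(volumes_ml))
    stop("need at least 3 (volume, rc) pairs")
  if (any(volumes_ml <= 0)) stop("volumes must be > 0")
  if (any(rcs <= 0 | rcs > 1.2)) stop("rcs must lie in (0, 1.2]")
  df <- data.frame(V = volumes_ml, rc = rcs)
  fit <- tryCatch(
    nls(rc ~ 1 - 1 / (1 + (V / b)^y), data = df,
        start = list(b = median(volumes_ml), y = 1),
        lower = c(b = 1e-8, y = 1e-8), algorithm = "port",
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("fit error: recovery-curve fit did not converge (",
                             conditionMessage(e), ")"))
  co <- coef(fit)
  structure(list(b = unname(co["b"]), y = unname(co["y"]),
                 residuals = unname(residuals(fit)),
                 fitted = unname(fitted(fit)), data = df),
            class = "rc_curve")
}

#' @export
print.rc_curve <- function(x, ...) {
  cat(sprintf("recovery curve f_RC(V) = 1 - (1 + (V/b)^y)^-1: b = %.4g mL, y = %.4g\n",
              x$b, x$y))
  invisible(x)
}

#' Evaluate the fitted recovery curve
#'
#' @param curve an `rc_curve` (or a list with `b` and `y`).
#' @param volume_ml volume(s) in mL, > 0.
#' @return f_RC(volume), in (0, 1).
#' @export
predict_rc <- function(curve, volume_ml) {
  if (any(volume_ml <= 0)) stop("volume must be > 0")
  1 - 1 / (1 + (volume_ml / curve$b)^curve$y)
}

#' Volume-derived recovery correction factor
#'
#' `1 / f_RC(V)`: the multiplicative correction applied to an uncorrected
#' measurement (or absorbed dose) of a lesion of volume V. Monotone
#' decreasing in volume; large for small lesions.
#'
#' @inheritParams predict_rc
#' @return The correction factor (>= 1 for volumes where f_RC <= 1).
#' @export
rc_correction_factor <- function(curve, volume_ml) {
  f <- predict_rc(curve, volume_ml)
  if (any(f <= 0)) stop("recovery curve evaluates to <= 0")
  1 / f
}
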