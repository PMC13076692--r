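#' Acquisition-noise model for the synthetic forward projection
#'
#' The scanner and iterative reconstruction are replaced by an image-space
#' surrogate: a scalar calibration converts activity concentration into
#' expected counts per voxel, Poisson counts are drawn, converted back, and
#' the Gaussian system blur is applied. The default order
#' (`"poisson-then-blur"`) draws counts on the unblurred grid and then
#' smooths, producing spatially correlated noise as in reconstructed SPECT.
#' The default calibration (0.003 counts per kBq/mL per voxel) yields a
#' background coefficient of variation of roughly 0.36 on the reference
#' configuration (sigma 6 mm, 4.8 mm voxels, 30 kBq/mL background), inside
#' the 0.3-0.5 range implied by measured phantom signal-to-noise ratios.
#'
#' @param counts_per_kBqmL_per_voxel calibration scalar, > 0.
#' @param seed optional RNG seed; a fixed seed makes the simulation
#'   bit-reproducible.
#' @param order `"poisson-then-blur"` or `"blur-then-poisson"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(counts_per_kBqmL_per_voxel = 0.003, seed = NULL,
                        order = c("poisson-then-blur", "blur-then-poisson")) {
  if (counts_per_kBqmL_per_voxel <= 0) stop("calibration must be > 0")
  structure(list(calibration = counts_per_kBqmL_per_voxel, seed = seed,
                 order = match.arg(order)),
            class = "noise_model")
}

#' Simulate a reconstructed SPECT volume from ground truth
#'
#' Image-space forward model standing in for acquisition plus quantitative
#' reconstruction: Gaussian blur at the system PSF, optionally composed with
#' the Poisson [noise_model]. Units (kBq/mL) are preserved; with
#' `noise = NULL` and `sigma = 0` the output equals the truth.
#'
#' @param truth ground-truth activity concentration, an [image3d].
#' @param psf a [psf_model] (or single sigma in mm).
#' @param noise a [noise_model], or `NULL` for a noiseless reconstruction.
#' @return The pseudo-reconstructed `image3d`.
#' @export
simulate_reconstruction <- function(truth, psf, noise = NULL) {
  stopifnot(inherits(truth, "image3d"))
  if (is.numeric(psf)) psf <- psf_model(psf)
  if (is.null(noise)) return(gaussian_blur(truth, psf))
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  cal <- noise$calibration
  draw <- function(img) {
    counts <- rpois(length(img$values), img$values * cal)
    image3d(array(counts / cal, dim(img)), img$spacing_mm, img$units)
  }
  if (noise$order == "poisson-then-blur") gaussian_blur(draw(truth), psf)
  else draw(gaussian_blur(truth, psf))
}
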