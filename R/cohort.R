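#' Synthetic patient cohort specification
#'
#' Declarative description of a cohort of virtual patients with spherical
#' lesions of known monoexponential kinetics inside an elliptical-cylinder
#' body compartment, imaged at fixed times post-injection. Defaults emulate a
#' radioligand-therapy dosimetry cohort: lesion volumes log-normal with
#' median 4 mL (most lesions a few mL, occasional tens of mL), mean
#' tumor-to-background ratio 9.2 (defined at the first imaging time), imaging
#' at 24, 48 and 72 h, lesion effective half-lives around 60 h (bounded above
#' by the 160.8 h physical half-life), background washout with a 50 h
#' effective half-life from 30 kBq/mL at t = 0, and injected activity around
#' 7308 MBq.
#'
#' @param n_patients number of virtual patients.
#' @param lesions_per_patient integer range (min, max), sampled uniformly.
#' @param volume_meanlog,volume_sdlog log-normal lesion-volume parameters
#'   (mL scale).
#' @param volume_range_ml hard truncation bounds on sampled volumes.
#' @param tbr_mean,tbr_sd lesion tumor-to-background ratio (normal, truncated
#'   at `tbr_min`), defined at the first timepoint.
#' @param tbr_min lower truncation for sampled TBRs.
#' @param lesion_teff_mean_h,lesion_teff_sd_h lesion effective half-life
#'   (normal, truncated to `[24, 160.8]` h so effective decay is at least
#'   physical).
#' @param bkg_conc_t0 background concentration at t = 0 (kBq/mL).
#' @param bkg_teff_h background effective half-life (h).
#' @param timepoints_h strictly increasing imaging times (>= 3 by default
#'   study design).
#' @param injected_mean_MBq,injected_sd_MBq injected activity distribution.
#' @param body_semiaxes_mm,body_height_mm body compartment geometry.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 10,
                        lesions_per_patient = c(1, 8),
                        volume_meanlog = log(4), volume_sdlog = 1.0,
                        volume_range_ml = c(0.5, 80),
                        tbr_mean = 9.2, tbr_sd = 3.0, tbr_min = 2.0,
                        lesion_teff_mean_h = 60, lesion_teff_sd_h = 15,
                        bkg_conc_t0 = 30, bkg_teff_h = 50,
                        timepoints_h = c(24, 48, 72),
                        injected_mean_MBq = 7308, injected_sd_MBq = 132,
                        body_semiaxes_mm = c(110, 90),
                        body_height_mm = 180) {
  if (n_patients < 0) stop("`n_patients` must be >= 0")
  if (length(timepoints_h) < 2 || any(diff(timepoints_h) <= 0))
    stop("`timepoints_h` must be strictly increasing")
  structure(as.list(environment()), class = "cohort_spec")
}

# sample from a truncated normal by rejection (bounded retries)
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- min(max(x, lo), hi)
  }
  out
}

#' Simulate a synthetic patient cohort
#'
#' Generates, for each virtual patient, non-overlapping spherical lesions in
#' the body compartment, paints per-timepoint ground-truth activity images
#' (each voxel follows its configured monoexponential exactly; lesions are
#' painted voxel-aligned on their hard masks so measured means match the
#' configured kinetics exactly on noiseless unblurred data), and produces
#' observed images through [simulate_reconstruction]. All ground truth is
#' retained for recovery tests.
#'
#' @param spec a [cohort_spec].
#' @param psf a [psf_model] (or sigma in mm) for the forward blur.
#' @param noise a [noise_model] or `NULL` (noiseless).
#' @param seed RNG seed; fixed seed gives bit-reproducible cohorts.
#' @param grid an [image3d] template for the patient volumes.
#' @return A list of per-patient studies, each a list with `truth` and
#'   `observed` (lists of [image3d] per timepoint), `lesions` (data.frame:
#'   `lesion_id`, `center_x/y/z_mm`, `radius_mm`, `volume_ml`, `tbr`,
#'   `A0_kBqmL`, `lambda_eff`), `lesion_masks` (list of logical arrays),
#'   `body_mask`, `injected_MBq`, `timepoints_h`.
#' @export
simulate_cohort <- function(spec, psf = psf_model(6.0), noise = NULL,
                            seed = 1L,
                            grid = image_grid(c(64L, 64L, 48L), 4.8)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.numeric(psf)) psf <- psf_model(psf)
  if (!is.null(noise)) noise$seed <- NULL  # all randomness flows from `seed`
  set.seed(seed)
  ref <- image3d(grid$values * 0, grid$spacing_mm, "kBq/mL")
  ctr <- grid_center_mm(ref)
  lambda_bkg <- log(2) / spec$bkg_teff_h
  t1 <- spec$timepoints_h[1]

  body_spec <- nema_phantom_spec(sphere_diameters_mm = 10,
                                 sphere_centers_mm = list(c(0, 0, 0)),
                                 body_semiaxes_mm = spec$body_semiaxes_mm,
                                 body_height_mm = spec$body_height_mm,
                                 fg_conc = spec$bkg_conc_t0,
                                 bg_conc = spec$bkg_conc_t0)
  body_mask <- body_occupancy(body_spec, ref, supersampling = 1L) >= 0.5

  lapply(seq_len(spec$n_patients), function(p) {
    rng <- spec$lesions_per_patient
    nles <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    vols <- pmin(pmax(rlnorm(nles, spec$volume_meanlog, spec$volume_sdlog),
                      spec$volume_range_ml[1]), spec$volume_range_ml[2])
    radii <- (3 * vols * 1000 / (4 * pi))^(1 / 3)
    tbrs <- rtruncnorm1(nles, spec$tbr_mean, spec$tbr_sd, lo = spec$tbr_min)
    teff <- rtruncnorm1(nles, spec$lesion_teff_mean_h, spec$lesion_teff_sd_h,
                        lo = 24, hi = LU177_HALF_LIFE_H)
    lambda_les <- log(2) / teff

    # rejection placement, non-overlapping, inside the body with margin
    centers <- vector("list", nles)
    a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
    hz <- spec$body_height_mm / 2
    for (i in seq_len(nles)) {
      placed <- FALSE
      for (try in 1:2000) {
        cand <- c(runif(1, -a, a), runif(1, -b, b),
                  runif(1, -(hz - radii[i] - 5), hz - radii[i] - 5))
        margin <- radii[i] + 5
        if ((cand[1] / (a - margin))^2 + (cand[2] / (b - margin))^2 > 1) next
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          gap <- radii[i] + radii[j] + 5
          if (sum((cand - centers[[j]])^2) < gap^2) { ok <- FALSE; break }
        }
        if (ok) { centers[[i]] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("generation error: could not place lesions without overlap")
    }

    masks <- lapply(seq_len(nles), function(i) {
      v <- rasterize_sphere(ctr + centers[[i]], radii[i], ref,
                            supersampling = 2L,
                            label = sprintf("lesion%d", i))
      m <- v$mask
      if (!any(m)) m <- v$frac == max(v$frac)  # sub-voxel lesion: seed voxel
      m
    })

    # lesion concentration at t1 = TBR * background(t1); A0 extrapolated to 0
    bkg_t1 <- spec$bkg_conc_t0 * exp(-lambda_bkg * t1)
    conc_t1 <- tbrs * bkg_t1
    A0 <- conc_t1 * exp(lambda_les * t1)

    truth <- lapply(spec$timepoints_h, function(t) {
      vals <- body_mask * (spec$bkg_conc_t0 * exp(-lambda_bkg * t))
      for (i in seq_len(nles))
        vals[masks[[i]]] <- A0[i] * exp(-lambda_les[i] * t)
      image3d(vals, ref$spacing_mm, "kBq/mL")
    })
    observed <- lapply(truth, function(tr)
      simulate_reconstruction(tr, psf, noise))

    lesions <- data.frame(
      lesion_id = seq_len(nles),
      center_x_mm = vapply(centers, `[[`, 0, 1) + ctr[1],
      center_y_mm = vapply(centers, `[[`, 0, 2) + ctr[2],
      center_z_mm = vapply(centers, `[[`, 0, 3) + ctr[3],
      radius_mm = radii,
      volume_ml = vapply(masks, sum, 0L) * voxel_volume_ml(ref),
      tbr = tbrs, A0_kBqmL = A0, lambda_eff = lambda_les)

    list(patient_id = p, truth = truth, observed = observed,
         lesions = lesions, lesion_masks = masks, body_mask = body_mask,
         injected_MBq = rnorm(1, spec$injected_mean_MBq, spec$injected_sd_MBq),
         timepoints_h = spec$timepoints_h)
  })
}
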