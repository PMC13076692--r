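small_grid <- function() image_grid(c(48L, 48L, 40L), 4.8)

test_that("cohort generation is bit-reproducible given a seed", {
  spec <- cohort_spec(n_patients = 2)
  a <- simulate_cohort(spec, psf = 6, noise = noise_model(), seed = 21,
                       grid = small_grid())
  b <- simulate_cohort(spec, psf = 6, noise = noise_model(), seed = 21,
                       grid = small_grid())
  expect_identical(a[[1]]$observed[[2]]$values, b[[1]]$observed[[2]]$values)
  expect_identical(a[[2]]$lesions, b[[2]]$lesions)
})

test_that("zero lesions leave only the blurred noisy background", {
  spec <- cohort_spec(n_patients = 1, lesions_per_patient = c(0, 0))
  st <- simulate_cohort(spec, psf = 6, noise = noise_model(), seed = 3,
                        grid = small_grid())[[1]]
  expect_identical(nrow(st$lesions), 0L)
  # truth is pure background: constant inside the body at each timepoint
  for (k in seq_along(st$truth)) {
    vals <- st$truth[[k]]$values[st$body_mask]
    expect_equal(max(vals) - min(vals), 0)
    expect_equal(unique(vals), 30 * exp(-log(2) / 50 * st$timepoints_h[k]))
  }
})

test_that("lesion kinetics follow the configured monoexponential exactly", {
  spec <- cohort_spec(n_patients = 1, lesions_per_patient = c(2, 2),
                      lesion_teff_mean_h = 24, lesion_teff_sd_h = 1e-9)
  st <- simulate_cohort(spec, psf = 0, noise = NULL, seed = 4,
                        grid = small_grid())[[1]]
  # effective half-life pinned at 24 h: activity halves between 24 and 48 h
  for (i in seq_len(nrow(st$lesions))) {
    m <- st$lesion_masks[[i]]
    m24 <- mean(st$truth[[1]]$values[m])
    m48 <- mean(st$truth[[2]]$values[m])
    expect_equal(m48 / m24, 0.5, tolerance = 1e-9)
    # painted value matches the stored A0 * exp(-lambda t) exactly
    expect_equal(m24, st$lesions$A0_kBqmL[i] * exp(-st$lesions$lambda_eff[i] * 24),
                 tolerance = 1e-12)
  }
})

test_that("configured TBR is realized on noiseless unblurred images", {
  spec <- cohort_spec(n_patients = 1, lesions_per_patient = c(1, 1),
                      volume_meanlog = log(15), volume_sdlog = 1e-9)
  st <- simulate_cohort(spec, psf = 0, noise = NULL, seed = 8,
                        grid = small_grid())[[1]]
  les <- segment_lesion(st$observed[[1]],
                        unlist(st$lesions[1, c("center_x_mm", "center_y_mm",
                                               "center_z_mm")]),
                        "fraction", 0.5)
  tbr <- measure_tbr(st$observed[[1]], les, body_mask = st$body_mask)
  expect_equal(tbr, st$lesions$tbr[1], tolerance = 1e-9)
})

test_that("sampled lesion TBRs average to the configured mean (100 lesions)", {
  spec <- cohort_spec(n_patients = 13, lesions_per_patient = c(8, 8),
                      tbr_mean = 9.2, tbr_sd = 3, tbr_min = 2)
  studies <- simulate_cohort(spec, psf = 0, noise = NULL, seed = 15,
                             grid = image_grid(c(56L, 56L, 48L), 4.8))
  tbrs <- unlist(lapply(studies, function(s) s$lesions$tbr))
  expect_gte(length(tbrs), 100)
  # truncation at 2 barely shifts the mean for these parameters
  se <- sd(tbrs) / sqrt(length(tbrs))
  expect_lt(abs(mean(tbrs) - 9.2), 3 * se + 0.05)
})

test_that("effective decay never exceeds physical decay in speed bounds", {
  spec <- cohort_spec(n_patients = 3)
  studies <- simulate_cohort(spec, psf = 0, noise = NULL, seed = 5,
                             grid = small_grid())
  lam <- unlist(lapply(studies, function(s) s$lesions$lambda_eff))
  expect_true(all(lam >= log(2) / (6.7 * 24) - 1e-12))
  expect_true(all(lam <= log(2) / 24 + 1e-12))
})
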