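mk_series <- function(vals_by_t, dims = c(3, 3, 3), sp = 4.8) {
  lapply(vals_by_t, function(v) image3d(array(v, dims), sp, "kBq/mL"))
}

test_that("TAC fit reproduces an exact halving series in closed form", {
  f <- fit_tac(mk_series(c(100, 50, 25)), c(24, 48, 72))
  expect_equal(unique(as.vector(f$lambda)), log(2) / 24, tolerance = 1e-12)
  expect_equal(unique(as.vector(f$A0)), 200, tolerance = 1e-9)
  expect_true(all(f$flag == 0L))
})

test_that("non-decaying voxels fall back to the physical decay floor", {
  f <- fit_tac(mk_series(c(40, 40, 40)), c(24, 48, 72))
  lam_phys <- log(2) / (6.7 * 24)
  expect_equal(unique(as.vector(f$lambda)), lam_phys, tolerance = 1e-12)
  expect_true(all(f$flag == 1L))
  # floor-constrained refit: A0 = exp(mean(log c + lambda*t))
  expect_equal(unique(as.vector(f$A0)), exp(mean(log(40) + lam_phys * c(24, 48, 72))),
               tolerance = 1e-9)
})

test_that("voxels with fewer than two positive samples are excluded with zero TIA", {
  s <- mk_series(c(1, 1, 1), dims = c(2, 2, 2))
  s[[1]]$values[1] <- 0; s[[2]]$values[1] <- 0
  f <- fit_tac(s, c(24, 48, 72))
  expect_identical(f$flag[1], 2L)
  tia <- integrate_tia(f)
  expect_identical(tia$values[1], 0)
  expect_true(all(tia$values[-1] > 0))
})

test_that("noisy exponentials recover the decay constant within 5% (median)", {
  set.seed(12)
  lam_true <- log(2) / 40
  reps <- 100
  lams <- replicate(reps, {
    t <- c(24, 48, 72)
    v <- 100 * exp(-lam_true * t) * exp(rnorm(3, 0, 0.05))
    f <- fit_tac(mk_series(as.list(v), dims = c(1, 1, 1)), t)
    f$lambda[1]
  })
  expect_lt(abs(median(lams) - lam_true) / lam_true, 0.05)
})

test_that("TIA follows the analytic integral and scales linearly", {
  f <- fit_tac(mk_series(c(100, 50, 25)), c(24, 48, 72))
  tia <- integrate_tia(f)
  vv <- voxel_volume_ml(c(4.8, 4.8, 4.8))
  expect_equal(unique(as.vector(tia$values)), 200 * 1000 * vv / (log(2) / 24),
               tolerance = 1e-9)
  expect_identical(tia$units, "Bq.h_per_voxel")
  # doubling A0 doubles TIA; doubling lambda halves it
  f2 <- fit_tac(mk_series(c(200, 100, 50)), c(24, 48, 72))
  expect_equal(integrate_tia(f2)$values, 2 * tia$values, tolerance = 1e-9)
  # same A0 = 200, twice the decay rate (lambda = ln2/12) -> half the TIA
  f3 <- fit_tac(mk_series(200 * exp(-log(2) / 12 * c(24, 48, 72))), c(24, 48, 72))
  expect_equal(integrate_tia(f3)$values, tia$values / 2, tolerance = 1e-9)
})

test_that("dose convolution matches the direct-sum oracle and is linear", {
  set.seed(13)
  tia_a <- array(runif(16^3), c(16, 16, 16))
  k <- array(runif(27), c(3, 3, 3))
  k <- (k + k[3:1, , ]) / 2; k <- (k + k[, 3:1, ]) / 2; k <- (k + k[, , 3:1]) / 2
  kern <- dose_kernel(k, 4.8)
  tia <- image3d(tia_a, 4.8, "Bq.h_per_voxel")
  dose <- convolve_dose(tia, kern)
  expect_identical(dose$units, "Gy")
  expect_equal(dose$values, brute_conv3(tia_a, k), tolerance = 1e-10)

  tia_b <- image3d(array(runif(16^3), c(16, 16, 16)), 4.8, "Bq.h_per_voxel")
  mix <- image3d(2 * tia$values + 3 * tia_b$values, 4.8, "Bq.h_per_voxel")
  expect_equal(convolve_dose(mix, kern)$values,
               2 * dose$values + 3 * convolve_dose(tia_b, kern)$values,
               tolerance = 1e-9)
  expect_error(convolve_dose(image3d(tia_a, 4.0, "Bq.h_per_voxel"), kern),
               "geometry")
})

test_that("single-voxel kernel: dose is sT; uniform TIA gives uniform interior dose", {
  kern <- dose_kernel(array(2.5, c(1, 1, 1)), 4.8)
  tia <- image3d(array(0, c(8, 8, 8)), 4.8, "Bq.h_per_voxel")
  tia$values[4, 4, 4] <- 7
  dose <- convolve_dose(tia, kern)
  expect_equal(dose$values[4, 4, 4], 17.5)
  expect_equal(sum(dose$values > 0), 1L)

  u <- image3d(array(3, c(8, 8, 8)), 4.8, "Bq.h_per_voxel")
  du <- convolve_dose(u, kern)
  expect_true(all(du$values == 7.5))
})

test_that("the local-deposition kernel scales with voxel mass and round-trips CSV", {
  k1 <- default_lu177_kernel(4.8)
  k2 <- default_lu177_kernel(4.8 / 2^(1 / 3))  # half the voxel volume
  expect_equal(k2$values[1] / k1$values[1], 2, tolerance = 1e-9)
  # dimensional check: E[J/decay] * 3600[decay/(Bq h)] / m[kg]
  m_kg <- 4.8^3 / 1e6
  expect_equal(k1$values[1], 147.9e3 * 1.602176634e-19 * 3600 / m_kg,
               tolerance = 1e-12)

  p <- file.path(tempdir(), "kern.csv")
  k <- array(c(rep(0.1, 13), 5, rep(0.1, 13)), c(3, 3, 3))
  kern <- dose_kernel(k, c(4.8, 4.8, 2.4))
  write_dose_kernel(kern, p)
  back <- read_dose_kernel(p)
  expect_identical(back$values, kern$values)
  expect_identical(back$spacing_mm, kern$spacing_mm)
})

test_that("kernel validation enforces shape, sign, and symmetry", {
  expect_error(dose_kernel(array(1, c(2, 2, 2)), 4.8), "odd")
  expect_error(dose_kernel(array(-1, c(1, 1, 1)), 4.8), ">= 0")
  bad <- array(0.1, c(3, 3, 3)); bad[1, 1, 1] <- 2; bad[2, 2, 2] <- 1
  expect_error(dose_kernel(bad, 4.8), "symmetric")
})

test_that("threshold segmentation recovers a noiseless sphere and honors contracts", {
  g <- image_grid(c(32, 32, 32), 4.8)
  ctr <- dim(g) * 4.8 / 2
  v <- rasterize_sphere(ctr, 12, g)
  img <- image3d(v$mask * 100 + 10, 4.8, "kBq/mL")
  seg <- segment_lesion(img, ctr, "fraction", 0.5)
  expect_identical(seg$mask, v$mask)
  expect_equal(seg$volume_ml, sum(v$mask) * voxel_volume_ml(g))

  seg_abs <- segment_lesion(img, ctr, "absolute", 50)
  expect_identical(seg_abs$mask, v$mask)
  expect_error(segment_lesion(img, ctr, "fraction", 1.01),
               "empty-segmentation")
})

test_that("segmentation keeps only the connected component under the seed", {
  g <- image_grid(c(32, 32, 32), 4.8)
  a <- array(0, dim(g))
  a[5:8, 5:8, 5:8] <- 100
  a[20:23, 20:23, 20:23] <- 100
  img <- image3d(a, 4.8, "kBq/mL")
  seg <- segment_lesion(img, c(6.5, 6.5, 6.5) * 4.8, "absolute", 50,
                        search_radius_mm = 10)
  expect_equal(sum(seg$mask), 64L)
  expect_true(all(which(seg$mask, arr.ind = TRUE) <= 8))
})

test_that("TBR is exact on noiseless data and scale invariant", {
  g <- image_grid(c(40, 40, 40), 4.8)
  ctr <- dim(g) * 4.8 / 2
  v <- rasterize_sphere(ctr, 10, g)
  img <- image3d(v$mask * (9.2 * 20 - 20) + 20, 4.8, "kBq/mL")
  les <- segment_lesion(img, ctr, "fraction", 0.5)
  expect_equal(measure_tbr(img, les), 9.2, tolerance = 1e-12)
  # lesion mean equal to background -> TBR 1
  flat <- image3d(array(20, dim(g)), 4.8, "kBq/mL")
  expect_equal(measure_tbr(flat, les), 1)
  # invariant under global scaling
  img2 <- image3d(img$values * 17, 4.8, "kBq/mL")
  expect_equal(measure_tbr(img2, les), measure_tbr(img, les), tolerance = 1e-12)
  # background copies must fit in the grid
  edge <- rasterize_sphere(c(7, 7, 7) * 4.8, 20, g)
  img3 <- image3d(edge$mask * 100 + 10, 4.8, "kBq/mL")
  les3 <- segment_lesion(img3, c(7, 7, 7) * 4.8, "fraction", 0.5)
  expect_error(measure_tbr(img3, les3), "placement")
})

test_that("compare_doses arithmetic and the RC arm are exact by construction", {
  g <- image_grid(c(16, 16, 16), 4.8)
  m <- array(FALSE, dim(g)); m[6:9, 6:9, 6:9] <- TRUE
  dose_or <- image3d(m * 100, 4.8, "Gy")
  dose_lrd <- image3d(m * 122, 4.8, "Gy")
  curve <- list(b = sum(m) * voxel_volume_ml(g), y = 1.3)  # lesion volume = b
  rep <- compare_doses(dose_or, dose_lrd, curve, list(mask_voi(m, g)),
                       injected_GBq = 2)
  expect_equal(rep$ad_or, 50)
  expect_equal(rep$ad_lrd, 61)
  expect_equal(rep$pct_lrd, 22)
  expect_equal(rep$ad_rc, 2 * rep$ad_or)  # f_RC(b) = 0.5
  expect_equal(rep$pct_rc, 100)

  same <- compare_doses(dose_or, dose_or, curve, list(mask_voi(m, g)), 2)
  expect_equal(same$pct_lrd, 0)
  empty <- compare_doses(dose_or, dose_lrd, curve, list(), 2)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("ad_or", "ad_lrd", "ad_rc", "pct_lrd", "pct_rc") %in%
                    names(empty)))
})
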