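test_that("unblurred noiseless phantom recovers RC = 1 in every sphere", {
  ph <- test_phantom(paint = "binary")
  tab <- compute_rc(ph$truth, ph$sphere_vois, 237)
  expect_true(all(abs(tab$rc - 1) < 0.005))
})

test_that("RCs increase strictly with sphere volume on the blurred phantom", {
  ph <- test_phantom()
  tab <- compute_rc(test_recon(6), ph$sphere_vois, 237)
  tab <- tab[order(tab$volume_ml), ]
  expect_true(all(diff(tab$rc) > 0))
})

test_that("spill-in: hot spheres in cold background recover less than at 8:1", {
  g <- compact_grid()
  cold <- generate_phantom(nema_phantom_spec(bg_conc = 0), g)
  warm <- test_phantom()
  rc_cold <- compute_rc(simulate_reconstruction(cold$truth, 6),
                        cold$sphere_vois, 237)$rc
  rc_warm <- compute_rc(test_recon(6), warm$sphere_vois, 237)$rc
  expect_true(all(rc_cold <= rc_warm + 1e-12))
})

test_that("SNR closed-form cases and ordering", {
  ph <- test_phantom()
  g <- ph$truth
  flat <- image3d(array(30, dim(g)), g$spacing_mm, "kBq/mL")
  # sphere mean equal to background mean (but noisy background) -> SNR 0
  perturbed <- flat
  bidx <- which(ph$background_vois[[1]]$mask)[1:2]
  perturbed$values[bidx] <- c(29, 31)
  expect_equal(compute_snr(perturbed, ph$sphere_vois[[1]], ph$background_vois),
               0, tolerance = 1e-12)

  noise <- flat
  set.seed(10)
  noise$values <- noise$values + array(rnorm(length(g$values)), dim(g))
  snr0 <- compute_snr(noise, ph$sphere_vois[[1]], ph$background_vois)
  # contrast doubling at fixed noise doubles the SNR
  boosted <- noise
  boosted$values[ph$sphere_vois[[1]]$mask] <-
    boosted$values[ph$sphere_vois[[1]]$mask] +
    (mean_in_voi(noise, ph$sphere_vois[[1]]) -
       mean(unlist(lapply(ph$background_vois, function(v) noise$values[v$mask]))))
  snr2 <- compute_snr(boosted, ph$sphere_vois[[1]], ph$background_vois)
  expect_equal(snr2, 2 * snr0, tolerance = 1e-9)

  # uniform background -> undefined SNR
  expect_error(compute_snr(flat, ph$sphere_vois[[1]], ph$background_vois),
               "undefined-SNR")
  expect_error(compute_snr(noise, ph$sphere_vois[[1]],
                           ph$background_vois[1]), "at least two")

  # noisy phantom: the largest sphere has higher SNR than the smallest visible
  rec <- test_recon_noisy(42)
  expect_gt(compute_snr(rec, ph$sphere_vois[["26.5 mL"]], ph$background_vois),
            compute_snr(rec, ph$sphere_vois[["2.6 mL"]], ph$background_vois))
})

test_that("recovery-curve fit recovers generating parameters and closed forms", {
  v <- c(1, 2, 5, 10, 25, 50)
  rc <- 1 - 1 / (1 + (v / 5)^1.5)
  curve <- fit_rc_curve(v, rc)
  expect_lt(abs(curve$b - 5), 1e-4)
  expect_lt(abs(curve$y - 1.5), 1e-4)
  # f_RC(b) = 0.5 for any y
  expect_equal(predict_rc(curve, curve$b), 0.5, tolerance = 1e-12)
  expect_equal(rc_correction_factor(curve, curve$b), 2, tolerance = 1e-12)
  # slow convergence toward full recovery at large volumes
  expect_lt(predict_rc(curve, 1e6), 1)
  expect_gt(predict_rc(curve, 1e6), 0.999)
})

test_that("the fit is scale-consistent in volume", {
  v <- c(1, 3, 8, 20, 40)
  rc <- 1 - 1 / (1 + (v / 6)^0.9)
  a <- fit_rc_curve(v, rc)
  b <- fit_rc_curve(10 * v, rc)
  expect_equal(b$b, 10 * a$b, tolerance = 1e-6)
  expect_equal(b$y, a$y, tolerance = 1e-6)
})

test_that("correction factors decrease monotonically with volume", {
  ph <- run_phantom_study(phantom_study_config(mfa_stop = 14.4, seed = 1))
  curve <- ph$rc_curve
  vols <- c(0.7, 2, 5, 20, 60)
  f <- rc_correction_factor(curve, vols)
  expect_true(all(diff(f) < 0))
  expect_gt(rc_correction_factor(curve, 2), rc_correction_factor(curve, 20))
})

test_that("fit inputs are validated", {
  expect_error(fit_rc_curve(c(1, 2), c(0.3, 0.5)), "at least 3")
  expect_error(fit_rc_curve(c(-1, 2, 3), c(0.3, 0.5, 0.6)), "> 0")
  expect_error(fit_rc_curve(c(1, 2, 3), c(0.3, 0.5, 1.5)), "\\(0, 1.2\\]")
})
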