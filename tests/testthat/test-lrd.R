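test_that("sigma 0 is a fixed point and n_iter 0 returns the input", {
  set.seed(8)
  img <- image3d(array(runif(10^3, 0.5, 2), c(10, 10, 10)), 4.8, "kBq/mL")
  for (n in c(0, 3))
    expect_equal(deconvolve(img, sigma_mm = 0, n_iter = n, init = "observed")$values,
                 img$values, tolerance = 1e-15)
  expect_identical(deconvolve(img, sigma_mm = 6, n_iter = 0)$values, img$values)
})

test_that("uniform-constant init, 1 iteration re-blurs the input (interior identity)", {
  rec <- test_recon_noisy(3)
  l1 <- deconvolve(rec, 6, 1, init = "uniform")
  rb <- gaussian_blur(rec, 6)
  d <- dim(rec$values)
  b <- 11  # two kernel half-widths (2 * 4 sigma = 48 mm) from the boundary
  core <- function(a) a[(b + 1):(d[1] - b), (b + 1):(d[2] - b), (b + 1):(d[3] - b)]
  expect_lt(max(abs(core(l1$values) - core(rb$values))) / max(rb$values), 1e-6)
})

test_that("non-negativity and total activity are preserved (observed init)", {
  rec <- test_recon_noisy(3)
  out <- deconvolve(rec, 6, 4, init = "observed")
  expect_true(all(out$values >= 0))
  expect_lt(abs(flux_report(rec, out)), 0.005)
  # per-iteration conservation
  cur <- rec
  for (k in 1:4) {
    nxt <- deconvolve(cur, 6, 1, init = "observed")
    expect_lt(abs(flux_report(cur, nxt)), 0.005)
    cur <- nxt
  }
})

test_that("uniform-constant init iteration 1 changes flux only by boundary loss", {
  rec <- test_recon_noisy(3)
  l1 <- deconvolve(rec, 6, 1, init = "uniform")
  expect_lt(abs(flux_report(rec, l1)), 0.005)
})

test_that("matched-PSF deconvolution restores the noiseless blurred phantom", {
  ph <- test_phantom()
  rec <- test_recon(6)
  base <- rmse_to(rec, ph$truth)
  # RMSE to ground truth is non-increasing over the first 10 iterations
  rs <- vapply(1:10, function(k)
    rmse_to(deconvolve(rec, 6, k, init = "observed"), ph$truth), numeric(1))
  expect_true(all(diff(rs) <= 1e-12))
  expect_lt(rs[10], base)
  # the uniform-constant path also improves on the input by 4 iterations
  expect_lt(rmse_to(deconvolve(rec, 6, 4, init = "uniform"), ph$truth), base)
})

test_that("the update matches the scikit-image reference implementation", {
  set.seed(5)
  a <- array(runif(32^3, 0.5, 1.5), c(32, 32, 32))
  img <- image3d(a, 4.8, "dimensionless")
  ours <- deconvolve(img, sigma_mm = 6, n_iter = 4, init = 0.5)
  k <- make_gaussian_kernel(psf_model(6), 4.8)
  td <- tempfile("rlref"); dir.create(td)
  write(as.vector(a), file.path(td, "img.txt"), ncolumns = 1)
  write(as.vector(k), file.path(td, "ker.txt"), ncolumns = 1)
  py <- c(
    "import numpy as np",
    "from skimage.restoration import richardson_lucy",
    sprintf("a = np.loadtxt(r'%s').reshape((32,32,32), order='F')",
            file.path(td, "img.txt")),
    sprintf("k = np.loadtxt(r'%s').reshape((%d,%d,%d), order='F')",
            file.path(td, "ker.txt"), dim(k)[1], dim(k)[2], dim(k)[3]),
    "out = richardson_lucy(a, k, num_iter=4, clip=False)",
    sprintf("np.savetxt(r'%s', out.ravel(order='F'))", file.path(td, "out.txt")))
  writeLines(py, file.path(td, "rl.py"))
  status <- system2("python", file.path(td, "rl.py"))
  expect_identical(status, 0L)
  ref <- array(scan(file.path(td, "out.txt"), quiet = TRUE), c(32, 32, 32))
  expect_lt(max(abs(ours$values - ref)) / max(abs(ref)), 1e-5)
})

test_that("degenerate inputs are handled per contract", {
  z <- image3d(array(0, c(6, 6, 6)), 4.8, "kBq/mL")
  expect_warning(out <- deconvolve(z, 6, 2), "all-zero")
  expect_identical(out$values, z$values)
  neg <- image3d(array(c(-1, rep(1, 215)), c(6, 6, 6)), 4.8, "dimensionless")
  expect_warning(deconvolve(neg, 2, 1), "clipped 1 negative")
  expect_error(deconvolve(test_recon(6), -1, 1), "domain")
})

test_that("iteration_sweep rows reproduce single-shot deconvolution", {
  ph <- test_phantom()
  rec <- test_recon_noisy(3)
  sw <- iteration_sweep(rec, 6, 3, ph$sphere_vois[1:4], ph$background_vois, 237)
  expect_identical(nrow(sw), 12L)  # 3 iterations x 4 spheres
  d3 <- deconvolve(rec, 6, 3, init = "uniform")
  tab3 <- rc_snr_table(d3, ph$sphere_vois[1:4], ph$background_vois, 237)
  expect_equal(sw$rc[sw$iteration == 3], tab3$rc, tolerance = 1e-12)
  sw1 <- iteration_sweep(rec, 6, 1, ph$sphere_vois[1:4], ph$background_vois, 237)
  expect_identical(unique(sw1$iteration), 1L)
})
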