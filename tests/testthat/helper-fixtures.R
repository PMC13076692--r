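# Shared fixtures, memoized so expensive objects are built once per session.
# The compact 56 x 48 x 48 grid at 4.8 mm holds the full phantom with >= 4
# sigma margins at the reference resolution.

.fx <- new.env(parent = emptyenv())

compact_grid <- function() image_grid(c(56L, 48L, 48L), 4.8)

test_phantom <- function(paint = "fractional") {
  key <- paste0("ph_", paint)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_phantom(nema_phantom_spec(), compact_grid(),
                                   paint = paint)
  .fx[[key]]
}

# noiseless pseudo-reconstruction at a given blur
test_recon <- function(sigma = 6.0) {
  key <- sprintf("rec_%g", sigma)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_reconstruction(test_phantom()$truth, sigma)
  .fx[[key]]
}

# noisy pseudo-reconstruction, fixed seed
test_recon_noisy <- function(seed = 42) {
  key <- sprintf("recn_%d", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_reconstruction(test_phantom()$truth, 6.0,
                                          noise_model(seed = seed))
  .fx[[key]]
}

# direct triple-loop 3D convolution (zero padding, "same" crop): the
# brute-force oracle for the FFT and separable paths
brute_conv3 <- function(x, k) {
  dx <- dim(x); dk <- dim(k); h <- (dk - 1) / 2
  out <- array(0, dx)
  for (i in seq_len(dx[1])) for (j in seq_len(dx[2])) for (l in seq_len(dx[3])) {
    acc <- 0
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (cc in seq_len(dk[3])) {
      ii <- i + h[1] - (a - 1); jj <- j + h[2] - (b - 1); ll <- l + h[3] - (cc - 1)
      if (ii >= 1 && ii <= dx[1] && jj >= 1 && jj <= dx[2] &&
          ll >= 1 && ll <= dx[3])
        acc <- acc + x[ii, jj, ll] * k[a, b, cc]
    }
    out[i, j, l] <- acc
  }
  out
}

rmse_to <- function(img, ref) sqrt(mean((img$values - ref$values)^2))
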