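test_that("single-coil SNR combination reduces to its closed form", {
  # S = 1, N = sigma^2, R = 1: output = sqrt(2) |I| / sigma
  set.seed(1)
  I <- array(complex(real = rnorm(64), imaginary = rnorm(64)), c(8, 8, 1))
  sigma <- 3
  out <- snr_combine(I, array(1 + 0i, c(8, 8, 1)),
                     matrix(sigma^2, 1, 1), undersampling_R = 1)
  expect_equal(out$pixels, sqrt(2) * Mod(I[, , 1]) / sigma, tolerance = 1e-12)
  # R enters as sqrt(2/R)
  out4 <- snr_combine(I, array(1 + 0i, c(8, 8, 1)), matrix(sigma^2, 1, 1),
                      undersampling_R = 4)
  expect_equal(out4$pixels, out$pixels / 2, tolerance = 1e-12)
})

test_that("SNR combination is invariant to global sensitivity scaling", {
  set.seed(2)
  nc <- 4
  I <- array(complex(real = rnorm(9 * 9 * nc), imaginary = rnorm(9 * 9 * nc)),
             c(9, 9, nc))
  S <- array(complex(real = rnorm(9 * 9 * nc), imaginary = rnorm(9 * 9 * nc)),
             c(9, 9, nc))
  A <- matrix(rnorm(nc^2), nc); ncov <- crossprod(A) + diag(nc)
  ref <- snr_combine(I, S, ncov)
  for (a in c(0.01, 3.7, 1200)) {
    sc <- snr_combine(I, a * S, ncov)
    expect_equal(sc$pixels, ref$pixels, tolerance = 1e-12)
  }
  expect_error(snr_combine(I, S, matrix(0, nc, nc)), "singular")
  # all-zero-sensitivity voxels are zeroed and flagged
  S0 <- S; S0[1, 1, ] <- 0
  z <- snr_combine(I, S0, ncov)
  expect_equal(z$pixels[1, 1], 0)
  expect_true(z$flagged[1, 1])
})

test_that("combination equals the whitened matched-filter oracle", {
  set.seed(3)
  nc <- 3
  I <- array(complex(real = rnorm(49 * nc), imaginary = rnorm(49 * nc)),
             c(7, 7, nc))
  S <- array(complex(real = rnorm(49 * nc), imaginary = rnorm(49 * nc)),
             c(7, 7, nc))
  A <- matrix(rnorm(nc^2), nc); ncov <- crossprod(A) + 0.5 * diag(nc)
  # oracle: whiten channels by ncov^(-1/2), then matched-filter combine
  ev <- eigen(ncov, symmetric = TRUE)
  W <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Im <- matrix(I, ncol = nc) %*% W
  Sm <- matrix(S, ncol = nc) %*% W
  oracle <- sqrt(2) * Mod(rowSums(Conj(Sm) * Im)) / sqrt(rowSums(Mod(Sm)^2))
  out <- snr_combine(I, S, ncov)
  expect_equal(as.vector(out$pixels), oracle, tolerance = 1e-10)
})

test_that("noise-only reconstructions have unit SNR per component", {
  # pseudo-replica: the complex combined estimate of pure noise has unit
  # standard deviation in each of its real and imaginary parts
  set.seed(4)
  nc <- 3
  n <- 120                      # 120^2 = 14400 pixels here; more in scripts
  A <- matrix(rnorm(nc^2), nc); ncov <- crossprod(A) + diag(nc)
  ev <- eigen(ncov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  noise <- matrix(complex(real = rnorm(n * n * nc),
                          imaginary = rnorm(n * n * nc)) / sqrt(2),
                  ncol = nc) %*% t(L)
  I <- array(noise, c(n, n, nc))
  S <- array(complex(real = rnorm(n * n * nc), imaginary = rnorm(n * n * nc)),
             c(n, n, nc))
  est <- snr_combine(I, S, ncov, complex_out = TRUE)$pixels
  expect_equal(stats::sd(Re(est)), 1, tolerance = 0.03)
  expect_equal(stats::sd(Im(est)), 1, tolerance = 0.03)
})

test_that("Fermi filter is near-unity at the centre and radially monotone", {
  # acquisition-scale grid (512 samples): centre gain within 1e-3 of 1 for
  # the default cutoff and exponent denominator 8
  k <- matrix(1 + 0i, 512, 512)
  f <- Mod(fermi_filter(k))
  expect_equal(f[257, 257], 1, tolerance = 1e-3)
  # monotone non-increasing along a radius
  prof <- f[257, 257:512]
  expect_true(all(diff(prof) <= 1e-12))
  # w -> 0 approaches an ideal circular low-pass
  k2 <- matrix(1 + 0i, 64, 64)
  fs <- Mod(fermi_filter(k2, radius_frac = 0.5, exponent_denominator = 1e-6))
  expect_true(all(fs < 1e-12 | abs(fs - 1) < 1e-12 | abs(fs - 0.5) < 1e-12))
  expect_error(fermi_filter(k2, radius_frac = 0), "radius_frac")
})

test_that("zero-padded reconstruction conserves values and round-trips", {
  set.seed(5)
  img <- matrix(rnorm(32 * 32), 32)
  k <- vwisim:::ft2(img)
  # factor 1: plain inverse FFT recovers the image exactly
  expect_equal(Re(zero_pad_recon(k, 1)), img, tolerance = 1e-10)
  # pure-DC k-space: constant image of unchanged value under any factor
  kdc <- matrix(0i, 16, 16); kdc[9, 9] <- 256 + 0i
  r1 <- zero_pad_recon(kdc, 1); r2 <- zero_pad_recon(kdc, 2)
  expect_equal(Re(r1), matrix(1, 16, 16), tolerance = 1e-12)
  expect_equal(Re(r2), matrix(1, 32, 32), tolerance = 1e-12)
  # factor 2 interpolates: original sample positions keep their values
  r2img <- zero_pad_recon(k, 2)
  expect_equal(Re(r2img[seq(1, 64, by = 2), seq(1, 64, by = 2)]), img,
               tolerance = 1e-9)
})

test_that("the full synthetic reconstruction recovers the phantom shape", {
  s <- signal_set(0.15, 0.03, 0.01)
  ph <- make_phantom(s, n_pix = 32, noise_sd = 0)
  cd <- make_coil_data(ph, 3, 0.25 * diag(3), seed = 6)
  rec <- reconstruct_snr(cd, pad = 2, fermi = TRUE)
  expect_equal(dim(rec$pixels), c(64, 64))
  expect_true(all(rec$pixels >= 0), all(is.finite(rec$pixels)))
  # wall is brighter than lumen in the reconstruction, as in the phantom
  ctr <- 32.5
  wall_px <- rec$pixels[round(ctr - ph$r_outer_mm / ph$pixel_mm * 2 * 0.85),
                        round(ctr)]
  lumen_px <- rec$pixels[round(ctr), round(ctr)]
  expect_gt(wall_px, lumen_px)
})
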