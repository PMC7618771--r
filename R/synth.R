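#' Synthetic multi-channel B1+ map set
#'
#' Emulates a 7T multi-channel transmit field over a simple head-and-neck
#' grid: the upper part of the grid is the head (containing the Circle of
#' Willis ROI), the lower part the neck (containing the feeding-artery ROI).
#' Channel magnitudes are smooth Gaussians around transmit element positions
#' ringing the head; in the neck the channel phases are deliberately spread so
#' that the CP-mode (all-zero relative phase) combination suffers destructive
#' interference there, reproducing the reduced neck coverage of a head coil
#' in CP mode by the designed `neck_dropoff` factor, while the CoW channels
#' add nearly in phase. A phase-only shim can therefore realign the neck
#' channels and gain neck |B1| without penalizing the CoW.
#'
#' @param n_channels number of transmit channels, >= 2 (8 typical at 7T).
#' @param nx,ny grid size (head+neck, ny rows; the lower third is neck).
#' @param neck_dropoff designed CP-mode neck attenuation factor in (0, 1]:
#'   mean CP |B1| in the neck ROI is approximately `neck_dropoff` times the
#'   CoW mean.
#' @param seed integer seed (maps are deterministic given the seed).
#' @return An object of class `b1_map_set`: `channel_maps` (nx x ny x
#'   n_channels complex array), `roi_neck`, `roi_cow` (logical nx x ny masks,
#'   disjoint), `n_channels`.
#' @export
make_b1_maps <- function(n_channels = 8, nx = 32, ny = 48,
                         neck_dropoff = 0.5, seed = 1L) {
  stopifnot(n_channels >= 1, neck_dropoff > 0, neck_dropoff <= 1.2)
  set.seed(as.integer(seed))
  xg <- matrix(seq(-1, 1, length.out = nx), nx, ny)
  yg <- matrix(seq(-1, 1, length.out = ny), nx, ny, byrow = TRUE)
  # head centre at y = +0.4 (CoW), neck below y < -0.35
  maps <- array(0i, c(nx, ny, n_channels))
  ang <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  for (c in seq_len(n_channels)) {
    cx <- 0.8 * cos(ang[c]); cy <- 0.4 + 0.5 * sin(ang[c])
    mag <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * 0.55^2)) +
      0.15 * exp(-((xg - cx)^2 + (yg + 0.7)^2) / (2 * 0.6^2))
    # smooth phase: moderately misaligned in the head (so CP is close to but
    # not exactly the CoW optimum, leaving slack for the constrained shim),
    # strongly spread in the neck
    spread <- pmin(1, pmax(0, (-yg - 0.1) / 0.6))   # 0 in head, 1 deep in neck
    ph <- 0.35 * sin(ang[c] + 1.3 * xg + 0.8 * yg) * (1 - spread) +
      spread * (ang[c] - pi) * 0.9 +
      stats::runif(1, -0.05, 0.05)
    maps[, , c] <- mag * exp(1i * ph)
  }
  roi_cow <- (xg^2 + (yg - 0.4)^2) < 0.3^2
  roi_neck <- (abs(xg) < 0.35) & (yg > -0.9) & (yg < -0.45)
  obj <- structure(list(channel_maps = maps, roi_neck = roi_neck,
                        roi_cow = roi_cow, n_channels = n_channels),
                   class = "b1_map_set")
  # rescale amplitudes below the head so the designed CP dropoff holds
  # exactly over the neck ROI (the blend reaches 1 above the ROI's top edge)
  cp <- combine_b1(obj, rep(0, n_channels))
  target <- neck_dropoff * mean(cp[roi_cow])
  cur <- mean(cp[roi_neck])
  w <- 1 + (target / cur - 1) * pmin(1, pmax(0, (-yg - 0.1) / 0.35))
  for (c in seq_len(n_channels)) maps[, , c] <- maps[, , c] * w
  obj$channel_maps <- maps
  obj
}

#' @export
print.b1_map_set <- function(x, ...) {
  cp <- combine_b1(x, rep(0, x$n_channels))
  cat(sprintf("B1+ map set: %d channels, %d x %d grid; CP-mode neck/CoW ratio %.3f\n",
              x$n_channels, dim(x$channel_maps)[1], dim(x$channel_maps)[2],
              mean(cp[x$roi_neck]) / mean(cp[x$roi_cow])))
  invisible(x)
}

#' Synthetic annular vessel phantom
#'
#' A circular vessel cross-section on a Cartesian grid in SNR units:
#' lumen at the blood signal, wall annulus at the vessel wall signal, and a
#' surround that is CSF or brain tissue per 60-degree sector (outer vessel
#' contrast in vivo is wall-to-CSF in some directions and wall-to-tissue in
#' others). The piecewise-constant scene is blurred with a Gaussian PSF
#' (emulating Fermi-filtered reconstruction blur) and white Gaussian noise is
#' added. Signal fractions of M0 are mapped to SNR units by `snr_scale`.
#'
#' @param signals a `signal_set` (fractions of M0) for lumen/wall/surround.
#' @param r_inner_mm,r_outer_mm lumen and outer wall radii (mm).
#' @param pixel_mm pixel size (mm), <= 0.5.
#' @param n_pix image width/height in pixels.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum (mm); the
#'   default is 1.2 times the acquired 0.47 mm pixel (zero-pad interpolation
#'   to the 0.23 mm grid adds no resolution); 0 disables
#'   blurring (the image is then exactly piecewise constant).
#' @param noise_sd white-noise standard deviation in SNR units.
#' @param snr_scale SNR units corresponding to full M0 (default 100).
#' @param tissue_signal surround signal (fraction of M0) for the
#'   brain-tissue sectors; default midway between wall and CSF.
#' @param seed integer noise seed.
#' @return An object of class `vessel_phantom`: `image` (n_pix x n_pix),
#'   `pixel_mm`, `center` (pixel coordinates, 1-based), `r_inner_mm`,
#'   `r_outer_mm`, `truth_signals`, `psf_fwhm_mm`, `noise_sd`, `snr_scale`.
#' @export
make_phantom <- function(signals, r_inner_mm = 1.5, r_outer_mm = 2.25,
                         pixel_mm = 0.23, n_pix = 64, psf_fwhm_mm = 0.56,
                         noise_sd = 1, snr_scale = 100,
                         tissue_signal = NULL, seed = 1L) {
  stopifnot(r_outer_mm > r_inner_mm, r_inner_mm > 0, pixel_mm <= 0.5,
            pixel_mm > 0)
  if (is.null(tissue_signal)) tissue_signal <- (signals$vw + signals$csf) / 2
  ctr <- (n_pix + 1) / 2
  scene_at <- function(xs, ys) {
    # xs, ys in mm relative to the centre
    r <- sqrt(xs^2 + ys^2)
    th <- atan2(ys, xs) %% (2 * pi)
    sector <- floor(th / (pi / 3)) %% 2   # alternate CSF / tissue per 60 deg
    out <- ifelse(sector == 0, signals$csf, tissue_signal)
    out[r <= r_outer_mm] <- signals$vw
    out[r <= r_inner_mm] <- signals$blood
    out
  }
  if (psf_fwhm_mm <= 0) {
    xs <- (matrix(seq_len(n_pix), n_pix, n_pix) - ctr) * pixel_mm
    ys <- (matrix(seq_len(n_pix), n_pix, n_pix, byrow = TRUE) - ctr) * pixel_mm
    img <- scene_at(xs, ys)
  } else {
    # supersample, blur with the Gaussian PSF, then point-sample the blurred
    # scene at the pixel centres (odd supersampling keeps centres on-grid)
    ss <- 5L
    nf <- n_pix * ss
    ctrf <- (nf + 1) / 2
    pf <- pixel_mm / ss
    xs <- (matrix(seq_len(nf), nf, nf) - ctrf) * pf
    ys <- (matrix(seq_len(nf), nf, nf, byrow = TRUE) - ctrf) * pf
    fine <- scene_at(xs, ys)
    sig_px <- psf_fwhm_mm / (2 * sqrt(2 * log(2))) / pf
    fine <- gauss_blur(fine, sig_px)
    mid <- (ss + 1L) / 2L
    img <- fine[seq(mid, nf, by = ss), seq(mid, nf, by = ss)]
  }
  img <- img * snr_scale
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(n_pix^2, 0, noise_sd), n_pix, n_pix)
  }
  structure(list(image = img, pixel_mm = pixel_mm, center = c(ctr, ctr),
                 r_inner_mm = r_inner_mm, r_outer_mm = r_outer_mm,
                 truth_signals = signals, psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd = noise_sd, snr_scale = snr_scale),
            class = "vessel_phantom")
}

# separable Gaussian blur with replicated edges
gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  pad_filter <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1, hw), , drop = FALSE], m,
                m[rep(n, hw), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(pad_filter(t(pad_filter(img))))
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("Vessel phantom: %dx%d px @ %.3g mm, radii %.3g/%.3g mm, PSF %.3g mm, noise sd %.3g SNR\n",
              nrow(x$image), ncol(x$image), x$pixel_mm, x$r_inner_mm,
              x$r_outer_mm, x$psf_fwhm_mm, x$noise_sd))
  invisible(x)
}

#' @export
plot.vessel_phantom <- function(x, ...) {
  graphics::image(x$image, col = grDevices::gray.colors(128), asp = 1,
                  axes = FALSE, main = "vessel phantom (SNR units)", ...)
  invisible(x)
}

#' Synthetic correlated multi-coil k-space data
#'
#' Builds per-channel k-space as the centred 2D FFT of the
#' sensitivity-weighted phantom plus correlated complex Gaussian noise
#' (covariance `noise_cov` per complex sample), together with matched
#' noise-only samples drawn from the same covariance — the inputs required by
#' the SNR-units reconstruction.
#'
#' @param phantom a `vessel_phantom` (its image is used as the object).
#' @param n_coils number of receive channels.
#' @param noise_cov n_coils x n_coils symmetric positive definite real noise
#'   covariance (per complex sample; identity * sd^2 typical). Default:
#'   identity.
#' @param undersampling_R undersampling factor recorded for the sqrt(2/R)
#'   SNR scaling (sampling itself is not decimated here).
#' @param n_noise number of noise-only samples per channel.
#' @param seed integer seed.
#' @return An object of class `coil_data`: `kspace` (nx x ny x n_coils,
#'   centred), `sens` (complex sensitivities), `ncov`, `noise_only`
#'   (n_noise x n_coils complex), `undersampling_R`.
#' @export
make_coil_data <- function(phantom, n_coils = 4, noise_cov = NULL,
                           undersampling_R = 1, n_noise = 20000, seed = 1L) {
  img <- phantom$image
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(noise_cov)) noise_cov <- diag(n_coils)
  ev <- eigen(noise_cov, symmetric = TRUE)
  if (any(ev$values < 0)) stop("noise covariance must be positive definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n_coils) %*% t(ev$vectors)
  set.seed(as.integer(seed))
  # smooth complex sensitivities around the FOV
  xg <- matrix(seq(-1, 1, length.out = nx), nx, ny)
  yg <- matrix(seq(-1, 1, length.out = ny), nx, ny, byrow = TRUE)
  sens <- array(0i, c(nx, ny, n_coils))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  for (c in seq_len(n_coils)) {
    cx <- 1.2 * cos(ang[c]); cy <- 1.2 * sin(ang[c])
    mag <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * 0.9^2))
    sens[, , c] <- mag * exp(1i * (0.3 * (xg * cos(ang[c]) + yg * sin(ang[c]))))
  }
  cgauss <- function(n) complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
  kspace <- array(0i, c(nx, ny, n_coils))
  noise_k <- matrix(cgauss(nx * ny * n_coils), ncol = n_coils) %*% t(L)
  for (c in seq_len(n_coils))
    kspace[, , c] <- ft2(img * sens[, , c]) +
      matrix(noise_k[, c], nx, ny)
  noise_only <- matrix(cgauss(n_noise * n_coils), ncol = n_coils) %*% t(L)
  structure(list(kspace = kspace, sens = sens, ncov = noise_cov,
                 noise_only = noise_only,
                 undersampling_R = as.integer(undersampling_R)),
            class = "coil_data")
}

#' Read / write synthetic containers
#'
#' Coil data are stored as a single-file array container with named elements
#' (`kspace`, `sens`, `ncov`, `noise_only`, `undersampling_R`); images and B1
#' maps can be written as NIfTI via [write_snr_nifti()].
#'
#' @param x a `coil_data` object.
#' @param file output path.
#' @export
write_coil_data <- function(x, file) {
  saveRDS(unclass(x), file)
  invisible(file)
}

#' @rdname write_coil_data
#' @export
read_coil_data <- function(file) {
  structure(readRDS(file), class = "coil_data")
}

#' Write / read a B1+ map set as per-channel NIfTI volumes
#'
#' Magnitude and phase volumes (`chNN_mag.nii.gz`, `chNN_phase.nii.gz`) plus
#' ROI masks (`roi_neck.nii.gz`, `roi_cow.nii.gz`) under `dir`.
#'
#' @param maps a `b1_map_set`.
#' @param dir output directory (created if missing).
#' @export
write_b1_maps <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (c in seq_len(maps$n_channels)) {
    m <- maps$channel_maps[, , c]
    RNifti::writeNifti(RNifti::asNifti(Mod(m)),
                       file.path(dir, sprintf("ch%02d_mag.nii.gz", c)))
    RNifti::writeNifti(RNifti::asNifti(Arg(m)),
                       file.path(dir, sprintf("ch%02d_phase.nii.gz", c)))
  }
  RNifti::writeNifti(RNifti::asNifti(maps$roi_neck * 1),
                     file.path(dir, "roi_neck.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$roi_cow * 1),
                     file.path(dir, "roi_cow.nii.gz"))
  invisible(dir)
}

#' @rdname write_b1_maps
#' @export
read_b1_maps <- function(dir) {
  mags <- sort(list.files(dir, "^ch[0-9]+_mag", full.names = TRUE))
  n <- length(mags)
  if (!n) stop("no channel maps found in ", dir)
  first <- RNifti::readNifti(mags[1])
  maps <- array(0i, c(dim(first)[1], dim(first)[2], n))
  for (c in seq_len(n)) {
    mg <- as.matrix(RNifti::readNifti(mags[c])[, ])
    ph <- as.matrix(RNifti::readNifti(sub("_mag", "_phase", mags[c]))[, ])
    maps[, , c] <- mg * exp(1i * ph)
  }
  roi_n <- as.matrix(RNifti::readNifti(file.path(dir, "roi_neck.nii.gz"))[, ]) > 0
  roi_c <- as.matrix(RNifti::readNifti(file.path(dir, "roi_cow.nii.gz"))[, ]) > 0
  structure(list(channel_maps = maps, roi_neck = roi_n, roi_cow = roi_c,
                 n_channels = n), class = "b1_map_set")
}
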