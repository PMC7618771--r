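#' Polar unwrapping of a vessel cross-section
#'
#' Interpolates the image along radial rays from the vessel centre to produce
#' a (direction x radius) polar map. Rays are sampled clockwise starting at
#' the vertical (12 o'clock) direction; bilinear interpolation on the
#' Cartesian grid, radial sampling on a fine interpolated grid (default
#' 0.05 mm).
#'
#' @param image an `snr_image`, `vessel_phantom` or plain matrix (rows = image
#'   rows, i.e. the vertical axis).
#' @param center vessel centre as (row, col) pixel coordinates (1-based).
#' @param n_directions number of radial directions (90 for paper-mode runs).
#' @param radial_step_mm radial sampling step (mm).
#' @param r_max_mm maximum sampled radius (mm); the full ray must stay inside
#'   the image.
#' @param pixel_mm pixel size (mm); taken from the input object when present.
#' @return An object of class `polar_map`: `profiles` (n_directions x n_r),
#'   `radii_mm`, `angles_rad` (clockwise from vertical), `center`,
#'   `radial_step_mm`, `pixel_mm`.
#' @export
polar_unwrap <- function(image, center = NULL, n_directions = 90,
                         radial_step_mm = 0.05, r_max_mm = NULL,
                         pixel_mm = NULL) {
  if (inherits(image, "vessel_phantom")) {
    if (is.null(pixel_mm)) pixel_mm <- image$pixel_mm
    if (is.null(center)) center <- image$center
    img <- image$image
  } else if (inherits(image, "snr_image")) {
    if (is.null(pixel_mm)) pixel_mm <- image$pixel_mm
    img <- Mod(image$pixels)
  } else img <- image
  if (is.null(pixel_mm) || is.na(pixel_mm)) stop("pixel_mm required")
  if (is.null(center)) stop("center required")
  nr <- nrow(img); nc <- ncol(img)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("centre outside image")
  if (is.null(r_max_mm))
    r_max_mm <- (min(center[1] - 1, nr - center[1], center[2] - 1,
                     nc - center[2]) - 1) * pixel_mm
  radii <- seq(radial_step_mm, r_max_mm, by = radial_step_mm)
  ang <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  prof <- matrix(NA_real_, n_directions, length(radii))
  for (j in seq_len(n_directions)) {
    # clockwise from vertical: up is decreasing row, clockwise moves to +col
    drow <- -cos(ang[j]); dcol <- sin(ang[j])
    rr <- center[1] + drow * radii / pixel_mm
    cc <- center[2] + dcol * radii / pixel_mm
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc))
      stop("ray exits the image; reduce r_max_mm")
    r0 <- pmin(floor(rr), nr - 1); c0 <- pmin(floor(cc), nc - 1)
    fr <- rr - r0; fc <- cc - c0
    prof[j, ] <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      img[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  structure(list(profiles = prof, radii_mm = radii, angles_rad = ang,
                 center = center, radial_step_mm = radial_step_mm,
                 n_directions = n_directions, pixel_mm = pixel_mm),
            class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("Polar map: %d directions x %d radial samples (step %.3g mm, r <= %.3g mm)\n",
              x$n_directions, length(x$radii_mm), x$radial_step_mm,
              max(x$radii_mm)))
  invisible(x)
}

#' @export
plot.polar_map <- function(x, ...) {
  graphics::image(x$angles_rad * 180 / pi, x$radii_mm, x$profiles,
                  col = grDevices::gray.colors(128),
                  xlab = "direction (deg, clockwise from vertical)",
                  ylab = "radius (mm)", main = "unwrapped vessel", ...)
  invisible(x)
}

# radial gradient of a polar map: value i is the difference between radial
# samples i+1 and i, located at the midpoint radius
polar_gradient <- function(polar) {
  g <- t(apply(polar$profiles, 1, diff))
  mid <- (polar$radii_mm[-1] + polar$radii_mm[-length(polar$radii_mm)]) / 2
  list(g = g, mid_mm = mid)
}

#' Identify inner and outer vessel boundaries from seeds
#'
#' Per direction, the inner boundary is placed at the radial-gradient maximum
#' (dark lumen to bright wall) within a search window around the inner seed
#' radius, and the outer boundary at the gradient extremum of the appropriate
#' sign (auto-detected from the profile unless given) around the outer seed.
#' Directions whose search window contains no usable extremum are flagged and
#' excluded from downstream metrics.
#'
#' @param polar a `polar_map`.
#' @param seeds list with `inner_mm` and `outer_mm`: approximate boundary
#'   radii, scalar or one value per direction (e.g. from [read_seeds()]).
#' @param window_mm full width of the search window around each seed (mm).
#' @param outer_sign +1 or -1 for the expected outer gradient sign, or NULL
#'   to detect it per direction from the window's dominant extremum.
#' @return An object of class `boundary_set`: `r_inner_mm`, `r_outer_mm`
#'   (per direction, NA when flagged), `flagged`, `seeds`, `window_mm`.
#' @export
find_boundaries <- function(polar, seeds, window_mm = 0.6,
                            outer_sign = NULL) {
  nd <- polar$n_directions
  si <- rep_len(seeds$inner_mm, nd)
  so <- rep_len(seeds$outer_mm, nd)
  gr <- polar_gradient(polar)
  eps <- 1e-9 * max(abs(polar$profiles), 1e-300)
  # Edge localization in two steps. (1) Candidate gradient extrema of the
  # requested sign inside the search window (interior local maxima of the
  # signed gradient, at least 30% of the window maximum); the candidate
  # NEAREST THE SEED is selected, so a displaced seed still locks onto the
  # same edge. (2) Sub-sample refinement: the bilinear radial gradient is
  # piecewise constant within each pixel span, so the bare argmax is biased
  # to the start of a plateau; the reported radius is the gradient centroid
  # of the contiguous above-half-peak run around the candidate -- tie-free,
  # invariant to intensity offset and equivariant under intensity scaling.
  locate_edge <- function(g, mid, sgn, seed) {
    gs <- sgn * g
    top <- max(gs)
    if (top <= eps) return(NA_real_)
    n <- length(gs)
    cand <- which(vapply(seq_len(n), function(i) {
      l <- if (i > 1) gs[i - 1] else -Inf
      r <- if (i < n) gs[i + 1] else -Inf
      gs[i] >= l && gs[i] >= r && (gs[i] > l || gs[i] > r)
    }, TRUE) & gs >= 0.3 * top)
    if (!length(cand)) cand <- which.max(gs)
    pk <- cand[which.min(abs(mid[cand] - seed))]
    keep <- gs >= gs[pk] / 2
    lo <- pk; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
    hi <- pk; while (hi < n && keep[hi + 1]) hi <- hi + 1
    run <- lo:hi
    sum(mid[run] * gs[run]) / sum(gs[run])
  }
  r_in <- r_out <- rep(NA_real_, nd)
  flagged <- logical(nd)
  for (j in seq_len(nd)) {
    wi <- which(abs(gr$mid_mm - si[j]) <= window_mm / 2)
    wo <- which(abs(gr$mid_mm - so[j]) <= window_mm / 2)
    if (!length(wi) || !length(wo)) { flagged[j] <- TRUE; next }
    r_in[j] <- locate_edge(gr$g[j, wi], gr$mid_mm[wi], 1, si[j])
    go <- gr$g[j, wo]
    sgn <- if (is.null(outer_sign))
      sign(go[which.max(abs(go))]) else outer_sign
    if (sgn == 0) { flagged[j] <- TRUE; next }
    r_out[j] <- locate_edge(go, gr$mid_mm[wo], sgn, so[j])
    if (is.na(r_in[j]) || is.na(r_out[j]) || r_out[j] <= r_in[j])
      flagged[j] <- TRUE
  }
  r_in[flagged] <- NA_real_; r_out[flagged] <- NA_real_
  structure(list(r_inner_mm = r_in, r_outer_mm = r_out, flagged = flagged,
                 seeds = list(inner_mm = si, outer_mm = so),
                 window_mm = window_mm),
            class = "boundary_set")
}

#' Seed file I/O
#'
#' Seeds are stored as CSV with columns `direction`, `r_inner_mm`,
#' `r_outer_mm` (a single row is treated as a global seed pair), so runs are
#' scriptable and reproducible.
#'
#' @param file CSV path.
#' @export
read_seeds <- function(file) {
  df <- utils::read.csv(file)
  list(inner_mm = df$r_inner_mm, outer_mm = df$r_outer_mm)
}

#' @rdname read_seeds
#' @param seeds list with `inner_mm`, `outer_mm`.
#' @export
write_seeds <- function(seeds, file) {
  n <- max(length(seeds$inner_mm), length(seeds$outer_mm))
  utils::write.csv(data.frame(direction = seq_len(n),
                              r_inner_mm = rep_len(seeds$inner_mm, n),
                              r_outer_mm = rep_len(seeds$outer_mm, n)),
                   file, row.names = FALSE)
  invisible(file)
}

#' Inner and outer boundary acutance
#'
#' Per direction and boundary: the maximum radial contrast (max minus min of
#' the interpolated profile) among samples within a window centred on the
#' boundary, divided by the window length — CNR per mm when the image is in
#' SNR units.
#'
#' @param polar a `polar_map`.
#' @param boundaries a `boundary_set`.
#' @param window_mm window length (mm), default 0.3.
#' @return List with `inner` and `outer` numeric vectors (CNR/mm per
#'   direction, NA for flagged directions).
#' @export
boundary_acutance <- function(polar, boundaries, window_mm = 0.3) {
  nd <- polar$n_directions
  one <- function(rb, j) {
    if (is.na(rb)) return(NA_real_)
    w <- which(abs(polar$radii_mm - rb) <= window_mm / 2)
    if (length(w) < 2) stop("acutance window outside the sampled profile")
    p <- polar$profiles[j, w]
    (max(p) - min(p)) / window_mm
  }
  list(inner = vapply(seq_len(nd), function(j)
         one(boundaries$r_inner_mm[j], j), 0),
       outer = vapply(seq_len(nd), function(j)
         one(boundaries$r_outer_mm[j], j), 0))
}

#' RMS radial signal gradient across the vessel wall
#'
#' For each direction, the root-mean-square of the radial signal differences
#' G_i between consecutive samples spanning the wall (inner to outer
#' boundary): `G_RMS = sqrt(sum(G_i^2) / n)` with n the number of
#' differences. Reported per mm (divided by the radial step) to match
#' SNR-units-per-mm axes; the per-step value is `g_rms_profile` applied to
#' the wall samples.
#'
#' @param polar a `polar_map`.
#' @param boundaries a `boundary_set`.
#' @param per_mm logical; divide by the radial step (default TRUE).
#' @return Numeric vector of G_RMS per direction (NA where flagged or where
#'   the wall spans fewer than 2 samples).
#' @export
g_rms <- function(polar, boundaries, per_mm = TRUE) {
  nd <- polar$n_directions
  out <- rep(NA_real_, nd)
  for (j in seq_len(nd)) {
    ri <- boundaries$r_inner_mm[j]; ro <- boundaries$r_outer_mm[j]
    if (is.na(ri) || is.na(ro)) next
    w <- which(polar$radii_mm >= ri & polar$radii_mm <= ro)
    if (length(w) < 2) next
    out[j] <- g_rms_profile(polar$profiles[j, w])
  }
  if (per_mm) out / polar$radial_step_mm else out
}

#' @rdname g_rms
#' @param profile numeric vector of wall samples (unit radial steps).
#' @export
g_rms_profile <- function(profile) {
  if (length(profile) < 2) stop("need at least 2 radial voxels across the wall")
  g <- diff(profile)
  sqrt(sum(g^2) / length(g))
}

#' Full acutance quantification of one vessel segment
#'
#' Polar unwrapping, boundary identification, boundary acutance, G_RMS and
#' 60-degree sub-segment means in one call.
#'
#' @inheritParams polar_unwrap
#' @param seeds seed list (see [find_boundaries()]).
#' @param search_window_mm boundary search window (mm).
#' @param acutance_window_mm acutance window (mm), default 0.3.
#' @return An object of class `acutance_metrics`: per-direction
#'   `inner_acutance`, `outer_acutance`, `g_rms` (all per mm), `boundaries`,
#'   `segment_means` (6 x 3 matrix over 60-degree sectors), and `flagged`.
#' @export
vessel_acutance <- function(image, seeds, center = NULL, n_directions = 90,
                            radial_step_mm = 0.05, r_max_mm = NULL,
                            pixel_mm = NULL, search_window_mm = 0.6,
                            acutance_window_mm = 0.3) {
  polar <- polar_unwrap(image, center, n_directions, radial_step_mm,
                        r_max_mm, pixel_mm)
  bnd <- find_boundaries(polar, seeds, search_window_mm)
  ac <- boundary_acutance(polar, bnd, acutance_window_mm)
  g <- g_rms(polar, bnd)
  sector <- floor((seq_len(n_directions) - 1) / (n_directions / 6)) + 1
  seg <- t(vapply(1:6, function(s) c(
    inner = mean(ac$inner[sector == s], na.rm = TRUE),
    outer = mean(ac$outer[sector == s], na.rm = TRUE),
    g_rms = mean(g[sector == s], na.rm = TRUE)), c(0, 0, 0)))
  structure(list(inner_acutance = ac$inner, outer_acutance = ac$outer,
                 g_rms = g, boundaries = bnd, segment_means = seg,
                 flagged = bnd$flagged, polar = polar),
            class = "acutance_metrics")
}

#' @export
print.acutance_metrics <- function(x, ...) {
  cat(sprintf("Vessel acutance over %d directions (%d flagged):\n",
              length(x$g_rms), sum(x$flagged)))
  cat(sprintf("  inner acutance %.3g, outer acutance %.3g CNR/mm; G_RMS %.3g per mm (means)\n",
              mean(x$inner_acutance, na.rm = TRUE),
              mean(x$outer_acutance, na.rm = TRUE),
              mean(x$g_rms, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.acutance_metrics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  ang <- seq_along(x$g_rms) - 1
  graphics::plot(ang, x$inner_acutance, type = "l", col = "forestgreen",
                 xlab = "direction (deg index)", ylab = "CNR/mm",
                 main = "boundary acutance",
                 ylim = range(c(x$inner_acutance, x$outer_acutance),
                              na.rm = TRUE))
  graphics::lines(ang, x$outer_acutance, col = "firebrick")
  graphics::legend("topright", c("inner", "outer"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  graphics::plot(ang, x$g_rms, type = "l", xlab = "direction (deg index)",
                 ylab = "delta-SNR/mm", main = "G_RMS")
  invisible(x)
}

#' Export per-direction metrics as CSV
#'
#' @param x an `acutance_metrics`.
#' @param file CSV path.
#' @export
write_acutance_csv <- function(x, file) {
  utils::write.csv(data.frame(
    direction = seq_along(x$g_rms),
    r_inner_mm = x$boundaries$r_inner_mm,
    r_outer_mm = x$boundaries$r_outer_mm,
    inner_acutance = x$inner_acutance,
    outer_acutance = x$outer_acutance,
    g_rms = x$g_rms), file, row.names = FALSE)
  invisible(file)
}

#' Paired one-tailed comparison of two protocols
#'
#' Paired-sample one-tailed t-test of the null hypothesis that protocol B
#' does not improve vessel visibility over protocol A (differences b - a,
#' alternative: mean > 0), plus the mean ratio and its 95% spread across
#' pairs. Pairs are slice-wise or segment-wise summary values (e.g. mean
#' G_RMS per slice).
#'
#' @param a,b equal-length numeric vectors of paired summary metrics, or
#'   lists of `acutance_metrics` (their mean G_RMS is used).
#' @param pairing label recorded in the result (`"slice"`, `"segment"`, ...).
#' @param alpha significance level (default 0.05).
#' @return An object of class `protocol_comparison`: `t`, `df`, `p`
#'   (one-tailed), `mean_ratio`, `ratio_spread` (95% range of per-pair
#'   ratios), `significant`, `degenerate` (zero-variance differences).
#' @export
compare_protocols <- function(a, b, pairing = "slice", alpha = 0.05) {
  pull <- function(x) if (is.list(x) && inherits(x[[1]], "acutance_metrics"))
    vapply(x, function(m) mean(m$g_rms, na.rm = TRUE), 0) else as.numeric(x)
  a <- pull(a); b <- pull(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- b - a
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 0.5 else if (mean(d) > 0) 0 else 1
  } else {
    tt <- mean(d) / (stats::sd(d) / sqrt(n))
    p <- stats::pt(tt, n - 1, lower.tail = FALSE)
  }
  ratios <- b / a
  structure(list(t = tt, df = n - 1, p = p,
                 mean_ratio = mean(b) / mean(a),
                 ratio_spread = mean(ratios, na.rm = TRUE) +
                   c(-1.96, 1.96) * stats::sd(ratios),
                 significant = p < alpha, degenerate = degenerate,
                 pairing = pairing, n = n),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat(sprintf("Paired one-tailed comparison (%s-wise, n = %d): t(%d) = %.4g, p = %.4g%s\n",
              x$pairing, x$n, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  cat(sprintf("  mean ratio %.4g (95%% spread %.4g to %.4g); %ssignificant at 0.05\n",
              x$mean_ratio, x$ratio_spread[1], x$ratio_spread[2],
              if (x$significant) "" else "not "))
  invisible(x)
}
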