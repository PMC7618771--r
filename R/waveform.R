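#' Synthetic pulsatile velocity waveforms
#'
#' Generates one cardiac cycle of a velocity waveform for the spin cohorts in
#' the simulation, scaled so the mean absolute velocity matches the requested
#' value. Three physiological shapes are provided:
#' \describe{
#'   \item{`csf`}{bidirectional two-harmonic oscillation with zero mean flow
#'     (CSF sloshes back and forth and crosses zero at least twice per cycle),
#'     emulating pulsatile CSF at the skull base.}
#'   \item{`vw`}{same bidirectional shape at vessel-wall amplitude (the wall
#'     moves slowly with the cardiac cycle).}
#'   \item{`blood`}{strictly positive two-harmonic raised-cosine shape with a
#'     systolic peak, emulating internal-carotid arterial flow.}
#'   \item{`constant`}{constant velocity (zero variance).}
#' }
#' The waveform is periodic: velocities at arbitrary times are obtained with
#' [waveform_velocity()], which wraps time modulo the cardiac period.
#'
#' @param kind `"csf"`, `"blood"`, `"vw"` or `"constant"`.
#' @param mean_cm_s requested mean absolute velocity (cm/s), >= 0.
#' @param period_ms cardiac period (ms), > 0; default 1000 ms.
#' @param n_samples samples per period on the stored grid.
#' @param seed integer seed; the shapes are deterministic, the seed only
#'   perturbs the relative harmonic phase slightly so repeated subjects differ.
#' @return An object of class `velocity_waveform` with fields `times_ms`,
#'   `velocities_cm_s`, `period_ms`, `kind`.
#' @examples
#' w <- make_waveform("csf", 0.367)
#' mean(abs(w$velocities_cm_s))  # 0.367 (within 1%)
#' @export
make_waveform <- function(kind = c("csf", "blood", "vw", "constant"),
                          mean_cm_s, period_ms = 1000, n_samples = 512,
                          seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(mean_cm_s >= 0, period_ms > 0, n_samples >= 8)
  t <- (seq_len(n_samples) - 1) / n_samples   # one period, [0, 1)
  set.seed(as.integer(seed))
  jitter <- stats::runif(1, -0.05, 0.05)      # small seed-dependent phase shift
  if (kind == "constant") {
    v <- rep(mean_cm_s, n_samples)
  } else if (kind == "blood") {
    # systolic peak near t = 0.15, always positive
    shape <- 1 + 0.85 * cos(2 * pi * (t - 0.15 - jitter)) +
      0.35 * cos(4 * pi * (t - 0.15 - jitter) + 0.9)
    shape <- pmax(shape, 0.05)
    v <- shape * (mean_cm_s / mean(abs(shape)))
  } else {
    # bidirectional, zero net flow, >= 2 zero crossings per period
    shape <- sin(2 * pi * (t - jitter)) + 0.45 * sin(4 * pi * (t - jitter) + 0.6)
    shape <- shape - mean(shape)
    v <- shape * (mean_cm_s / mean(abs(shape)))
  }
  structure(list(times_ms = t * period_ms, velocities_cm_s = v,
                 period_ms = period_ms, kind = kind,
                 mean_cm_s = mean_cm_s),
            class = "velocity_waveform")
}

#' Evaluate a waveform at arbitrary times
#'
#' Linear interpolation on the periodic stored grid; times are wrapped modulo
#' the cardiac period, so the waveform extends over any simulation duration.
#'
#' @param waveform a `velocity_waveform`.
#' @param times_ms numeric vector of absolute times (ms).
#' @return Velocities (cm/s) at the requested times.
#' @export
waveform_velocity <- function(waveform, times_ms) {
  tm <- times_ms %% waveform$period_ms
  n <- length(waveform$times_ms)
  # periodic linear interpolation
  xs <- c(waveform$times_ms, waveform$period_ms)
  vs <- c(waveform$velocities_cm_s, waveform$velocities_cm_s[1])
  stats::approx(xs, vs, xout = tm, rule = 2)$y
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("Velocity waveform '%s': period %.0f ms, mean |v| %.4g cm/s, %d samples\n",
              x$kind, x$period_ms, mean(abs(x$velocities_cm_s)),
              length(x$velocities_cm_s)))
  invisible(x)
}

#' @export
plot.velocity_waveform <- function(x, ...) {
  graphics::plot(x$times_ms, x$velocities_cm_s, type = "l",
                 xlab = "time (ms)", ylab = "velocity (cm/s)",
                 main = sprintf("%s waveform", x$kind), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
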