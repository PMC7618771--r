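#' One-dimensional DANTE parameter sweep
#'
#' Sweeps one of the four DANTE parameters (flip angle, number of pulses,
#' gradient amplitude, interpulse time) over a grid, holding every other
#' parameter at the base protocol's value, and simulates the VW/CSF/blood
#' signal levels for each grid value in the requested vessel wall motion
#' modes. Grid evaluations are independent, so results do not depend on
#' evaluation order.
#'
#' @param base a `vwi_protocol` providing all non-swept parameters.
#' @param parameter `"flip_deg"`, `"n_pulses"`, `"grad_mT_m"` or
#'   `"interpulse_ms"`.
#' @param grid strictly increasing numeric vector of swept values.
#' @param motion_modes vessel wall motion modes to simulate.
#' @param seed waveform seed.
#' @return A data frame of class `sweep_result` with columns `parameter`,
#'   `value`, `motion_mode`, `vw`, `csf`, `blood`, `vw_minus_csf`,
#'   `vw_minus_blood`; the base protocol is kept as attribute `"base"`.
#' @export
sweep_parameter <- function(base, parameter = c("flip_deg", "n_pulses",
                                                "grad_mT_m", "interpulse_ms"),
                            grid,
                            motion_modes = c("pulsating", "stationary"),
                            seed = 1L) {
  parameter <- match.arg(parameter)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  rows <- list()
  for (v in grid) {
    p <- base
    p$dante[[parameter]] <- if (parameter == "n_pulses") as.integer(v) else v
    for (mm in motion_modes) {
      s <- simulate_signal_set(p, mm, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, value = v, motion_mode = mm,
        vw = s$vw, csf = s$csf, blood = s$blood,
        vw_minus_csf = s$vw - s$csf, vw_minus_blood = s$vw - s$blood)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
plot.sweep_result <- function(x, motion_mode = "pulsating", ...) {
  d <- x[x$motion_mode == motion_mode, ]
  graphics::matplot(d$value, cbind(d$vw, d$csf, d$blood), type = "l",
                    lty = 1, col = c("black", "dodgerblue", "firebrick"),
                    xlab = unique(d$parameter), ylab = "signal (M0)",
                    main = sprintf("%s sweep (%s VW)", unique(d$parameter),
                                   motion_mode), ...)
  graphics::legend("topright", c("VW", "CSF", "blood"), lty = 1,
                   col = c("black", "dodgerblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Sweep objective: constrained pulsating-VW contrast
#'
#' The documented protocol-selection objective: maximize the pulsating
#' vessel-wall-to-CSF contrast subject to (i) the blood signal not exceeding
#' `blood_max` (fraction of M0) and (ii) the stationary-VW contrast not
#' falling more than `stationary_loss_max` below the best stationary contrast
#' on the same grid. Infeasible grid points score NA.
#'
#' @param sweep a `sweep_result` containing both motion modes.
#' @param blood_max blood-signal ceiling (fraction of M0).
#' @param stationary_loss_max allowed relative stationary-contrast loss.
#' @return Data frame with `value` and `objective` (NA where infeasible).
#' @export
sweep_objective <- function(sweep, blood_max = 0.02,
                            stationary_loss_max = 0.05) {
  pu <- sweep[sweep$motion_mode == "pulsating", ]
  st <- sweep[sweep$motion_mode == "stationary", ]
  if (!nrow(st)) stop("objective needs the stationary motion mode in the sweep")
  st <- st[match(pu$value, st$value), ]
  ok <- pu$blood <= blood_max &
    st$vw_minus_csf >= (1 - stationary_loss_max) * max(st$vw_minus_csf)
  data.frame(value = pu$value,
             objective = ifelse(ok, pu$vw_minus_csf, NA_real_))
}

#' Coordinate-wise optimum DANTE parameters from sweeps
#'
#' Applies [sweep_objective()] to each one-dimensional sweep and picks, per
#' swept parameter, the feasible grid value with the highest objective. Ties
#' are broken toward the lower SAR proxy, then toward the shorter
#' preparation.
#'
#' @param sweeps list of `sweep_result` objects (one per DANTE parameter;
#'   all four for a full protocol selection).
#' @param blood_max,stationary_loss_max objective settings.
#' @return A `dante_params` with each swept parameter at its selected value
#'   (non-swept parameters from the sweeps' base protocol), with the
#'   per-parameter selections as attribute `"selection"`.
#' @export
select_optimum <- function(sweeps, blood_max = 0.02,
                           stationary_loss_max = 0.05) {
  if (!length(sweeps)) stop("empty sweeps")
  base <- attr(sweeps[[1]], "base")
  dante <- base$dante
  sel <- list()
  for (sw in sweeps) {
    par <- unique(sw$parameter)
    obj <- sweep_objective(sw, blood_max, stationary_loss_max)
    if (all(is.na(obj$objective)))
      stop("no feasible grid value for parameter ", par)
    cand <- obj$value[!is.na(obj$objective) &
                        obj$objective >= max(obj$objective, na.rm = TRUE) - 1e-12]
    if (length(cand) > 1) {
      # tie-break: lower SAR proxy, then shorter preparation
      sar <- vapply(cand, function(v) {
        d <- dante; d[[par]] <- v; sar_proxy(d)
      }, 0)
      cand <- cand[sar == min(sar)]
      if (length(cand) > 1) {
        dur <- vapply(cand, function(v) {
          d <- dante; d[[par]] <- v; d$n_pulses * d$interpulse_ms
        }, 0)
        cand <- cand[which.min(dur)]
      }
    }
    sel[[par]] <- cand[1]
    dante[[par]] <- if (par == "n_pulses") as.integer(cand[1]) else cand[1]
  }
  attr(dante, "selection") <- sel
  dante
}

#' TR selection by SNR efficiency
#'
#' Evaluates the reference-tissue signal on a TR grid and returns the
#' candidate maximizing signal / sqrt(TR) (SNR per unit scan time); ties go
#' to the shorter TR. By default the signal is the DANTE-free centre-echo
#' signal of the supplied readout simulated for the reference tissue; a
#' custom `signal_fun(tr_s)` can be supplied (e.g. a closed-form
#' saturation-recovery model for validation).
#'
#' @param grid numeric vector of candidate TRs (s), positive.
#' @param tissue reference `tissue_params`.
#' @param space a `space_params` (its `tr_s` is overridden per candidate).
#' @param signal_fun optional function(tr_s) -> signal.
#' @return A list of class `tr_candidate`: `tr_s`, `signal`, `efficiency`,
#'   and the full `table`.
#' @export
optimize_tr <- function(grid, tissue = NULL, space = NULL,
                        signal_fun = NULL) {
  if (!length(grid) || any(grid <= 0)) stop("TR grid must be positive")
  if (is.null(signal_fun)) {
    stopifnot(!is.null(tissue), !is.null(space))
    if (is.null(space$flip_train_deg))
      space$flip_train_deg <- vfa_train(tissue, space)
    signal_fun <- function(tr) {
      sp <- space; sp$tr_s <- tr
      prot <- protocol("tr_scan", dante_params(0, 0), sp,
                       if (identical(tissue$field_t, "3T")) "3T" else "7T")
      simulate_protocol(prot, tissue, NULL)$signal
    }
  }
  sig <- vapply(grid, signal_fun, 0)
  eff <- sig / sqrt(grid)
  best <- which(eff >= max(eff) - 1e-15)
  best <- best[which.min(grid[best])]
  structure(list(tr_s = grid[best], signal = sig[best],
                 efficiency = eff[best],
                 table = data.frame(tr_s = grid, signal = sig,
                                    efficiency = eff)),
            class = "tr_candidate")
}

#' @export
print.tr_candidate <- function(x, ...) {
  cat(sprintf("Best TR: %.3g s (signal %.4g, SNR/sqrt(TR) efficiency %.4g)\n",
              x$tr_s, x$signal, x$efficiency))
  invisible(x)
}
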