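#' Generate a variable flip angle (VFA) refocusing train
#'
#' Computes an echo-train of refocusing flip angles realizing a prescribed
#' signal evolution for a reference tissue. With `target_mode = "plateau"`
#' (default) the prescribed echo amplitudes fall quickly from the first echo
#' (time constant `decay_tau_ms`, the transition into the low-flip
#' pseudo-steady state) onto a slowly decaying plateau at `plateau_frac` of
#' the first echo; the plateau itself decays at the relaxation-limited
#' pseudo-steady-state rate `sin^2(a/2)/T2 + cos^2(a/2)/T1` evaluated at
#' `plateau_flip_deg`, which is the slowest evolution a refocusing train can
#' sustain for the reference tissue (a strictly constant plateau is
#' infeasible for finite T1/T2). With `target_mode = "constant"` the target
#' stays at the first echo (useful only for non-relaxing tissue). Each flip
#' angle is solved by root-finding against the actual static EPG forward
#' model, so the returned train reproduces the prescribed evolution exactly
#' for the reference tissue; the smaller-flip (lower-SAR) branch is returned.
#'
#' @param tissue reference `tissue_params` (typically the vessel wall preset).
#' @param space a `space_params` giving etl and echo spacing.
#' @param target_mode `"plateau"` (default) or `"constant"`.
#' @param start_flip_deg flip of the first refocusing pulse (degrees).
#' @param plateau_frac plateau level as a fraction of the first echo.
#' @param decay_tau_ms prescribed transition decay constant (ms).
#' @param plateau_flip_deg nominal plateau flip used to set the sustainable
#'   plateau decay rate.
#' @return Numeric vector of `etl` flip angles (degrees), with the achieved
#'   echo amplitudes as attribute `"echoes"`.
#' @export
vfa_train <- function(tissue, space, target_mode = c("plateau", "constant"),
                      start_flip_deg = 120, plateau_frac = 0.4,
                      decay_tau_ms = 40, plateau_flip_deg = 60) {
  target_mode <- match.arg(target_mode)
  etl <- space$etl
  esp <- space$echo_spacing_ms
  ap <- plateau_flip_deg * pi / 180
  r_slow <- sin(ap / 2)^2 / tissue$t2_ms + cos(ap / 2)^2 / tissue$t1_ms
  state <- epg_equilibrium(2 * etl + 2, 1)
  state <- epg_rf(state, space$excitation_deg, 90)
  half <- function(st) epg_grad_shift(epg_relax(st, esp / 2, tissue), 1L)
  echo_for <- function(st, flip) {
    st <- half(epg_rf(st, flip, 0))
    Mod(epg_signal(st))
  }
  flips <- numeric(etl)
  echoes <- numeric(etl)
  flips[1] <- start_flip_deg
  state <- half(state)
  state <- half(epg_rf(state, start_flip_deg, 0))
  echoes[1] <- Mod(epg_signal(state))
  s1 <- echoes[1]
  if (etl >= 2) {
    for (j in 2:etl) {
      tj <- (j - 1) * esp
      target <- if (target_mode == "constant") s1 else
        s1 * max(plateau_frac * exp(-tj * r_slow), exp(-tj / decay_tau_ms))
      pre <- half(state)
      # echo amplitude is not monotone in the flip (stimulated pathways peak
      # below 180 deg): locate the maximizing flip, then solve on the rising
      # branch so the smaller-flip (lower-SAR) solution is returned
      opt <- stats::optimize(function(a) echo_for(pre, a), c(0.01, 180),
                             maximum = TRUE, tol = 0.05)
      a_max <- opt$maximum
      if (echo_for(pre, 180) > opt$objective) a_max <- 180
      if (echo_for(pre, a_max) < target - 1e-9 * s1)
        stop(sprintf("prescribed signal evolution infeasible at echo %d (needs flip > 180 deg)", j))
      if (echo_for(pre, 0.01) >= target) {
        flips[j] <- 0.01
      } else {
        flips[j] <- stats::uniroot(function(a) echo_for(pre, a) - target,
                                   c(0.01, a_max), tol = 1e-4)$root
      }
      state <- half(epg_rf(pre, flips[j], 0))
      echoes[j] <- Mod(epg_signal(state))
    }
  }
  attr(flips, "echoes") <- echoes
  flips
}

# --- event-list builders ----------------------------------------------------

# velocity sampled at interval midpoints (intervals ~1 ms are short relative
# to the cardiac period, so piecewise-constant velocity is adequate)
wf_v <- function(waveform, t_start, dt) {
  if (is.null(waveform)) return(rep(0, length(t_start)))
  waveform_velocity(waveform, t_start + dt / 2)
}

events_dante <- function(dante, waveform = NULL, b1_scale = 1, t0 = 0) {
  n <- dante$n_pulses
  if (n == 0L) return(epg_events(numeric(0), character(0)))
  phases <- dante_phases(dante)
  has_grad <- dante$grad_mT_m > 0 && dante$grad_dur_ms > 0
  ip <- dante$interpulse_ms
  tj <- t0 + (seq_len(n) - 1) * ip
  if (has_grad) {
    g <- dante$grad_dur_ms
    rest <- ip - g
    epg_events(
      as.vector(rbind(tj, tj, tj + g, tj + g)),
      rep(c("rf", "evolve_g", "shift", "evolve"), n),
      as.vector(rbind(rep(dante$flip_deg * b1_scale, n), rep(g, n),
                      rep(1, n), rep(rest, n))),
      as.vector(rbind(phases, wf_v(waveform, tj, g), rep(0, n),
                      wf_v(waveform, tj + g, rest))))
  } else {
    epg_events(
      as.vector(rbind(tj, tj)),
      rep(c("rf", "evolve"), n),
      as.vector(rbind(rep(dante$flip_deg * b1_scale, n), rep(ip, n))),
      as.vector(rbind(phases, wf_v(waveform, tj, ip))))
  }
}

events_space <- function(space, waveform = NULL, b1_scale = 1, t0 = 0) {
  esp <- space$echo_spacing_ms
  flips <- space$flip_train_deg
  if (is.null(flips)) stop("flip_train_deg not populated")
  n <- space$etl
  h <- esp / 2
  tj <- t0 + (seq_len(n) - 1) * esp
  z <- rep(0, n)
  bind_events(
    epg_events(t0, "rf", space$excitation_deg * b1_scale, 90),
    epg_events(
      as.vector(rbind(tj, tj + h, tj + h, tj + h, tj + esp, tj + esp)),
      rep(c("evolve", "shift", "rf", "evolve", "shift", "echo"), n),
      as.vector(rbind(rep(h, n), rep(1, n), pmin(flips * b1_scale, 180),
                      rep(h, n), rep(1, n), z)),
      as.vector(rbind(wf_v(waveform, tj, h), z, z,
                      wf_v(waveform, tj + h, h), z, z))))
}

#' Apply a DANTE preparation to an EPG state
#'
#' Runs `n_pulses` iterations of [RF at flip * b1_scale, then gradient
#' dephasing plus relaxation/flow/diffusion over the interpulse interval].
#'
#' @param state an `epg_state`.
#' @param dante a `dante_params`.
#' @param tissue a `tissue_params`.
#' @param waveform a `velocity_waveform` (or NULL for a static cohort).
#' @param b1_scale relative transmit field at the cohort's location, >= 0.
#' @param t0 absolute start time (ms) for waveform sampling.
#' @return The prepared `epg_state`.
#' @export
dante_prep <- function(state, dante, tissue, waveform = NULL, b1_scale = 1,
                       t0 = 0) {
  if (b1_scale < 0) stop("b1_scale must be >= 0")
  ev <- events_dante(dante, waveform, b1_scale, t0)
  if (nrow(ev) == 0L) return(state)
  run_epg_events(ev, tissue, state$max_order, state$dk_per_shift, state)$state
}

#' Spatial saturation band
#'
#' Models the saturation slab as complete nulling of the magnetization of any
#' spin cohort resident inside the band (at 3T: inflowing blood below the FOV
#' at saturation time); cohorts outside the band are untouched. No slab
#' profile is modelled.
#'
#' @param state an `epg_state`.
#' @param tissue_in_band logical; is the simulated cohort inside the band?
#' @return The (possibly nulled) `epg_state`.
#' @export
apply_sat_band <- function(state, tissue_in_band) {
  if (isTRUE(tissue_in_band)) {
    state$Fp[] <- 0i; state$Fm[] <- 0i; state$Z[] <- 0i
  }
  state
}

#' Simulate a SPACE readout train
#'
#' Excitation followed by `etl` refocusing intervals with relaxation, flow and
#' diffusion; returns the echo magnitudes.
#'
#' @inheritParams dante_prep
#' @param space a `space_params` with a populated flip train.
#' @return Numeric vector of |echo| per echo index, with the final state as
#'   attribute `"state"`.
#' @export
space_readout <- function(state, space, tissue, waveform = NULL, b1_scale = 1,
                          t0 = 0) {
  ev <- events_space(space, waveform, b1_scale, t0)
  res <- run_epg_events(ev, tissue, state$max_order, state$dk_per_shift, state)
  out <- Mod(res$echoes)
  attr(out, "state") <- res$state
  out
}

# intravoxel velocity-scale quadrature per tissue (see methods vignette):
# blood is laminar (uniform on [0, 2 * mean], midpoint rule); CSF and VW are
# plug flow with a 10% Gaussian spread (5-node Gauss-Hermite quadrature).
vel_scales <- function(tissue, n_laminar = 8) {
  if (tissue$name == "blood") {
    list(scales = (2 * seq_len(n_laminar) - 1) / n_laminar,
         weights = rep(1 / n_laminar, n_laminar))
  } else {
    gh_nodes <- c(-2.0201828705, -0.9585724646, 0, 0.9585724646, 2.0201828705)
    gh_w <- c(0.0199532421, 0.3936193232, 0.9453087205, 0.3936193232,
              0.0199532421)
    list(scales = 1 + 0.1 * sqrt(2) * gh_nodes, weights = gh_w / sum(gh_w))
  }
}

#' Simulate a full DANTE-SPACE protocol for one tissue
#'
#' Runs `n_tr` full repetitions from thermal equilibrium (DANTE preparation,
#' optional saturation band, SPACE readout, recovery to the next TR) and
#' returns the echo magnitude at the k-space-centre echo
#' (`round(te_eq / echo_spacing)`) of the final simulated TR. Two TRs are
#' simulated by default so that magnetization history from the first
#' repetition is reflected in the reported signal.
#'
#' For blood the cohort signal is averaged (complex) over a laminar
#' intravoxel velocity distribution; CSF and vessel wall use plug flow. If the
#' protocol carries a saturation band, the blood cohort (resident below the
#' FOV between DANTE and readout) is saturated; other tissues are not.
#'
#' @param prot a `vwi_protocol`.
#' @param tissue a `tissue_params`.
#' @param waveform a `velocity_waveform` for the cohort (NULL = static).
#' @param n_tr number of repetitions simulated (>= 2 recommended).
#' @param phase_offset_ms cardiac phase offset of the waveform at t = 0.
#' @param max_order_factor multiplier on the default truncation order
#'   (used by the truncation-convergence checks).
#' @return A list of class `protocol_signal` with `signal` (magnitude of the
#'   centre echo, fraction of M0), `echoes` (etl x n_tr magnitude matrix of
#'   the last velocity cohort), `echo_index`.
#' @export
simulate_protocol <- function(prot, tissue, waveform = NULL, n_tr = 2,
                              phase_offset_ms = 0, max_order_factor = 1) {
  space <- prot$space
  dante <- prot$dante
  echo_index <- as.integer(round(space$te_eq_ms / space$echo_spacing_ms))
  if (echo_index < 1L || echo_index > space$etl)
    stop("te_eq_ms falls outside the echo train")
  tr_ms <- space$tr_s * 1000
  sat_delay <- if (!is.null(prot$sat_band)) prot$sat_band$delay_ms else 0
  prep_ms <- dante$n_pulses * dante$interpulse_ms
  readout_ms <- space$etl * space$echo_spacing_ms
  rest_ms <- tr_ms - prep_ms - sat_delay - readout_ms
  if (rest_ms < 0) stop("TR shorter than preparation + readout")
  b1_prep <- if (tissue$name == "blood") prot$b1_scale_prep else
    prot$b1_scale_readout
  in_band <- !is.null(prot$sat_band) && tissue$name == "blood"
  dk <- dante_dk(dante)
  max_order <- ceiling(max_order_factor *
                         (n_tr * (dante$n_pulses + 2L * space$etl) + 4L))

  # event list for one cohort velocity scale
  build <- function(scale) {
    wf <- waveform
    if (!is.null(wf)) wf$velocities_cm_s <- wf$velocities_cm_s * scale
    rows <- vector("list", 4L * n_tr)
    k <- 0L
    for (tr in seq_len(n_tr)) {
      t0 <- (tr - 1) * tr_ms + phase_offset_ms
      k <- k + 1L; rows[[k]] <- events_dante(dante, wf, b1_prep, t0)
      t <- t0 + prep_ms
      if (in_band) {
        k <- k + 1L
        rows[[k]] <- epg_events(c(t, t), c("sat", "evolve"),
                                c(0, sat_delay),
                                c(0, wf_v(wf, t, sat_delay)))
      } else if (sat_delay > 0) {
        k <- k + 1L
        rows[[k]] <- epg_events(t, "evolve", sat_delay,
                                wf_v(wf, t, sat_delay))
      }
      t <- t + sat_delay
      k <- k + 1L
      rows[[k]] <- events_space(space, wf, prot$b1_scale_readout, t)
      t <- t + readout_ms
      k <- k + 1L
      rows[[k]] <- epg_events(t, "evolve", rest_ms, wf_v(wf, t, rest_ms))
    }
    do.call(bind_events, rows[seq_len(k)])
  }

  vq <- if (is.null(waveform)) list(scales = 1, weights = 1) else
    vel_scales(tissue)
  acc <- 0
  for (i in seq_along(vq$scales)) {
    res <- run_epg_events(build(vq$scales[i]), tissue, max_order, dk)
    em <- matrix(res$echoes, nrow = space$etl, ncol = n_tr)
    acc <- acc + vq$weights[i] * em
  }
  structure(list(signal = Mod(acc[echo_index, n_tr]),
                 echoes = Mod(acc), echo_index = echo_index,
                 tissue = tissue$name, n_tr = n_tr),
            class = "protocol_signal")
}

#' @export
print.protocol_signal <- function(x, ...) {
  cat(sprintf("Simulated %s signal: %.4g M0 (centre echo %d, TR %d)\n",
              x$tissue, x$signal, x$echo_index, x$n_tr))
  invisible(x)
}

#' Simulate VW / CSF / blood signal levels for a protocol
#'
#' Convenience wrapper building the packaged pulsatile waveforms (means from
#' the tissue preset table) and simulating all three tissues.
#'
#' @param prot a `vwi_protocol`.
#' @param motion_mode `"pulsating"` (vessel wall moves with its waveform) or
#'   `"stationary"` (vessel wall static); CSF and blood are always pulsatile.
#' @param phase_offset_ms cardiac phase offset (ms).
#' @param seed waveform seed.
#' @return An object of class `signal_set` with fields `vw`, `csf`, `blood`
#'   (fractions of M0) and `motion_mode`.
#' @export
simulate_signal_set <- function(prot, motion_mode = c("pulsating",
                                                      "stationary"),
                                phase_offset_ms = 0, seed = 1L) {
  motion_mode <- match.arg(motion_mode)
  fl <- prot$field_t
  wf_vw <- if (motion_mode == "pulsating")
    make_waveform("vw", tissue_preset("vw", fl)$mean_speed_cm_s, seed = seed)
  else NULL
  wf_csf <- make_waveform("csf", tissue_preset("csf", fl)$mean_speed_cm_s,
                          seed = seed)
  wf_bl <- make_waveform("blood", tissue_preset("blood", fl)$mean_speed_cm_s,
                         seed = seed)
  signal_set(
    vw = simulate_protocol(prot, tissue_preset("vw", fl), wf_vw,
                           phase_offset_ms = phase_offset_ms)$signal,
    csf = simulate_protocol(prot, tissue_preset("csf", fl), wf_csf,
                            phase_offset_ms = phase_offset_ms)$signal,
    blood = simulate_protocol(prot, tissue_preset("blood", fl), wf_bl,
                              phase_offset_ms = phase_offset_ms)$signal,
    motion_mode = motion_mode)
}

#' Signal-level container
#'
#' @param vw,csf,blood signal magnitudes (fraction of M0, in [0, 1]).
#' @param motion_mode `"pulsating"` or `"stationary"` (vessel wall motion).
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(vw, csf, blood, motion_mode = "pulsating") {
  vals <- c(vw = vw, csf = csf, blood = blood)
  if (any(vals < 0 | vals > 1)) stop("signal magnitudes must lie in [0, 1]")
  structure(list(vw = vw, csf = csf, blood = blood,
                 motion_mode = motion_mode), class = "signal_set")
}

#' Vessel wall contrasts
#'
#' @param signals a `signal_set`.
#' @return An object of class `contrast_result` with `vw_minus_csf` and
#'   `vw_minus_blood`.
#' @export
contrasts <- function(signals) {
  structure(list(vw_minus_csf = signals$vw - signals$csf,
                 vw_minus_blood = signals$vw - signals$blood),
            class = "contrast_result")
}

#' Simulated CSF-signal reduction of a DANTE preparation
#'
#' Percentage reduction of the pulsatile-CSF centre-echo signal caused by the
#' protocol's DANTE module, relative to the identical simulation with the
#' module disabled (`n_pulses = 0`), everything else unchanged. Because the
#' cardiac phase at DANTE onset is arbitrary in an ungated acquisition, the
#' signals are averaged over `n_phases` evenly spaced cardiac start phases
#' before the ratio is taken.
#'
#' @param prot a `vwi_protocol`.
#' @param waveform pulsatile CSF `velocity_waveform`; default built from the
#'   tissue preset mean for the protocol's field strength.
#' @param n_phases number of cardiac start phases averaged (default 8).
#' @param seed waveform seed (used only when `waveform` is NULL).
#' @return CSF signal reduction in percent (0 when `n_pulses = 0`).
#' @export
csf_reduction <- function(prot, waveform = NULL, n_phases = 8, seed = 1L) {
  csf <- tissue_preset("csf", prot$field_t)
  if (is.null(waveform))
    waveform <- make_waveform("csf", csf$mean_speed_cm_s, seed = seed)
  prot_off <- prot
  prot_off$dante$n_pulses <- 0L
  offsets <- (seq_len(n_phases) - 1) / n_phases * waveform$period_ms
  s_on <- vapply(offsets, function(ph)
    simulate_protocol(prot, csf, waveform, phase_offset_ms = ph)$signal, 0)
  s_off <- vapply(offsets, function(ph)
    simulate_protocol(prot_off, csf, waveform, phase_offset_ms = ph)$signal, 0)
  if (mean(s_off) <= 0) stop("zero reference CSF signal")
  100 * (1 - mean(s_on) / mean(s_off))
}

#' Relative SAR proxy of a DANTE preparation
#'
#' Hard-pulse energy proxy `n_pulses * flip_deg^2`, valid for ratio
#' comparisons between DANTE modules only (not an absolute SAR in W/kg).
#'
#' @param dante a `dante_params`.
#' @return Dimensionless relative SAR proxy.
#' @export
sar_proxy <- function(dante) dante$n_pulses * dante$flip_deg^2
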