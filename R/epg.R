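#' Extended phase graph (EPG) configuration states
#'
#' The EPG formalism tracks the magnetization of a voxel as complex amplitudes
#' of dephasing-order configuration states: transverse states F(k) and
#' longitudinal states Z(k), where one unit of k corresponds to the phase
#' pattern wound by one dephasing-gradient lobe (`dk_per_shift` rad/mm).
#'
#' Storage convention (Weigel-style operator set): `Fp[k+1]` holds F(k) for
#' k >= 0, `Fm[k+1]` holds conj(F(-k)), and `Z[k+1]` holds Z(k); negative-order
#' longitudinal states follow from Z(-k) = conj(Z(k)). At equilibrium only
#' Z(0) = 1 is populated. Amplitudes pushed beyond `max_order` by gradient
#' shifts are dropped (documented truncation loss); the shipped defaults make
#' this loss negligible (see the truncation-convergence tests).
#'
#' @param max_order truncation order K; states with |k| > K are dropped.
#' @param dk_per_shift physical dephasing increment per unit order (rad/mm).
#' @return An object of class `epg_state` with fields `Fp`, `Fm`, `Z`
#'   (complex vectors of length `max_order + 1`), `max_order`, `dk_per_shift`.
#' @examples
#' s <- epg_equilibrium(10)
#' Re(s$Z[1])  # 1
#' @export
epg_equilibrium <- function(max_order, dk_per_shift = 1) {
  stopifnot(max_order >= 1, is.finite(dk_per_shift))
  z <- complex(max_order + 1)
  z[1] <- 1 + 0i
  structure(list(Fp = complex(max_order + 1), Fm = complex(max_order + 1),
                 Z = z, max_order = as.integer(max_order),
                 dk_per_shift = dk_per_shift),
            class = "epg_state")
}

#' @export
print.epg_state <- function(x, ...) {
  pop <- sum(Mod(x$Fp) > 1e-12 | Mod(x$Fm) > 1e-12 | Mod(x$Z) > 1e-12)
  cat(sprintf("EPG state: max_order %d, dk %.4g rad/mm, %d populated orders, F(0) = %.4g%+.4gi\n",
              x$max_order, x$dk_per_shift, pop, Re(x$Fp[1]), Im(x$Fp[1])))
  invisible(x)
}

#' Instantaneous RF rotation of an EPG state
#'
#' Mixes the (F+, F-, Z) triplet of every order by the unitary rotation of a
#' hard RF pulse with the given flip angle and phase. There is no inter-order
#' transfer; the rotation acts order-by-order.
#'
#' @param state an `epg_state`.
#' @param flip_deg flip angle in degrees, in [0, 180].
#' @param phase_deg RF phase in degrees (0 = rotation about x).
#' @return The rotated `epg_state`.
#' @export
epg_rf <- function(state, flip_deg, phase_deg = 0) {
  if (!is.finite(flip_deg) || !is.finite(phase_deg))
    stop("non-finite RF angle")
  if (flip_deg < 0 || flip_deg > 180)
    stop("flip_deg must lie in [0, 180]")
  a <- flip_deg * pi / 180
  p <- phase_deg * pi / 180
  c2 <- cos(a / 2)^2; s2 <- sin(a / 2)^2
  sa <- sin(a); ca <- cos(a)
  eip <- exp(1i * p)
  Fp <- state$Fp; Fm <- state$Fm; Z <- state$Z
  state$Fp <- c2 * Fp + eip^2 * s2 * Fm - 1i * eip * sa * Z
  state$Fm <- s2 * Fp / eip^2 + c2 * Fm + 1i * sa * Z / eip
  state$Z  <- -0.5i * sa * Fp / eip + 0.5i * eip * sa * Fm + ca * Z
  state
}

#' Relaxation of an EPG state over a free interval
#'
#' Transverse orders decay with exp(-dt/T2), longitudinal orders with
#' exp(-dt/T1); the order-0 longitudinal state recovers toward thermal
#' equilibrium (Z0 -> 1 in M0 units).
#'
#' @param state an `epg_state`.
#' @param dt_ms interval duration (ms), >= 0.
#' @param tissue a `tissue_params` supplying T1 and T2.
#' @return The relaxed `epg_state`.
#' @export
epg_relax <- function(state, dt_ms, tissue) {
  stopifnot(dt_ms >= 0)
  e1 <- exp(-dt_ms / tissue$t1_ms)
  e2 <- exp(-dt_ms / tissue$t2_ms)
  state$Fp <- state$Fp * e2
  state$Fm <- state$Fm * e2
  state$Z <- state$Z * e1
  state$Z[1] <- state$Z[1] + (1 - e1)
  state
}

#' Gradient shift of EPG configuration orders
#'
#' Shifts all transverse configuration orders by `n_shifts` dephasing units,
#' with the standard F+/F- crossover at order 0; longitudinal orders are
#' unaffected by gradients. Amplitudes shifted beyond `max_order` are dropped.
#'
#' @param state an `epg_state`.
#' @param n_shifts signed integer number of unit shifts; |n| <= max_order.
#' @return The shifted `epg_state`.
#' @export
epg_grad_shift <- function(state, n_shifts) {
  n <- as.integer(n_shifts)
  if (abs(n) > state$max_order) stop("|n_shifts| exceeds max_order")
  if (n == 0L) return(state)
  K <- state$max_order
  if (n < 0L) {
    # mirror: F(k) -> F(k+n) is the conjugate-symmetric image of a +|n| shift
    tmp <- state$Fp; state$Fp <- state$Fm; state$Fm <- tmp
    state <- epg_grad_shift(state, -n)
    tmp <- state$Fp; state$Fp <- state$Fm; state$Fm <- tmp
    return(state)
  }
  Fp <- state$Fp; Fm <- state$Fm
  new_Fp <- complex(K + 1)
  new_Fm <- complex(K + 1)
  # F_new(k) = F_old(k - n)
  if (n <= K) new_Fp[(n + 1):(K + 1)] <- Fp[1:(K + 1 - n)]
  # orders 0..n-1 come from old negative orders -(n-k): F(-(m)) = conj(Fm[m+1])
  new_Fp[1:n] <- Conj(Fm[seq(n + 1, 2, by = -1)])
  if (n <= K) new_Fm[1:(K + 1 - n)] <- Fm[(n + 1):(K + 1)]
  state$Fp <- new_Fp
  state$Fm <- new_Fm
  state
}

#' Coherent flow phase and diffusion damping for one interval
#'
#' A spin cohort moving with velocity v translates the wound configuration
#' patterns, so each order k acquires phase k * dk_per_shift * v * dt (applied
#' to both transverse and longitudinal orders). Diffusion damps each order by
#' exp(-D * kbar^2 * dt) with the order's effective squared dephasing moment:
#' during gradient-off intervals kbar^2 = (k dk)^2; during the gradient-on
#' (hard-gradient) transition from order k to k+1 the standard transition
#' moment (k^2 + k + 1/3) dk^2 is used for transverse states.
#'
#' @param state an `epg_state`.
#' @param v_cm_s cohort velocity (cm/s); may be negative (direction reversal).
#' @param dt_ms interval duration (ms), >= 0.
#' @param tissue a `tissue_params` supplying the diffusion coefficient.
#' @param grad_on logical; if TRUE the interval is the gradient-on period that
#'   effects a +1 shift, and the transverse diffusion moment includes the
#'   transition term.
#' @return The evolved `epg_state` (no relaxation; combine with [epg_relax()]).
#' @export
epg_flow_diffusion <- function(state, v_cm_s, dt_ms, tissue, grad_on = FALSE) {
  stopifnot(dt_ms >= 0)
  if (dt_ms == 0) return(state)
  K <- state$max_order
  k <- 0:K
  dk <- state$dk_per_shift
  v_mm_ms <- v_cm_s * 0.01            # cm/s -> mm/ms
  theta <- k * dk * v_mm_ms * dt_ms   # rad, per order
  ph <- exp(1i * theta)
  D <- tissue$diffusion_mm2_s / 1000  # mm^2/s -> mm^2/ms
  if (grad_on) {
    bT <- (k^2 + k + 1 / 3) * dk^2 * dt_ms
  } else {
    bT <- (k * dk)^2 * dt_ms
  }
  bL <- (k * dk)^2 * dt_ms
  aT <- exp(-D * bT)
  aL <- exp(-D * bL)
  state$Fp <- state$Fp * ph * aT
  state$Fm <- state$Fm * ph * aT   # Fm stores conj(F(-k)): same phase factor
  zk <- state$Z * ph * aL
  # Z(0) must stay real (Z(x) is real-valued); guard against rounding drift
  zk[1] <- complex(real = Re(state$Z[1]) * aL[1], imaginary = 0)
  state$Z <- zk
  state
}

#' Observable transverse signal of an EPG state
#'
#' @param state an `epg_state`.
#' @return The complex F(0) amplitude (the echo/FID-forming coherence).
#' @export
epg_signal <- function(state) state$Fp[1]
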