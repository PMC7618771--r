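#' Sequence event lists
#'
#' Both the EPG engine and the brute-force isochromat oracle consume the same
#' time-ordered tabular event list, so that any convention error in one engine
#' surfaces as a disagreement with the other. Events are rows of a data frame
#' with columns `time_ms`, `event_type`, `p1`, `p2`:
#' \describe{
#'   \item{`rf`}{hard RF pulse; `p1` = flip (deg), `p2` = phase (deg).}
#'   \item{`evolve`}{free interval; `p1` = duration (ms), `p2` = cohort
#'     velocity (cm/s): relaxation, coherent motion and diffusion damping.}
#'   \item{`evolve_g`}{as `evolve` but with the dephasing gradient on, so the
#'     transverse diffusion moment includes the k -> k+1 transition term; by
#'     convention an `evolve_g` is followed by a `shift`.}
#'   \item{`shift`}{impulse dephasing gradient; `p1` = signed unit shifts.}
#'   \item{`sat`}{spatial saturation: all magnetization nulled.}
#'   \item{`echo`}{record the observable transverse signal.}
#' }
#'
#' @param time_ms,event_type,p1,p2 event fields (vectors of equal length).
#' @return An event data frame of class `epg_events`.
#' @export
epg_events <- function(time_ms, event_type, p1 = 0, p2 = 0) {
  n <- length(time_ms)
  df <- data.frame(time_ms = time_ms, event_type = event_type,
                   p1 = rep_len(p1, n), p2 = rep_len(p2, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("epg_events", "data.frame")
  df
}

bind_events <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("epg_events", "data.frame")
  df
}

#' Serialize / read an event list as plain text
#'
#' @param events an `epg_events` data frame.
#' @param file path to a CSV file.
#' @return `read_events` returns the event list; `write_events` its path,
#'   invisibly.
#' @export
write_events <- function(events, file) {
  utils::write.csv(as.data.frame(events), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  epg_events(df$time_ms, df$event_type, df$p1, df$p2)
}

#' Run an event list through the EPG engine
#'
#' @param events an `epg_events` data frame.
#' @param tissue a `tissue_params`.
#' @param max_order truncation order for the state.
#' @param dk_per_shift dephasing increment per unit shift (rad/mm).
#' @param state optional starting `epg_state` (default: thermal equilibrium).
#' @return A list with `echoes` (complex vector, one per `echo` event) and
#'   `state` (the final `epg_state`).
#' @export
run_epg_events <- function(events, tissue, max_order, dk_per_shift,
                           state = NULL) {
  if (is.null(state)) state <- epg_equilibrium(max_order, dk_per_shift)
  type <- events$event_type
  p1 <- events$p1
  p2 <- events$p2
  echoes <- complex(sum(type == "echo"))
  ei <- 0L
  for (i in seq_along(type)) {
    tp <- type[i]
    if (tp == "rf") {
      state <- epg_rf(state, p1[i], p2[i])
    } else if (tp == "evolve" || tp == "evolve_g") {
      state <- epg_relax(state, p1[i], tissue)
      state <- epg_flow_diffusion(state, p2[i], p1[i], tissue,
                                  grad_on = (tp == "evolve_g"))
    } else if (tp == "shift") {
      state <- epg_grad_shift(state, p1[i])
    } else if (tp == "sat") {
      state$Fp[] <- 0i; state$Fm[] <- 0i; state$Z[] <- 0i
    } else if (tp == "echo") {
      ei <- ei + 1L
      echoes[ei] <- epg_signal(state)
    } else stop("unknown event type: ", tp)
  }
  list(echoes = echoes, state = state)
}

#' Isochromat ensemble for brute-force Bloch validation
#'
#' Spatial positions are spread uniformly over one dephasing period
#' 2*pi/dk (so the discrete position average reproduces the configuration-state
#' average exactly up to order aliasing), and each isochromat carries a
#' relative speed factor drawn from the intravoxel velocity distribution:
#' laminar (uniform on [0, 2]) for blood, plug flow with a 10% Gaussian spread
#' for CSF and vessel wall, or exact plug flow (`"plug"`).
#'
#' @param n_positions number of spatial offsets; choose > the largest populated
#'   configuration order to avoid aliasing.
#' @param dk_per_shift dephasing increment (rad/mm) of the matching EPG state.
#' @param distribution intravoxel velocity distribution: `"plug"`, `"laminar"`
#'   or `"gauss10"`.
#' @param n_speeds number of speed samples (1 for plug).
#' @param seed RNG seed for the Gaussian spread.
#' @return An object of class `isochromat_ensemble` with fields
#'   `positions_mm`, `rel_speed`, and `magnetization` (3 x N, columns
#'   (Mx, My, Mz) in M0 units, initialized at equilibrium).
#' @export
isochromat_ensemble <- function(n_positions = 64, dk_per_shift = 1,
                                distribution = c("plug", "laminar", "gauss10"),
                                n_speeds = 1, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_positions >= 1, n_speeds >= 1)
  period <- if (dk_per_shift > 0) 2 * pi / dk_per_shift else 1
  pos <- (seq_len(n_positions) - 0.5) / n_positions * period
  rel <- switch(distribution,
    plug = rep(1, n_speeds),
    laminar = (2 * seq_len(n_speeds) - 1) / n_speeds,  # midpoints of U[0, 2]
    gauss10 = { set.seed(as.integer(seed)); stats::rnorm(n_speeds, 1, 0.1) })
  grid <- expand.grid(pos = pos, rel = rel)
  n <- nrow(grid)
  M <- rbind(numeric(n), numeric(n), rep(1, n))
  structure(list(positions_mm = grid$pos, rel_speed = grid$rel,
                 magnetization = M, dk_per_shift = dk_per_shift),
            class = "isochromat_ensemble")
}

#' Brute-force Bloch oracle
#'
#' Integrates the same event list as [run_epg_events()] by direct per-isochromat
#' Bloch rotations, relaxation and position updates, and returns the
#' ensemble-averaged transverse magnetization at each `echo` event. This is the
#' independent validator for the EPG engine: it shares no code with the
#' configuration-state operators. Diffusion is not represented (use D = 0
#' tissues when comparing engines; diffusion has its own closed-form tests).
#'
#' @param events an `epg_events` data frame.
#' @param tissue a `tissue_params`.
#' @param ensemble an `isochromat_ensemble`.
#' @return A list with `echoes` (complex vector) and `ensemble` (final state).
#' @export
run_isochromat_events <- function(events, tissue, ensemble) {
  n <- length(ensemble$positions_mm)
  if (n == 0L) stop("empty ensemble")
  x <- ensemble$positions_mm
  rel <- ensemble$rel_speed
  M <- ensemble$magnetization
  dk <- ensemble$dk_per_shift
  type <- events$event_type; p1 <- events$p1; p2 <- events$p2
  echoes <- complex(sum(type == "echo"))
  ei <- 0L
  for (i in seq_along(type)) {
    tp <- type[i]
    if (tp == "rf") {
      a <- p1[i] * pi / 180; ph <- p2[i] * pi / 180
      ux <- cos(ph); uy <- sin(ph)
      ca <- cos(a); sa <- sin(a); oc <- 1 - ca
      # Rodrigues rotation by +a about the in-plane axis (ux, uy, 0)
      R <- matrix(c(ca + ux^2 * oc, ux * uy * oc,      uy * sa,
                    ux * uy * oc,   ca + uy^2 * oc,   -ux * sa,
                    -uy * sa,       ux * sa,           ca),
                  3, 3, byrow = TRUE)
      M <- R %*% M
    } else if (tp == "evolve" || tp == "evolve_g") {
      dt <- p1[i]
      e1 <- exp(-dt / tissue$t1_ms); e2 <- exp(-dt / tissue$t2_ms)
      M[1, ] <- M[1, ] * e2
      M[2, ] <- M[2, ] * e2
      M[3, ] <- M[3, ] * e1 + (1 - e1)
      x <- x + p2[i] * rel * 0.01 * dt    # cm/s -> mm/ms
    } else if (tp == "shift") {
      phi <- -p1[i] * dk * x              # gradient impulse phase on M+
      mp <- complex(real = M[1, ], imaginary = M[2, ]) * exp(1i * phi)
      M[1, ] <- Re(mp); M[2, ] <- Im(mp)
    } else if (tp == "sat") {
      M[] <- 0
    } else if (tp == "echo") {
      ei <- ei + 1L
      echoes[ei] <- mean(complex(real = M[1, ], imaginary = M[2, ]))
    } else stop("unknown event type: ", tp)
  }
  ensemble$positions_mm <- x
  ensemble$magnetization <- M
  list(echoes = echoes, ensemble = ensemble)
}
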