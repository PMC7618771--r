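# shared fixtures: small tissues, tiny protocols and event lists built in code

fix_tissue <- function(t1 = 1000, t2 = 100, v = 0, d = 0, name = "t") {
  tissue_params(name, t1, t2, v, d, "custom")
}

# a short DANTE + SPACE protocol that runs in milliseconds
tiny_protocol <- function(n_pulses = 20, flip = 12, etl = 8, esp = 5,
                          tr_s = 0.5, grad = 24, field = "7T") {
  sp <- space_params(tr_s, esp, etl, te_eq_ms = esp * round(etl / 2),
                     flip_train_deg = rep(120, etl))
  protocol("tiny", dante_params(flip, n_pulses, 1, grad, 0.5), sp, field)
}

# random short event list (RF / gradient shifts / free evolution), used by the
# EPG-vs-Bloch equivalence tests
random_events <- function(n_pulses, seed, esp_ms = 1, v_cm_s = 0) {
  set.seed(seed)
  flips <- runif(n_pulses, 5, 170)
  phases <- runif(n_pulses, 0, 360)
  shifts <- sample(c(-1L, 1L, 1L), n_pulses, replace = TRUE)
  dts <- runif(n_pulses, 0.3, esp_ms)
  tj <- cumsum(c(0, dts[-n_pulses]))
  epg_events(
    as.vector(rbind(tj, tj, tj + dts / 2, tj + dts)),
    rep(c("rf", "evolve", "shift", "echo"), n_pulses),
    as.vector(rbind(flips, dts, shifts, rep(0, n_pulses))),
    as.vector(rbind(phases, rep(v_cm_s, n_pulses), rep(0, n_pulses),
                    rep(0, n_pulses))))
}

expect_rel_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
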