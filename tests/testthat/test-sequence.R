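test_that("VFA train realizes its prescribed evolution", {
  vw <- tissue_preset("vw", "7T")
  # etl = 1: the single flip is the configured start flip
  sp1 <- space_params(2, 5, 1, 5)
  expect_equal(as.numeric(vfa_train(vw, sp1, start_flip_deg = 111)), 111)
  # without relaxation, a constant-signal target converges to a constant
  # asymptotic flip (static pseudo-steady state)
  inf <- fix_tissue(1e9, 1e8)
  ft <- vfa_train(inf, space_params(2, 5, 40, 100),
                  target_mode = "constant", start_flip_deg = 60)
  expect_lt(abs(ft[40] - ft[35]), 0.5)
  e <- attr(ft, "echoes")
  expect_equal(e / e[1], rep(1, 40), tolerance = 1e-3)
  # packaged 7T preset train has length 74 (echo train length)
  p7 <- protocol_preset("7T_cp_opt")
  expect_length(p7$space$flip_train_deg, 74)
  # an unsustainably high constant target reports the failing echo index
  expect_error(vfa_train(vw, space_params(2, 5, 20, 50),
                         target_mode = "constant", start_flip_deg = 170),
               "infeasible at echo")
})

test_that("DANTE preparation handles its degenerate cases", {
  vw <- tissue_preset("vw", "7T")
  d0 <- dante_params(12, 0)
  s <- epg_equilibrium(20, 1)
  expect_identical(dante_prep(s, d0, vw), s)
  expect_error(dante_prep(s, dante_params(12, 5), vw, b1_scale = -1), ">= 0")
  # flip 0: pure relaxation + spoiling of pre-existing transverse signal
  sx <- epg_rf(s, 30, 0)
  d <- dante_params(0, 10, 1, 24, 0.5)
  sp <- dante_prep(epg_grad_shift(sx, 0), d, vw)
  expect_equal(Mod(epg_signal(sp)), 0, tolerance = 1e-12)  # shifted away
  expect_gt(Re(sp$Z[1]), Re(sx$Z[1]))                      # T1 recovery
})

test_that("saturation band nulls in-band cohorts and recovers with T1", {
  s <- epg_rf(epg_equilibrium(8), 40, 10)
  expect_identical(apply_sat_band(s, FALSE), s)
  s0 <- apply_sat_band(s, TRUE)
  expect_true(all(Mod(s0$Fp) == 0) && all(Mod(s0$Z) == 0))
  # saturated blood recovering 400 ms with T1 = 1779 ms (3T): closed form
  bl3 <- tissue_preset("blood", "3T")
  sr <- epg_relax(s0, 400, bl3)
  expect_equal(Re(sr$Z[1]), 1 - exp(-400 / 1779), tolerance = 1e-12)
  expect_equal(Re(sr$Z[1]), 0.2015, tolerance = 1e-3)
})

test_that("SPACE readout reproduces CPMG limits and its timing", {
  # all flips 180, no relaxation, static: constant echo amplitudes
  inf <- fix_tissue(1e12, 1e11)
  sp <- space_params(2, 5, 12, 30, flip_train_deg = rep(180, 12))
  st <- epg_equilibrium(30, 1)
  e <- space_readout(st, sp, inf)
  expect_equal(as.numeric(e), rep(e[1], 12), tolerance = 1e-9)
  # static tissue matches the isochromat oracle within 1%
  vw <- tissue_preset("vw", "7T")
  sp2 <- space_params(2, 5, 10, 25, flip_train_deg = seq(150, 60, by = -10))
  ev <- events_space(sp2, NULL, 1, 0)
  epg <- run_epg_events(ev, vw, 25, 1)
  orc <- run_isochromat_events(ev, vw, isochromat_ensemble(64, 1))
  expect_lt(max(Mod(epg$echoes - orc$echoes)) / max(Mod(orc$echoes)), 0.01)
  # 74 echoes at 4.62 ms spacing last 342 ms
  p7 <- protocol_preset("7T_cp_opt")
  expect_equal(p7$space$etl * p7$space$echo_spacing_ms, 341.88,
               tolerance = 1e-9)
})

test_that("simulate_protocol is consistent with a bare SPACE readout", {
  # zero velocity, no DANTE, very long TR: equals the bare echo amplitude
  vw <- tissue_preset("vw", "7T")
  prot <- tiny_protocol(n_pulses = 0, etl = 10, esp = 5, tr_s = 60)
  prot$space$flip_train_deg <- rep(110, 10)
  res <- simulate_protocol(prot, vw, NULL)
  bare <- space_readout(epg_equilibrium(24, dante_dk(prot$dante)),
                        prot$space, vw)
  expect_equal(res$signal, bare[res$echo_index], tolerance = 1e-6)
  # equivalent TE before the first echo is rejected
  expect_error(simulate_protocol(
    protocol("bad", dante_params(12, 0),
             space_params(2, 5, 10, 2, flip_train_deg = rep(100, 10))),
    vw, NULL), "outside the echo train")
})

test_that("second and third TR signals agree (effective steady state)", {
  # constant-velocity CSF so the repetitions are strictly comparable (with
  # pulsatile flow and a TR that is not a multiple of the cardiac period,
  # consecutive repetitions sample different cardiac phases)
  csf <- tissue_preset("csf", "3T")
  wf <- make_waveform("constant", csf$mean_speed_cm_s)
  p <- protocol_preset("3T_opt")
  s2 <- simulate_protocol(p, csf, wf, n_tr = 2)$signal
  s3 <- simulate_protocol(p, csf, wf, n_tr = 3)$signal
  expect_lt(abs(s3 - s2) / s2, 0.01)
})

test_that("more DANTE pulses never increase fast-flowing blood signal", {
  bl <- tissue_preset("blood", "7T")
  wf <- make_waveform("constant", bl$mean_speed_cm_s)
  sig <- vapply(c(0, 50, 100, 170, 250), function(n) {
    prot <- tiny_protocol(n_pulses = n, etl = 10, esp = 5, tr_s = 1.5,
                          grad = 70)
    prot$space$flip_train_deg <- rep(110, 10)
    simulate_protocol(prot, bl, wf)$signal
  }, 0)
  expect_true(all(diff(sig) <= 1e-9))
  expect_true(all(sig >= 0 & sig <= 1))
})

test_that("truncation is converged for the packaged protocols", {
  # doubling max_order changes the reported echo by < 0.1%
  csf3 <- tissue_preset("csf", "3T")
  wf <- make_waveform("csf", csf3$mean_speed_cm_s)
  p <- protocol_preset("3T_opt")
  s1 <- simulate_protocol(p, csf3, wf)$signal
  s2 <- simulate_protocol(p, csf3, wf, max_order_factor = 2)$signal
  expect_lt(abs(s2 - s1) / s1, 1e-3)
})

test_that("contrasts and the SAR proxy are exact arithmetic", {
  s <- signal_set(0.2, 0.05, 0.02)
  ct <- contrasts(s)
  expect_equal(ct$vw_minus_csf, 0.15)
  expect_equal(ct$vw_minus_blood, 0.18)
  s0 <- signal_set(0.1, 0.1, 0.1)
  expect_equal(unlist(contrasts(s0)[1:2]), c(vw_minus_csf = 0, vw_minus_blood = 0))
  # antisymmetry under swapping vw and csf
  sw <- signal_set(0.05, 0.2, 0.02)
  expect_equal(contrasts(sw)$vw_minus_csf, -ct$vw_minus_csf)
  expect_error(signal_set(1.2, 0, 0), "0, 1")
  # SAR proxy: n * flip^2, ratios only
  expect_equal(sar_proxy(dante_params(12, 250)), 36000)
  expect_equal(1 - sar_proxy(dante_params(8, 150)) /
                 sar_proxy(dante_params(12, 250)), 1 - 9600 / 36000)
  expect_equal(sar_proxy(dante_params(9, 400)),
               2 * sar_proxy(dante_params(9, 200)))
})

test_that("csf_reduction is zero without DANTE", {
  p <- tiny_protocol(n_pulses = 0, etl = 8, esp = 5, tr_s = 1, field = "3T")
  p$space$flip_train_deg <- rep(100, 8)
  expect_equal(csf_reduction(p, n_phases = 2), 0, tolerance = 1e-9)
})

test_that("protocol files round-trip and presets match their print", {
  p <- protocol_preset("3T_opt")
  expect_equal(p$space$tr_s, 2.10)
  expect_equal(p$dante$n_pulses, 250L)
  expect_equal(p$dante$flip_deg, 12)
  expect_equal(p$sat_band$slab_mm, 70)
  expect_identical(p$b1_mode, "homogeneous")
  expect_equal(p$b1_scale_prep, 1.0)
  f <- tempfile(fileext = ".ini")
  write_protocol(p, f)
  p2 <- read_protocol(f)
  expect_equal(p2$dante, p$dante)
  expect_equal(p2$space$tr_s, p$space$tr_s)
  expect_equal(p2$space$flip_train_deg, p$space$flip_train_deg,
               tolerance = 1e-6)
  unlink(f)
  # the literature preset refuses to simulate with unset DANTE values
  expect_error(protocol_preset("7T_lit"), "unset DANTE values")
})
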