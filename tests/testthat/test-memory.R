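test_that("hysteresis windows: present for balanced nonlinear CIPF only", {
  pb <- bistable_params()
  hy <- hysteresis_curves("CIPF", pb, fgf_level = 1)
  expect_gt(hy$window_size, 0)
  expect_lt(hy$window_lo, hy$window_hi)
  # branches identical outside the window
  out <- hy$off_curve$dose < hy$window_lo * 0.99 |
    hy$off_curve$dose > hy$window_hi * 1.01
  expect_rel_equal(hy$on_curve$response[out], hy$off_curve$response[out],
                   1e-6)
  # acyclic classes: never
  for (cl in c("STI", "SUI", "CFF"))
    expect_equal(hysteresis_curves(cl, pb, fgf_level = 1)$window_size, 0,
                 label = cl)
  # all-linear CIPF: never
  expect_equal(hysteresis_curves("CIPF", linear_params(0.95),
                                 fgf_level = 1)$window_size, 0)
  # no FGF drive: loop open, no hysteresis
  expect_equal(hysteresis_curves("CIPF", pb, fgf_level = 0)$window_size, 0)
})

test_that("window grows with matched loop strength", {
  wins <- vapply(c(0.85, 0.9, 0.95), function(s) {
    p <- model_params(K_tbt = 0.5, fb_link = inhib_link(s, n = 4),
                      bf_link = inhib_link(s, n = 4))
    hysteresis_curves("CIPF", p, fgf_level = 1)$window_size
  }, numeric(1))
  expect_true(all(diff(wins) > 0))
})

test_that("memory classification separates the three types", {
  expect_equal(classify_memory("CIPF", bistable_params(), 1)$label,
               "hysteretic")
  expect_equal(classify_memory("AUTOREG", autoreg_params(2), 1)$label,
               "irreversible")
  p_off <- bistable_params()
  p_off$fb_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  p_off$bf_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  expect_equal(classify_memory("CIPF", p_off, 1)$label, "none")
})

test_that("CIPF is never irreversible across sampled sets", {
  sets <- sample_parameters(3, 40, seed = 23)
  for (p in sets) {
    m <- classify_memory("CIPF", p, fgf_level = p$K_tf)
    expect_true(m$label != "irreversible")
  }
})

test_that("washout with persistent signalling mimics irreversibility", {
  p <- bistable_params()
  proto <- washout_protocol(prestim_dose = 64, prestim_duration = 2,
                            residual_tau = 100,
                            reapplied_doses = c(0, 0.25, 0.5, 1, 4),
                            readout_time = 12)
  res <- simulate_washout("CIPF", p, proto, fgf_level = 1)
  on <- res[res$initial_state == "on", ]
  off <- res[res$initial_state == "off", ]
  # pre-stimulated cells stay high at every reapplied dose
  expect_true(all(on$response > 0.5 * max(on$response)))
  expect_true(all(on$response > off$response))
})

test_that("washout with receptor inhibitor converges to the hysteresis branches", {
  # finite bistable band [~0.19, ~3.0]: the branches rejoin at high dose
  p <- finite_band_params()
  doses <- c(0, 0.7, 9)
  proto <- washout_protocol(prestim_dose = 100 * p$K_tb,
                            prestim_duration = 60, residual_tau = 1e-6,
                            inhibitor_applied = TRUE,
                            reapplied_doses = doses, readout_time = 600)
  res <- simulate_washout("CIPF", p, proto, fgf_level = 1)
  on <- res[res$initial_state == "on", ]
  off <- res[res$initial_state == "off", ]
  on_ref <- compute_dose_response("CIPF", p, 0.7, 1, "on")$response
  # on-pretreated: follows the on branch inside the band, returns to
  # baseline at zero dose (hysteretic, not irreversible)
  expect_equal(on$response[1], 0, tolerance = 1e-4)
  expect_equal(on$response[2], on_ref, tolerance = 1e-3)
  # inside the band the pretreatments diverge; above it they meet
  expect_gt(on$response[2], off$response[2] * 1.5)
  expect_equal(on$response[3], off$response[3], tolerance = 1e-4)
})

test_that("washout branches coincide for monostable parameters", {
  p <- linear_params()
  proto <- washout_protocol(prestim_dose = 64, prestim_duration = 30,
                            residual_tau = 1e-6, inhibitor_applied = TRUE,
                            reapplied_doses = c(0.2, 1, 5),
                            readout_time = 400)
  res <- simulate_washout("CIPF", p, proto, fgf_level = 1)
  on <- res[res$initial_state == "on", ]
  off <- res[res$initial_state == "off", ]
  expect_rel_equal(on$response, off$response, 1e-4)
})
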