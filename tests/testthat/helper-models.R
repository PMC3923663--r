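# Shared fixtures: representative parameter sets built in code.

# Balanced, strongly nonlinear toggle: bistable at intermediate BMP doses
# under FGF at K_tf.
bistable_params <- function() {
  model_params(K_tbt = 0.5,
               fb_link = inhib_link(0.9, n = 4),
               bf_link = inhib_link(0.9, n = 4))
}

# All-linear balanced links (context-1 style); never bistable.
linear_params <- function(p = 0.88) {
  model_params(K_tbt = 0.5,
               fb_link = inhib_link(p, n = 1),
               bf_link = inhib_link(p, n = 1))
}

# Asymmetric toggle whose bistable dose band is finite (the low state dies
# at saturating BMP): band roughly [0.19, 3.0], race window [0.18, 0.29].
finite_band_params <- function() {
  model_params(K_tbt = 0.5,
               fb_link = inhib_link(0.80, n = 4),
               bf_link = inhib_link(0.90, n = 4))
}

# Auto-regulatory contrast model with strong self-activation on B_I:
# bistable at zero input, hence irreversible once on.
autoreg_params <- function(kc_a = 2) {
  model_params(K_tbt = 0.5,
               fb_link = inhib_link(0.5, n = 1),
               bf_link = inhib_link(0.5, n = 1),
               auto_link = list(kc = kc_a, K = 1, n = 4))
}

# Noiseless Hill curve on a dose grid, as a dose-response data.frame.
hill_curve <- function(ymax, ec50, nH, doses) {
  data.frame(dose = doses, response = ymax / (1 + (ec50 / doses)^nH))
}

expect_rel_equal <- function(a, b, tol) {
  expect_true(all(abs(a - b) <= tol * pmax(abs(b), 1e-12)),
              label = sprintf("max rel err %.3g <= %g",
                              max(abs(a - b) / pmax(abs(b), 1e-12)), tol))
}
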