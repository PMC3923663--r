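test_that("origin is the steady state at zero inputs", {
  p <- bistable_params()
  for (cl in c("STI", "SUI", "CFF", "CIPF")) {
    s <- integrate_to_steady(build_rhs(cl, p), c(0, 0, 0), B = 0, F = 0)
    expect_true(attr(s, "converged"))
    expect_lt(max(abs(s)), 1e-9)
  }
})

test_that("STI saturated fixed point matches the hand-computed value", {
  p <- model_params(kc1 = 2, K_BI = 0.5, kc5 = 3, K_BT = 1.5, K_tbt = 0.8,
                    n3 = 2)
  s <- integrate_to_steady(build_rhs("STI", p), c(0, 0, 0),
                           B = 1e8 * p$K_tb, F = 0)
  b_i_star <- 2 / 0.5
  b_t_star <- 3 / 1.5 * hill_activation(b_i_star, 0.8, 2)
  expect_equal(unname(s[[1]]), b_i_star, tolerance = 1e-6)
  expect_equal(unname(s[[3]]), b_t_star, tolerance = 1e-6)
})

test_that("closed forms agree with numerical steady states", {
  sets <- sample_parameters(4, 12, seed = 31)
  for (cl in c("STI", "SUI", "CFF")) {
    for (p in sets[1:4]) {
      for (B in c(0.2, 1, 5) * p$K_tb) {
        cf <- closed_form_bt(cl, p, B, F = p$K_tf)
        s <- integrate_to_steady(build_rhs(cl, p), c(0, 0, 0),
                                 B = B, F = p$K_tf)
        expect_equal(cf, unname(s[[3]]), tolerance = 1e-6, label = cl)
      }
    }
  }
  expect_error(closed_form_bt("CIPF", sets[[1]], 1, 1))
})

test_that("CFF high-dose asymptote releases the feedforward inhibition", {
  # with saturating B, B_I fully suppresses F_I production, so B_T matches
  # the F = 0 asymptote
  p <- model_params(K_tbt = 0.5, fb_link = inhib_link(0.9, n = 4),
                    bf_link = inhib_link(0.95, n = 4))
  hi <- 1e5 * p$K_tb
  expect_equal(closed_form_bt("CFF", p, hi, F = 1),
               closed_form_bt("CFF", p, hi, F = 0), tolerance = 1e-3)
})

test_that("open-loop characteristic finds the right crossings", {
  # all-linear links: a single crossing over a range of drives
  pl <- linear_params(0.95)
  for (B in c(0.1, 0.5, 1, 4, 20)) {
    ol <- open_loop_characteristic(pl, B = B, F = 1)
    expect_equal(nrow(ol$fixed_points), 1L, label = sprintf("B = %g", B))
    expect_false(ol$bistable)
  }
  # balanced nonlinear links at mid dose: three crossings, outer two stable
  pb <- bistable_params()
  ol <- open_loop_characteristic(pb, B = 0.5, F = 1)
  expect_equal(nrow(ol$fixed_points), 3L)
  expect_equal(ol$fixed_points$stable, c(TRUE, FALSE, TRUE))
  expect_true(ol$bistable)
  # crossing count is odd and stability alternates over a dose scan
  for (B in 10^seq(-2, 2, length.out = 9)) {
    fp <- open_loop_characteristic(pb, B = B, F = 1)$fixed_points
    expect_equal(nrow(fp) %% 2, 1)
    expect_equal(fp$stable, rep(c(TRUE, FALSE), length.out = nrow(fp)))
  }
  # severed feedback: constant return map, single crossing
  p0 <- bistable_params()
  p0$bf_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  ol0 <- open_loop_characteristic(p0, B = 0.5, F = 1)
  expect_equal(nrow(ol0$fixed_points), 1L)
  expect_lt(diff(range(ol0$g_values)), 1e-12)
})

test_that("open-loop bistability matches two-initial-condition integration", {
  pb <- bistable_params()
  ol <- open_loop_characteristic(pb, B = 0.5, F = 1)
  res <- find_all_steady_states("CIPF", pb, B = 0.5, F = 1,
                                method = "integrate")
  expect_equal(nrow(res$states), sum(ol$fixed_points$stable))
  expect_lt(res$residual, 1e-6)
})

test_that("stable-state count is 1 outside and 2 inside the window", {
  # finite bistable band: roughly [0.19, 3.0] on the dose axis
  pb <- finite_band_params()
  n_at <- function(B) sum(open_loop_characteristic(pb, B, 1)$fixed_points$stable)
  expect_equal(n_at(0.7), 2L)
  expect_equal(n_at(0.05), 1L)
  expect_equal(n_at(9), 1L)
  # acyclic classes and CIPF at B = 0: single state
  res_in <- find_all_steady_states("CIPF", pb, B = 0.7, F = 1)
  expect_equal(nrow(res_in$states), 2L)
  for (cl in c("STI", "SUI", "CFF")) {
    res <- find_all_steady_states(cl, pb, B = 0.7, F = 1)
    expect_equal(nrow(res$states), 1L, label = cl)
  }
  res0 <- find_all_steady_states("CIPF", pb, B = 0, F = 1)
  expect_equal(nrow(res0$states), 1L)
  expect_lt(res0$states$B_T, 1e-9)
})
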