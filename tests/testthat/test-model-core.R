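test_that("hill_activation matches its closed form and rejects bad input", {
  expect_equal(hill_activation(1, k = 1, n = 3), 0.5)
  expect_equal(hill_activation(2.7, k = 2.7, n = 1.5), 0.5)
  expect_equal(hill_activation(0, k = 1, n = 2), 0)
  expect_equal(hill_activation(3, k = 1, n = 2), 0.9)
  # monotone in x, antitone in k
  x <- seq(0, 10, length.out = 50)
  expect_true(all(diff(hill_activation(x, 2, 3)) >= 0))
  expect_true(all(hill_activation(1.7, c(1, 2, 4), 2) ==
                    sort(hill_activation(1.7, c(1, 2, 4), 2),
                         decreasing = TRUE)))
  expect_error(hill_activation(1, k = 0, n = 1))
  expect_error(hill_activation(1, k = 1, n = 0.5))
  expect_error(hill_activation(-1, k = 1, n = 1))
})

test_that("inhibition factors behave per form", {
  sat <- inhib_link(0.88, k = 1, n = 1, form = "saturating")
  expect_equal(inhibition_factor(0, sat), 1)
  expect_equal(inhibition_factor(1, sat), 1 - 0.88 * 0.5)  # 0.56
  expect_equal(inhibition_factor(1e12, sat), 0.12, tolerance = 1e-9)
  div <- inhib_link(0.88, n = 1)  # k = (1-p)/p
  expect_equal(inhibition_factor(0, div), 1)
  expect_equal(inhibition_factor(1, div), 0.12)  # strength at unit level
  expect_lt(inhibition_factor(100, div), 0.002)  # unbounded suppression
  x <- seq(0, 5, length.out = 30)
  expect_true(all(diff(inhibition_factor(x, div)) <= 0))
  expect_error(inhib_link(1.2))
  expect_error(inhib_link(0.5, k = -1))
})

test_that("representative rhs agrees with term-by-term evaluation", {
  p <- model_params(kc1 = 1.3, kc3 = 0.8, kc5 = 2, K_tb = 1.5, K_tf = 0.7,
                    K_tbt = 0.4, K_BI = 1.1, K_FI = 0.9, K_BT = 1.2,
                    n1 = 2, n2 = 1, n3 = 3,
                    fb_link = inhib_link(0.8, k = 0.3, n = 2),
                    bf_link = inhib_link(0.7, k = 0.5, n = 4))
  st <- c(B_I = 0.4, F_I = 0.25, B_T = 0.6)
  B <- 2; F <- 1.4
  h <- function(x, k, n) x^n / (k^n + x^n)
  fac_fb <- inhibition_factor(st[["F_I"]], p$fb_link)
  fac_bf <- inhibition_factor(st[["B_I"]], p$bf_link)
  expected <- list(
    STI = c(1.3 * h(B, 1.5, 2) - 1.1 * 0.4,
            0.8 * h(F, 0.7, 1) - 0.9 * 0.25,
            2 * h(0.4, 0.4, 3) * fac_fb - 1.2 * 0.6),
    SUI = c(1.3 * h(B, 1.5, 2) * fac_fb - 1.1 * 0.4,
            0.8 * h(F, 0.7, 1) - 0.9 * 0.25,
            2 * h(0.4, 0.4, 3) - 1.2 * 0.6),
    CFF = c(1.3 * h(B, 1.5, 2) - 1.1 * 0.4,
            0.8 * h(F, 0.7, 1) * fac_bf - 0.9 * 0.25,
            2 * h(0.4, 0.4, 3) * fac_fb - 1.2 * 0.6),
    CIPF = c(1.3 * h(B, 1.5, 2) * fac_fb - 1.1 * 0.4,
             0.8 * h(F, 0.7, 1) * fac_bf - 0.9 * 0.25,
             2 * h(0.4, 0.4, 3) - 1.2 * 0.6))
  for (cl in names(expected)) {
    rhs <- build_rhs(cl, p)
    expect_equal(unname(rhs(st, B, F)), expected[[cl]], tolerance = 1e-12,
                 label = cl)
  }
  # zero inputs, zero state: origin is a fixed point
  expect_equal(unname(build_rhs("CIPF", p)(c(0, 0, 0), 0, 0)), c(0, 0, 0))
  # STI production-only start
  d0 <- build_rhs("STI", p)(c(0, 0, 0), B = 2, F = 0)
  expect_equal(d0[["B_I"]], 1.3 * h(2, 1.5, 2))
  expect_gt(d0[["B_I"]], 0)
})

test_that("topology rhs reproduces the representative models", {
  p <- bistable_params()
  rhs_rep <- build_rhs("CIPF", p)
  top <- topology(1, 1, 1, 1)  # F_I -| B_I, B_I -| F_I
  expect_equal(top$class_label, "CIPF")
  rhs_top <- build_topology_rhs(top, p)
  st <- c(0.3, 0.2, 0.1, 0.05)
  d_rep <- rhs_rep(st[1:3], B = 1.2, F = 0.8)
  d_top <- rhs_top(st, B = 1.2, F = 0.8)
  expect_equal(unname(d_top[1:3]), unname(d_rep), tolerance = 1e-12)
})

test_that("links to F_T cannot influence B_T", {
  # F_I -| B_T with B -> F link landing on F_T: B_T dynamics identical to STI
  p <- linear_params()
  top <- topology(1, 2, 1, 2)   # F_I -| B_T ; B_I -| F_T
  expect_equal(top$class_label, "STI")
  rhs_top <- build_topology_rhs(top, p)
  rhs_sti <- build_rhs("STI", p)
  s <- integrate_to_steady(rhs_top, c(0, 0, 0, 0), B = 2, F = 1)
  s_ref <- integrate_to_steady(rhs_sti, c(0, 0, 0), B = 2, F = 1)
  expect_equal(unname(s[[3]]), unname(s_ref[[3]]), tolerance = 1e-8)
})

test_that("deleting a downstream-targeted B->F link leaves B_T unchanged", {
  p <- linear_params()
  # B->F link targets F_T (tier 2), downstream of the F->B source F_I:
  # disabling it must not move the B_T steady state
  top <- topology(1, 1, 1, 2)
  expect_equal(top$class_label, "SUI")
  p_cut <- p; p_cut$bf_link <- inhib_link(0, k = 1, n = 1,
                                          form = "saturating")
  for (B in c(0.5, 2, 8)) {
    s1 <- integrate_to_steady(build_topology_rhs(top, p), c(0, 0, 0, 0),
                              B = B, F = 1)
    s2 <- integrate_to_steady(build_topology_rhs(top, p_cut), c(0, 0, 0, 0),
                              B = B, F = 1)
    expect_equal(unname(s1[[3]]), unname(s2[[3]]), tolerance = 1e-8)
  }
})

test_that("trajectories stay non-negative", {
  p <- bistable_params()
  rhs <- build_rhs("CIPF", p)
  sol <- deSolve::ode(y = c(B_I = 0, F_I = 0.9, B_T = 0),
                      times = seq(0, 50, by = 0.5),
                      func = function(t, y, pp) list(rhs(y, 1.5, 1)),
                      parms = NULL)
  expect_true(all(sol[, -1] >= -1e-10))
})

test_that("nondimensionalisation preserves response shape and rescales max", {
  p <- model_params(kc1 = 3, K_BI = 0.7, kc3 = 2, K_FI = 1.3, kc5 = 5,
                    K_BT = 2, K_tbt = 1.1, n1 = 2, n3 = 2,
                    fb_link = inhib_link(0.8, n = 2),
                    bf_link = inhib_link(0.7, n = 2))
  nd <- nondimensionalize(p)
  expect_equal(nd$kc5, 1)
  expect_equal(nd$K_BT, 1)
  f1 <- fit_hill(compute_dose_response("CIPF", p, fgf_level = 2))
  f2 <- fit_hill(compute_dose_response("CIPF", nd, fgf_level = 2))
  expect_equal(f1$nH, f2$nH, tolerance = 1e-6)
  expect_equal(f1$ec50, f2$ec50, tolerance = 1e-6)
  expect_equal(max_asymptotic("CIPF", p, 2),
               max_asymptotic("CIPF", nd, 2) * p$kc5 / p$K_BT,
               tolerance = 1e-9)
  # already-scaled parameters are unchanged on the B_T equation
  p0 <- model_params()
  nd0 <- nondimensionalize(p0)
  expect_equal(nd0$kc5, p0$kc5)
  expect_equal(nd0$K_tbt, p0$K_tbt)
})

test_that("removing both links reduces every class to the BMP core pathway", {
  p <- bistable_params()
  p$fb_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  p$bf_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  doses <- default_dose_grid(p, n = 10)
  core <- closed_form_bt("STI", p, doses, F = 0)
  for (cl in c("STI", "SUI", "CFF", "CIPF")) {
    dr <- compute_dose_response(cl, p, doses, fgf_level = 1)
    expect_rel_equal(dr$response, core, 1e-8)
  }
})

test_that("CIPF reduces to SUI when the B->F link is removed", {
  p <- bistable_params()
  p$bf_link <- inhib_link(0, k = 1, n = 1, form = "saturating")
  doses <- default_dose_grid(p, n = 12)
  cipf <- compute_dose_response("CIPF", p, doses, fgf_level = 1)
  sui <- compute_dose_response("SUI", p, doses, fgf_level = 1)
  expect_rel_equal(cipf$response, sui$response, 1e-6)
})

test_that("parameter sets round-trip through flat records and files", {
  p <- bistable_params()
  expect_equal(params_unflatten(params_flatten(p)), p)
  pa <- autoreg_params()
  expect_equal(params_unflatten(params_flatten(pa)), pa)
  tmp_json <- tempfile(fileext = ".json")
  tmp_csv <- tempfile(fileext = ".csv")
  write_params(list(p, pa), tmp_json)
  write_params(list(p, pa), tmp_csv)
  expect_equal(read_params(tmp_json), list(p, pa))
  back <- read_params(tmp_csv)
  expect_equal(params_flatten(back[[1]]), params_flatten(p))
  unlink(c(tmp_json, tmp_csv))
})
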