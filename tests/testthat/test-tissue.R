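test_that("threshold length scale matches its closed form", {
  expect_equal(threshold_lengthscale(22, 32, 100), 100 / log(32 / 22))
  expect_equal(round(threshold_lengthscale(22, 32, 100), -1), 270)
  expect_equal(threshold_lengthscale(3, 3 * exp(1), 57), 57)
  expect_equal(threshold_lengthscale(1, 2, 100), 100 / log(2))
  expect_error(threshold_lengthscale(5, 5, 10))
  expect_error(threshold_lengthscale(8, 3, 10))
})

test_that("exponential gradient fitting recovers noiseless parameters", {
  x <- seq(0, 900, length.out = 15)
  c_true <- 10 * exp(-x / 290) + 1
  f <- fit_exponential_gradient(x, c_true)
  expect_true(f$ok)
  expect_equal(f$A, 10, tolerance = 1e-6)
  expect_equal(f$lambda, 290, tolerance = 1e-6)
  expect_equal(f$b, 1, tolerance = 1e-6)
  # background-free profile: lambda equals -1/slope of log c
  c0 <- 5 * exp(-x / 150)
  f0 <- fit_exponential_gradient(x, c0)
  expect_equal(f0$lambda, -1 / coef(lm(log(c0) ~ x))[[2]], tolerance = 1e-6)
  # flat profile (background dominates): flagged non-identifiable
  expect_false(fit_exponential_gradient(x, 100 + 0.1 * exp(-x / 290))$ok)
})

test_that("two points read off a clean exponential return its length scale", {
  g <- gradient_profile(A = 40, lambda = 335)
  x1 <- 120; x2 <- 470
  expect_equal(threshold_lengthscale(g(x2), g(x1), x2 - x1), 335,
               tolerance = 1e-9)
})

test_that("equivalence point sits at the symmetry midpoint", {
  p <- bistable_params()
  L <- 1000
  bg <- gradient_profile(A = 50, lambda = 270, L = L, decreasing = FALSE)
  fg <- gradient_profile(A = 50, lambda = 270)
  expect_equal(equivalence_point(bg, fg, p, L), L / 2, tolerance = 1e-6)
  # uniform FGF, exponential BMP: closed-form crossing position
  fg_u <- gradient_profile(A = 1e-9, lambda = 1, b = 5)
  bg2 <- gradient_profile(A = 50, lambda = 300, L = L, decreasing = FALSE)
  # drives equal where B(x) = F level (symmetric kinetics, equal half-sats)
  x_expect <- L - 300 * log(50 / 5)
  expect_equal(equivalence_point(bg2, fg_u, p, L), x_expect,
               tolerance = 1e-6)
  fg_none <- gradient_profile(A = 1e-12, lambda = 1)
  expect_error(equivalence_point(bg2, fg_none, p, L))
})

test_that("toggle border lands on the equivalence point", {
  p <- bistable_params()
  L <- 1000
  bg <- gradient_profile(A = 50, lambda = 270, L = L, decreasing = FALSE)
  fg <- gradient_profile(A = 30, lambda = 350)
  tis <- simulate_tissue("CIPF", p, bg, fg, L, n_cells = 150)
  eq <- equivalence_point(bg, fg, p, L)
  expect_lt(abs(tis$border - eq), tis$cell_spacing)
})

test_that("uniform zero FGF reduces the tissue to the core dose response", {
  p <- bistable_params()
  L <- 800; lam <- 100; A <- 20
  bg <- gradient_profile(A = A, lambda = lam, L = L, decreasing = FALSE)
  fg <- gradient_profile(A = 1e-15, lambda = 1)
  tis <- simulate_tissue("CIPF", p, bg, fg, L, n_cells = 160)
  # predicted border: where the BMP-alone steady response crosses half the
  # response at the BMP-rich end
  resp <- function(B) closed_form_bt("STI", p, B, F = 0)  # core pathway
  half <- resp(A) / 2
  B_half <- uniroot(function(B) resp(B) - half, c(1e-6, A))$root
  x_pred <- L + lam * log(B_half / A)
  expect_lt(abs(tis$border - x_pred), 2 * tis$cell_spacing)
})

test_that("pattern scales with proportional tissue and gradient scaling", {
  p <- bistable_params()
  L <- 1000
  bg <- gradient_profile(A = 50, lambda = 270, L = L, decreasing = FALSE)
  fg <- gradient_profile(A = 30, lambda = 350)
  st <- scaling_test("CIPF", p, bg, fg, L, scales = c(0.5, 1, 2),
                     n_cells = 150)
  spacing_rel <- 1 / 149
  expect_lt(attr(st, "max_deviation"), spacing_rel)
  expect_equal(st$relative_border[st$scale == 1],
               st$relative_border[st$scale == 2], tolerance = spacing_rel)
  # negative control: scaling the tissue but not the gradients shifts x/L
  neg <- scaling_test("CIPF", p, bg, fg, L, scales = c(0.5, 1, 2),
                      n_cells = 150, scale_gradients = FALSE)
  expect_gt(attr(neg, "max_deviation"), 10 * spacing_rel)
})

test_that("two loop variants produce ordered borders consistent with EC50s", {
  p <- bistable_params()
  dm <- dual_loop_model(p, loop_deltas = c(fb_p = 1.5))
  r <- dual_ec50_analysis(dm, fgf_level = 1)
  L <- 1000
  bg <- gradient_profile(A = 50, lambda = 270, L = L, decreasing = FALSE)
  fg <- gradient_profile(A = 30, lambda = 350)
  t1 <- simulate_tissue("CIPF", dm$params1, bg, fg, L, n_cells = 150)
  t2 <- simulate_tissue("CIPF", dm$params2, bg, fg, L, n_cells = 150)
  expect_gt(abs(t2$border - t1$border), t1$cell_spacing)
  # higher EC50 -> border closer to the BMP source (smaller target domain,
  # larger x on the axis where BMP rises towards L)
  expect_equal(r$ec50_ratio > 1, t2$border > t1$border)
})

test_that("dual-loop EC50 dissociation: loop-level shifts, downstream does not", {
  p <- bistable_params()
  expect_equal(unlist(dual_ec50_analysis(dual_loop_model(p),
                                         fgf_level = 1)[c("ec50_ratio",
                                                          "max_ratio")]),
               c(ec50_ratio = 1, max_ratio = 1))
  down <- dual_ec50_analysis(dual_loop_model(p,
                                             downstream_deltas = c(kc5 = 2)),
                             fgf_level = 1)
  expect_equal(down$ec50_ratio, 1, tolerance = 0.01)
  expect_equal(down$max_ratio, 2, tolerance = 0.01)
  loop <- dual_ec50_analysis(dual_loop_model(p, loop_deltas = c(bf_p = 2)),
                             fgf_level = 1)
  expect_gt(abs(loop$ec50_ratio - 1), 0.05)
  expect_error(dual_loop_model(p, loop_deltas = c(kc5 = 2)))
  expect_error(dual_loop_model(p, downstream_deltas = c(fb_p = 2)))
})
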