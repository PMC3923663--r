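# Dose-response generation and characterisation (max level, EC50, apparent
# Hill coefficient nH), and the with/without-FGF property ratios that
# discriminate the model classes.

#' Default log-spaced BMP dose grid
#'
#' 40 log-spaced doses over `[K_tb/100, 100 * K_tb]`, wide enough to resolve
#' apparent Hill coefficients up to ~10.
#'
#' @param params An [model_params()] object (only `K_tb` is used).
#' @param n Number of doses.
#' @param span Decades either side of `K_tb`.
#' @return Strictly increasing numeric vector of doses.
#' @export
default_dose_grid <- function(params, n = 40L, span = 2) {
  10^seq(log10(params$K_tb) - span, log10(params$K_tb) + span, length.out = n)
}

#' Steady-state BMP dose-response of a model
#'
#' Computes steady B_T at each dose at a fixed FGF level. The branch is
#' selected by `init_policy`: `"off"` starts every dose from the zero state
#' (nothing expressed; in multistable regimes the outcome is the winner of
#' the kinetic race between the two pathways, found by integration), `"on"`
#' follows the branch continued down from the saturating-BMP pre-stimulus
#' state.
#'
#' `method = "auto"` (default) uses analytic fixed points wherever the
#' steady state is unique and integrates the ODE from the protocol's initial
#' state only in multistable regimes (the on branch uses the monotone
#' largest-fixed-point continuation when the pre-stimulus lands on the high
#' state). `method = "ode"` integrates every dose and exists as an
#' independent cross-check.
#'
#' @param model_class Model class label.
#' @param params An [model_params()] object.
#' @param dose_grid Strictly increasing BMP doses; default
#'   [default_dose_grid()].
#' @param fgf_level FGF concentration (scalar, >= 0).
#' @param init_policy `"off"` or `"on"`.
#' @param method `"auto"` or `"ode"`.
#' @return An object of class `"ms_dose_response"`: data.frame with columns
#'   `dose`, `response` and attributes `fgf_level`, `init_policy`,
#'   `model_class`.
#' @export
compute_dose_response <- function(model_class, params, dose_grid = NULL,
                                  fgf_level = 0,
                                  init_policy = c("off", "on"),
                                  method = c("auto", "ode")) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  init_policy <- match.arg(init_policy)
  method <- match.arg(method)
  if (is.null(dose_grid)) dose_grid <- default_dose_grid(params)
  stopifnot(all(diff(dose_grid) > 0), all(dose_grid >= 0), fgf_level >= 0)
  resp <- if (method == "auto") {
    top_high <- if (init_policy == "on")
      prestim_lands_high(model_class, params, fgf_level) else NA
    vapply(dose_grid, function(d)
      branch_bt(model_class, params, d, fgf_level, init_policy, top_high),
      numeric(1))
  } else {
    ode_branch_response(model_class, params, dose_grid, fgf_level, init_policy)
  }
  structure(data.frame(dose = dose_grid, response = resp),
            fgf_level = fgf_level, init_policy = init_policy,
            model_class = model_class, class = c("ms_dose_response",
                                                 "data.frame"))
}

# Does the saturating-BMP pre-stimulus (zero state, 100 x K_tb) land on the
# high branch? Decides whether the on branch follows the upper fixed-point
# continuation or collapses onto the off branch.
prestim_lands_high <- function(model_class, params, fgf_level) {
  fps <- steady_states_analytic(model_class, params, B = 100 * params$K_tb,
                                F = fgf_level)
  fps <- fps[fps$stable, , drop = FALSE]
  if (nrow(fps) == 1L) return(TRUE)
  out <- race_outcome(model_class, params, B = 100 * params$K_tb,
                      F = fgf_level, fps = fps)
  out$B_I >= max(fps$B_I) * (1 - 1e-6)
}

# Single-dose branch-selected steady B_T. Off: zero-init outcome (analytic
# when unique, integrated race otherwise). On: largest stable fixed point
# when the pre-stimulus landed high, else identical to off.
branch_bt <- function(model_class, params, dose, fgf_level, init_policy,
                      top_high = NA) {
  fps <- steady_states_analytic(model_class, params, B = dose, F = fgf_level)
  fps <- fps[fps$stable, , drop = FALSE]
  if (nrow(fps) == 1L) return(fps$B_T)
  if (init_policy == "on") {
    if (is.na(top_high))
      top_high <- prestim_lands_high(model_class, params, fgf_level)
    if (top_high) return(fps$B_T[which.max(fps$B_I)])
  }
  race_outcome(model_class, params, dose, fgf_level, fps = fps)$B_T
}

# Pure-ODE branch following (independent cross-check). Off: each dose
# integrated from the zero state. On: descending continuation from the
# saturating-BMP pre-stimulus state.
ode_branch_response <- function(model_class, params, dose_grid, fgf_level,
                                init_policy) {
  rhs <- build_rhs(model_class, params)
  n <- length(dose_grid)
  resp <- numeric(n)
  if (init_policy == "off") {
    init <- init_state(model_class, params, fgf_level, "off")
    for (i in seq_len(n)) {
      s <- integrate_to_steady(rhs, init, B = dose_grid[i], F = fgf_level)
      if (!attr(s, "converged"))
        stop("non-convergence at dose index ", i, " (dose ", dose_grid[i], ")")
      resp[i] <- s[[3]]
    }
  } else {
    state <- init_state(model_class, params, fgf_level, "on")
    for (i in rev(seq_len(n))) {
      state <- integrate_to_steady(rhs, state, B = dose_grid[i],
                                   F = fgf_level)
      if (!attr(state, "converged"))
        stop("non-convergence at dose index ", i, " (dose ", dose_grid[i], ")")
      resp[i] <- state[[3]]
    }
  }
  resp
}

#' Fit a Hill equation to a dose-response curve
#'
#' Bounded least-squares fit of `y = ymax * d^nH / (ec50^nH + d^nH)` with
#' three restarts (`nH` started at 1, 2 and 4; `ec50` at the interpolated
#' half-maximum crossing), keeping the lowest residual sum of squares. Flat
#' or all-zero curves are flagged as degenerate and not fit.
#'
#' @param dr An `"ms_dose_response"` or a data.frame with `dose` and
#'   `response` columns (>= 6 points spanning the transition).
#' @return Object of class `"ms_hill_fit"`: list with `ymax`, `ec50`, `nH`,
#'   `rss`, `ok` (FALSE when degenerate, unconverged, or relative RMS
#'   residual > 5% of the fitted maximum).
#' @export
fit_hill <- function(dr) {
  d <- dr$dose; y <- dr$response
  stopifnot(length(d) >= 6, all(d > 0))
  out <- list(ymax = NA_real_, ec50 = NA_real_, nH = NA_real_,
              rss = NA_real_, ok = FALSE)
  class(out) <- "ms_hill_fit"
  ymax0 <- max(y)
  if (ymax0 <= 0 || (ymax0 - min(y)) < 1e-3 * ymax0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ec0 <- half_max_crossing(d, y)
  df <- data.frame(d = d, y = y)
  best <- NULL
  for (n0 in c(1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ymax / (1 + (ec50 / d)^nH), data = df,
                        start = list(ymax = ymax0, ec50 = ec0, nH = n0),
                        lower = c(ymax = 1e-12, ec50 = min(d), nH = 0.05),
                        upper = c(ymax = 10 * ymax0, ec50 = max(d), nH = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)), rss = rss)
  }
  if (is.null(best)) return(out)
  out$ymax <- best$ymax; out$ec50 <- best$ec50; out$nH <- best$nH
  out$rss <- best$rss
  out$ok <- sqrt(best$rss / length(y)) / best$ymax <= 0.05
  out
}

# Interpolated dose at which the response first crosses half its maximum.
half_max_crossing <- function(d, y) {
  half <- max(y) / 2
  i <- which(y >= half)[1]
  if (is.na(i) || i == 1L) return(d[1])
  # linear interpolation in log-dose
  f <- (half - y[i - 1]) / (y[i] - y[i - 1])
  10^(log10(d[i - 1]) + f * (log10(d[i]) - log10(d[i - 1])))
}

#' @export
print.ms_hill_fit <- function(x, ...) {
  if (!is.na(x$ymax))
    cat(sprintf("Hill fit: ymax = %.4g, EC50 = %.4g, nH = %.3g (rss %.3g, %s)\n",
                x$ymax, x$ec50, x$nH, x$rss, if (x$ok) "ok" else "flagged"))
  else cat("Hill fit: degenerate/failed\n")
  invisible(x)
}

#' @export
coef.ms_hill_fit <- function(object, ...) {
  c(ymax = object$ymax, ec50 = object$ec50, nH = object$nH)
}

#' @export
predict.ms_hill_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$dose else newdata
  object$ymax / (1 + (object$ec50 / d)^object$nH)
}

#' Asymptotic maximal B_T response
#'
#' Steady B_T at an extremely high BMP dose (`1e4 * K_tb`), capturing the
#' asymptotic maximum rather than the largest value on a finite grid.
#'
#' @inheritParams compute_dose_response
#' @return Scalar response value.
#' @export
max_asymptotic <- function(model_class, params, fgf_level = 0) {
  branch_bt(model_class, params, dose = 1e4 * params$K_tb,
            fgf_level = fgf_level, init_policy = "off")
}

#' Response-property changes upon FGF addition
#'
#' Fits the BMP dose-response with and without FGF and reports the three
#' ratios (with FGF / without FGF) of maximal level (asymptotic), EC50 and
#' apparent Hill coefficient. The off-branch curve is used.
#'
#' @inheritParams compute_dose_response
#' @param dose_grid Dose grid passed to [compute_dose_response()].
#' @return Object of class `"ms_response_change"`: list with `max_ratio`,
#'   `ec50_ratio`, `nh_ratio` and the two `"ms_hill_fit"` objects.
#' @export
response_change <- function(model_class, params, fgf_level,
                            dose_grid = NULL) {
  dr0 <- compute_dose_response(model_class, params, dose_grid, fgf_level = 0)
  dr1 <- compute_dose_response(model_class, params, dose_grid,
                               fgf_level = fgf_level)
  f0 <- fit_hill(dr0); f1 <- fit_hill(dr1)
  if (is.na(f0$nH) || is.na(f1$nH))
    stop("Hill fit failed for ", model_class, " response")
  m0 <- max_asymptotic(model_class, params, 0)
  m1 <- max_asymptotic(model_class, params, fgf_level)
  structure(list(max_ratio = m1 / m0, ec50_ratio = f1$ec50 / f0$ec50,
                 nh_ratio = f1$nH / f0$nH, fit_no_fgf = f0, fit_fgf = f1),
            class = "ms_response_change")
}

#' @export
print.ms_response_change <- function(x, ...) {
  cat(sprintf("FGF-addition response change: max x%.3g, EC50 x%.3g, nH x%.3g\n",
              x$max_ratio, x$ec50_ratio, x$nh_ratio))
  invisible(x)
}
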