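# Hysteresis protocols: on/off-branch dose responses, bistability-window
# measurement, washout-paradigm simulation with persistent ligand signalling,
# and reversibility classification against the auto-regulatory contrast model.

#' On- and off-branch dose responses and the bistability window
#'
#' Computes the BMP dose-response twice -- started from the zero-BMP ("off")
#' steady state and continued down from the saturating-BMP ("on") state --
#' and measures the hysteresis window: the maximal dose interval over which
#' the two branches differ by more than 1% relative. Window edges found on
#' the grid are refined by bisection between the bracketing doses.
#'
#' @inheritParams compute_dose_response
#' @param rel_tol Relative branch-difference threshold defining the window.
#' @return Object of class `"ms_hysteresis"`: list with `off_curve`,
#'   `on_curve` (both `"ms_dose_response"`), `window_lo`, `window_hi`,
#'   `window_size` (`window_hi - window_lo` in dose units; 0 if none).
#' @export
hysteresis_curves <- function(model_class, params, dose_grid = NULL,
                              fgf_level = 0, method = c("auto", "ode"),
                              rel_tol = 0.01) {
  method <- match.arg(method)
  if (is.null(dose_grid)) dose_grid <- default_dose_grid(params)
  off <- compute_dose_response(model_class, params, dose_grid, fgf_level,
                               init_policy = "off", method = method)
  on <- compute_dose_response(model_class, params, dose_grid, fgf_level,
                              init_policy = "on", method = method)
  top_high <- if (method == "auto")
    prestim_lands_high(model_class, params, fgf_level) else NA
  differs <- branch_differs(off$response, on$response, rel_tol)
  if (!any(differs)) {
    win <- c(lo = 0, hi = 0)
  } else {
    idx <- range(which(differs))
    split_at <- function(i_out, i_in) {
      # bisect between a non-differing and a differing dose
      if (i_out < 1 || i_out > length(dose_grid)) return(dose_grid[i_in])
      lo <- dose_grid[min(i_out, i_in)]; hi <- dose_grid[max(i_out, i_in)]
      for (k in 1:12) {
        mid <- sqrt(lo * hi)
        db <- single_dose_branches(model_class, params, mid, fgf_level,
                                   method, top_high)
        dd <- branch_differs(db["off"], db["on"], rel_tol)
        if (i_out < i_in) { if (dd) hi <- mid else lo <- mid }
        else { if (dd) lo <- mid else hi <- mid }
      }
      sqrt(lo * hi)
    }
    win <- c(lo = split_at(idx[1] - 1L, idx[1]),
             hi = split_at(idx[2] + 1L, idx[2]))
  }
  structure(list(off_curve = off, on_curve = on,
                 window_lo = unname(win["lo"]), window_hi = unname(win["hi"]),
                 window_size = unname(win["hi"] - win["lo"])),
            class = "ms_hysteresis")
}

branch_differs <- function(off, on, rel_tol) {
  ref <- pmax(abs(on), abs(off))
  abs(on - off) > rel_tol * pmax(ref, 1e-12) & ref > 1e-12
}

single_dose_branches <- function(model_class, params, dose, fgf_level,
                                 method = "auto", top_high = NA) {
  if (method == "auto") {
    c(off = branch_bt(model_class, params, dose, fgf_level, "off"),
      on = branch_bt(model_class, params, dose, fgf_level, "on", top_high))
  } else {
    rhs <- build_rhs(model_class, params)
    s_off <- integrate_to_steady(rhs, init_state(model_class, params,
                                                 fgf_level, "off"),
                                 B = dose, F = fgf_level)
    s_on <- integrate_to_steady(rhs, init_state(model_class, params,
                                                fgf_level, "on"),
                                B = dose, F = fgf_level)
    c(off = s_off[[3]], on = s_on[[3]])
  }
}

#' @export
print.ms_hysteresis <- function(x, ...) {
  if (x$window_size > 0)
    cat(sprintf("hysteresis: bistable window [%.4g, %.4g] (width %.4g)\n",
                x$window_lo, x$window_hi, x$window_size))
  else cat("hysteresis: none (identical on/off branches)\n")
  invisible(x)
}

#' Classify the memory type of a model
#'
#' Drives the system to its "on" state at saturating BMP, removes BMP (dose
#' 0, FGF held), and classifies the long-horizon outcome: `"irreversible"`
#' when B_T stays above 10x the off-state baseline, `"hysteretic"` when B_T
#' returns to baseline but the dose response is branch-dependent somewhere,
#' `"none"` otherwise.
#'
#' @inheritParams compute_dose_response
#' @return Object of class `"ms_memory"`: list with `label`, `final_bt`,
#'   `baseline_bt`, `window_size`.
#' @export
classify_memory <- function(model_class, params, fgf_level = 0) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  rhs <- build_rhs(model_class, params)
  on0 <- init_state(model_class, params, fgf_level, "on")
  s <- integrate_to_steady(rhs, on0, B = 0, F = fgf_level)
  baseline <- branch_bt(model_class, params, dose = 0,
                        fgf_level = fgf_level, init_policy = "off")
  tol <- 1e-6 * params$kc5 / params$K_BT
  irreversible <- s[[3]] > 10 * baseline + tol
  label <- if (irreversible) "irreversible" else {
    hy <- hysteresis_curves(model_class, params, fgf_level = fgf_level)
    if (hy$window_size > 0) "hysteretic" else "none"
  }
  structure(list(label = label, final_bt = unname(s[[3]]),
                 baseline_bt = baseline,
                 window_size = if (irreversible) NA_real_ else hy$window_size),
            class = "ms_memory")
}

#' @export
print.ms_memory <- function(x, ...) {
  cat("memory class:", x$label, "\n")
  invisible(x)
}

#' Washout protocol description
#'
#' Parameters of the in-silico analogue of the BMP washout experiments:
#' cells are pre-stimulated (or not) with a high BMP dose, the ligand is
#' washed out, a test dose is reapplied, and the target is read out later.
#' Receptor-bound BMP dissociates slowly, so signalling decays with time
#' constant `residual_tau` after washout unless a BMP-receptor inhibitor is
#' co-applied (which zeroes the residual immediately).
#'
#' @param prestim_dose Pre-stimulus BMP dose (e.g. 64 ng/ml-equivalent).
#' @param prestim_duration Duration of the pre-stimulus, > 0.
#' @param residual_tau Decay time constant of post-washout residual
#'   signalling, > 0.
#' @param inhibitor_applied If TRUE, residual signalling is cut to zero at
#'   washout.
#' @param reapplied_doses Doses reapplied after washout.
#' @param readout_time Absolute time of readout (from the start of the
#'   pre-stimulus), > `prestim_duration`.
#' @return Object of class `"ms_washout_protocol"`.
#' @export
washout_protocol <- function(prestim_dose, prestim_duration, residual_tau,
                             inhibitor_applied = FALSE,
                             reapplied_doses, readout_time) {
  stopifnot(prestim_dose >= 0, prestim_duration > 0, residual_tau > 0,
            all(reapplied_doses >= 0))
  if (readout_time <= prestim_duration)
    stop("readout_time must lie after the washout (prestim_duration)")
  structure(list(prestim_dose = prestim_dose,
                 prestim_duration = prestim_duration,
                 residual_tau = residual_tau,
                 inhibitor_applied = inhibitor_applied,
                 reapplied_doses = reapplied_doses,
                 readout_time = readout_time),
            class = "ms_washout_protocol")
}

#' Simulate a BMP washout experiment
#'
#' Integrates the model through pre-stimulus, washout and re-application for
#' two populations: "on"-pretreated (pre-stimulated at `prestim_dose`) and
#' "off"-pretreated (pre-stimulus 0). After washout the effective BMP dose is
#' `reapplied + prestim * exp(-(t - t_wash)/residual_tau)` (residual zeroed
#' if the receptor inhibitor is applied). FGF is held constant throughout.
#'
#' @inheritParams compute_dose_response
#' @param protocol A [washout_protocol()].
#' @return Data.frame with columns `initial_state` ("on"/"off"), `dose`
#'   (reapplied) and `response` (B_T at readout).
#' @export
simulate_washout <- function(model_class, params, protocol, fgf_level = 0) {
  stopifnot(inherits(protocol, "ms_washout_protocol"))
  rhs <- build_rhs(model_class, params)
  t_wash <- protocol$prestim_duration
  res0 <- if (protocol$inhibitor_applied) 0 else protocol$prestim_dose
  run_pop <- function(prestim) {
    init <- init_state(model_class, params, fgf_level, "off")
    # pre-stimulus phase (constant dose)
    sol <- deSolve::ode(y = init, times = c(0, t_wash),
                        func = function(t, y, p) list(rhs(y, prestim,
                                                          fgf_level)),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    state_wash <- sol[nrow(sol), -1]
    vapply(protocol$reapplied_doses, function(dose) {
      b_eff <- function(t) dose +
        (if (prestim > 0) res0 * exp(-(t - t_wash) / protocol$residual_tau)
         else 0)
      sol2 <- deSolve::ode(y = state_wash,
                           times = c(t_wash, protocol$readout_time),
                           func = function(t, y, p)
                             list(rhs(y, b_eff(t), fgf_level)),
                           parms = NULL, method = "lsoda",
                           rtol = 1e-10, atol = 1e-12)
      sol2[nrow(sol2), "B_T"]
    }, numeric(1))
  }
  on_resp <- run_pop(protocol$prestim_dose)
  off_resp <- run_pop(0)
  data.frame(initial_state = rep(c("on", "off"),
                                 each = length(protocol$reapplied_doses)),
             dose = rep(protocol$reapplied_doses, 2),
             response = c(on_resp, off_resp))
}
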