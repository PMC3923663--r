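# Steady-state analysis.
#
# The three acyclic classes (STI, SUI, CFF) admit closed-form steady states by
# sequential substitution. CIPF's mutual-inhibition loop is handled through
# its 1D open-loop characteristic g(u): clamp the B_I input into the B->F
# inhibition at u, equilibrate F_I, and return the resulting B_I. Closed-loop
# fixed points are the crossings g(u) = u; because g is a composition of two
# nonincreasing maps it is nondecreasing, so crossings alternate
# stable/unstable and bistability is exactly >= 3 crossings.

# Steady open-loop drives of the two intermediates: a = max steady B_I given
# ligand B (no inhibition), c = max steady F_I given ligand F.
pathway_drives <- function(params, B, F) {
  list(a = params$kc1 / params$K_BI * hill_activation(B, params$K_tb, params$n1),
       c = params$kc3 / params$K_FI * hill_activation(F, params$K_tf, params$n2))
}

# B_T steady level given steady B_I (and F_I for the classes where F_I
# inhibits B_T directly).
bt_from_bi <- function(model_class, params, B_I, F_I) {
  bt <- params$kc5 / params$K_BT * hill_activation(B_I, params$K_tbt, params$n3)
  if (model_class %in% c("STI", "CFF"))
    bt <- bt * inhibition_factor(F_I, params$fb_link)
  bt
}

#' Closed-form steady-state B_T for the acyclic model classes
#'
#' Sequential substitution: equilibrate F_I from the FGF input, then B_I, then
#' B_T. Vectorised over `B`. CIPF has no general closed form and is rejected;
#' use [find_all_steady_states()] or [open_loop_characteristic()] instead.
#'
#' @param model_class `"STI"`, `"SUI"` or `"CFF"`.
#' @param params An [model_params()] object.
#' @param B,F Ligand concentrations (`B` may be a vector).
#' @return Steady-state B_T value(s).
#' @export
closed_form_bt <- function(model_class, params, B, F) {
  model_class <- match.arg(model_class, c("STI", "SUI", "CFF"))
  d <- pathway_drives(params, B, F)
  st <- closed_form_state(model_class, params, d$a, d$c)
  bt_from_bi(model_class, params, st$B_I, st$F_I)
}

# (B_I*, F_I*) for the acyclic classes from the drives a (vector) and c.
closed_form_state <- function(model_class, params, a, c) {
  switch(model_class,
    STI = list(B_I = a, F_I = rep(c, length(a))),
    SUI = list(B_I = a * inhibition_factor(c, params$fb_link),
               F_I = rep(c, length(a))),
    CFF = list(B_I = a, F_I = c * inhibition_factor(a, params$bf_link)),
    stop("no closed form for class ", model_class))
}

# Loop-return map of the CIPF loop for clamped B_I input u, given drives a, c.
cipf_loop_map <- function(params, a, c) {
  function(u)
    a * inhibition_factor(c * inhibition_factor(u, params$bf_link),
                          params$fb_link)
}

# All fixed points of a nondecreasing scalar map g on [0, upper]:
# roots of g(u) - u located by sign changes on a dense grid and refined with
# uniroot. Returns data.frame(u, stable); stable where g crosses from above.
fixed_points_1d <- function(g, upper, n_grid = 256L, tol = 1e-12) {
  if (upper <= 0) return(data.frame(u = 0, stable = TRUE))
  u <- seq(0, upper, length.out = n_grid)
  h <- g(u) - u
  roots <- numeric(0)
  sgn <- sign(h)
  for (i in seq_len(n_grid - 1L)) {
    if (h[i] == 0) { roots <- c(roots, u[i]); next }
    if (sgn[i] * sgn[i + 1L] < 0) {
      r <- stats::uniroot(function(z) g(z) - z, c(u[i], u[i + 1L]),
                          tol = tol * max(upper, 1))$root
      roots <- c(roots, r)
    }
  }
  if (h[n_grid] == 0) roots <- c(roots, u[n_grid])
  if (length(roots) == 0) {
    # g bounded in [0, upper] with h continuous: a root exists; fall back to
    # minimising |h| on the grid (can occur at grazing tangencies)
    roots <- u[which.min(abs(h))]
  }
  roots <- sort(unique(roots))
  # dedup near-identical roots (tangencies resolved to two near roots)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-8 * max(upper, 1))
    roots <- roots[keep]
  }
  eps <- 1e-7 * max(upper, 1)
  stable <- vapply(roots, function(r) {
    g(min(r + eps, upper)) - (r + eps) < 0 || g(max(r - eps, 0)) - (r - eps) > 0
  }, logical(1))
  data.frame(u = roots, stable = stable)
}

# CIPF steady states from the open-loop characteristic. Returns data.frame
# (B_I, F_I, B_T, stable), sorted by B_I.
cipf_steady_states <- function(params, B, F) {
  d <- pathway_drives(params, B, F)
  if (d$a <= 0)
    return(data.frame(B_I = 0, F_I = d$c, B_T = 0, stable = TRUE))
  fp <- fixed_points_1d(cipf_loop_map(params, d$a, d$c), upper = d$a)
  F_I <- d$c * inhibition_factor(fp$u, params$bf_link)
  data.frame(B_I = fp$u, F_I = F_I,
             B_T = bt_from_bi("CIPF", params, fp$u, F_I),
             stable = fp$stable)
}

# AUTOREG steady states: B_I solves kc1 h(B) inh(F_I) + kc_a h(B_I) = K_BI B_I
# with F_I = c fixed (no B->F link in the contrast model).
autoreg_steady_states <- function(params, B, F) {
  d <- pathway_drives(params, B, F)
  al <- params$auto_link
  base <- d$a * inhibition_factor(d$c, params$fb_link)
  g <- function(u) base + al$kc / params$K_BI * hill_activation(u, al$K, al$n)
  upper <- base + al$kc / params$K_BI
  fp <- fixed_points_1d(g, upper = upper)
  data.frame(B_I = fp$u, F_I = d$c,
             B_T = params$kc5 / params$K_BT *
               hill_activation(fp$u, params$K_tbt, params$n3),
             stable = fp$stable)
}

#' Open-loop characteristic of the CIPF loop
#'
#' Breaks the B_I -> F_I inhibition, clamps the B_I value feeding it at `u`,
#' equilibrates F_I, and returns the B_I level the closed loop would produce:
#' `g(u) = a * (1 - p_fb * h(c * (1 - p_bf * h(u))))`. Fixed points of the
#' closed loop are the crossings `g(u) = u`; the system is bistable exactly
#' when there are three crossings (two stable separated by one unstable).
#'
#' @param params CIPF [model_params()].
#' @param B,F Ligand concentrations (scalars).
#' @param u_grid Optional grid of clamped-input values; defaults to 256 points
#'   spanning `[0, a]`, which always brackets all crossings. A user grid that
#'   fails to bracket is expanded automatically.
#' @return An object of class `"ms_openloop"`: list with `u_grid`, `g_values`,
#'   `fixed_points` (data.frame `u`, `stable`) and `bistable` flag.
#' @export
open_loop_characteristic <- function(params, B, F, u_grid = NULL) {
  stopifnot(inherits(params, "ms_params"))
  d <- pathway_drives(params, B, F)
  g <- cipf_loop_map(params, d$a, d$c)
  upper <- d$a
  if (!is.null(u_grid)) {
    stopifnot(all(u_grid >= 0))
    if (max(u_grid) < upper) u_grid <- c(u_grid, upper)  # expand to bracket
  } else {
    u_grid <- seq(0, max(upper, .Machine$double.eps), length.out = 256L)
  }
  fp <- fixed_points_1d(g, upper = max(upper, max(u_grid)))
  structure(list(u_grid = u_grid, g_values = g(u_grid), fixed_points = fp,
                 bistable = sum(fp$stable) >= 2L),
            class = "ms_openloop")
}

#' @export
print.ms_openloop <- function(x, ...) {
  cat(sprintf("open-loop characteristic: %d fixed point(s), %s\n",
              nrow(x$fixed_points),
              if (x$bistable) "bistable" else "monostable"))
  invisible(x)
}

#' Integrate an ODE model to steady state
#'
#' Integrates with a stiff-capable solver over successive horizons until the
#' largest time-derivative falls below `tol * scale`, doubling the horizon up
#' to three times before flagging non-convergence.
#'
#' @param rhs A derivative function from [build_rhs()] or
#'   [build_topology_rhs()].
#' @param init Numeric initial state (same length the rhs expects).
#' @param B,F Ligand concentrations (scalars, held constant).
#' @param tol Steady-state tolerance on `max |d/dt|`, relative to `scale`.
#' @param t_max Initial integration horizon.
#' @param scale Characteristic production scale used to normalise the
#'   residual (default 1, appropriate for near-nondimensional parameters).
#' @return The final state vector with attributes `converged` (logical) and
#'   `residual` (max `|d/dt|` at the returned state).
#' @export
integrate_to_steady <- function(rhs, init, B, F, tol = 1e-9, t_max = 200,
                                scale = 1) {
  stopifnot(tol > 0, t_max > 0)
  state <- init
  deriv_fun <- function(t, y, parms) list(rhs(y, B, F))
  horizon <- t_max
  for (attempt in 1:7) {
    sol <- deSolve::ode(y = state, times = c(0, horizon), func = deriv_fun,
                        parms = NULL, method = "lsoda",
                        rtol = max(tol / 100, 1e-10),
                        atol = max(tol / 1000, 1e-12))
    state <- sol[nrow(sol), -1]
    residual <- max(abs(rhs(state, B, F)))
    if (residual < tol * scale) {
      attr(state, "converged") <- TRUE
      attr(state, "residual") <- residual
      return(state)
    }
    horizon <- horizon * 2
  }
  attr(state, "converged") <- FALSE
  attr(state, "residual") <- residual
  warning("integrate_to_steady: residual ", signif(residual, 3),
          " above tolerance after doubled horizons")
  state
}

# Initial conditions of the two dose-response protocols. "Off": the zero
# state (nothing expressed; from here the two pathways race for dominance at
# each dose). "On": the steady state reached from the zero state at
# saturating BMP (100 x K_tb) with the same FGF level -- the in-silico
# analogue of the high-dose pre-stimulus.
init_state <- function(model_class, params, F, which = c("off", "on")) {
  which <- match.arg(which)
  if (which == "off") return(c(B_I = 0, F_I = 0, B_T = 0))
  rhs <- build_rhs(model_class, params)
  s <- integrate_to_steady(rhs, c(B_I = 0, F_I = 0, B_T = 0),
                           B = 100 * params$K_tb, F = F,
                           tol = 1e-7, t_max = relax_horizon(params))
  c(B_I = s[[1]], F_I = s[[2]], B_T = s[[3]])
}

# Integration horizon adapted to the slowest relaxation rate of the system.
relax_horizon <- function(params) {
  50 / min(params$K_BI, params$K_FI, params$K_BT)
}

# Steady outcome of integrating from the zero state at one dose, snapped to
# the nearest stable analytic fixed point (removes integrator tolerance
# noise). `fps` may pass precomputed fixed points.
race_outcome <- function(model_class, params, B, F, fps = NULL) {
  if (is.null(fps)) fps <- steady_states_analytic(model_class, params, B, F)
  fps <- fps[fps$stable, , drop = FALSE]
  if (nrow(fps) == 1L) return(fps)
  rhs <- build_rhs(model_class, params)
  # loose tolerance: only the basin matters, the result is snapped to the
  # nearest stable fixed point
  s <- integrate_to_steady(rhs, c(B_I = 0, F_I = 0, B_T = 0), B = B, F = F,
                           tol = 1e-6, t_max = relax_horizon(params))
  fps[which.min(abs(fps$B_I - s[[1]])), , drop = FALSE]
}

# Dispatch table for analytic steady states of any class. Returns data.frame
# (B_I, F_I, B_T, stable).
steady_states_analytic <- function(model_class, params, B, F) {
  if (model_class == "CIPF") return(cipf_steady_states(params, B, F))
  if (model_class == "AUTOREG") return(autoreg_steady_states(params, B, F))
  d <- pathway_drives(params, B, F)
  st <- closed_form_state(model_class, params, d$a, d$c)
  data.frame(B_I = st$B_I, F_I = st$F_I,
             B_T = bt_from_bi(model_class, params, st$B_I, st$F_I),
             stable = TRUE)
}

#' Find all steady states of a model at given ligand inputs
#'
#' Unions the analytic fixed points (closed form for the acyclic classes,
#' open-loop crossings for CIPF/AUTOREG) with numerically integrated steady
#' states started from the "off" and "on" initial conditions, deduplicates,
#' and reports the residual `max |d/dt|` of each retained state.
#'
#' @param model_class Model class label.
#' @param params An [model_params()] object.
#' @param B,F Ligand concentrations (scalars).
#' @param method `"analytic"` (fixed-point solve only), `"integrate"`
#'   (two-init numerical integration only), or `"both"` (default: union).
#' @param dedup_tol Relative tolerance on B_I used to merge duplicate states.
#' @return List with `states` (data.frame `B_I`, `F_I`, `B_T`, `stable`),
#'   `converged` and `residual`.
#' @export
find_all_steady_states <- function(model_class, params, B, F,
                                   method = c("both", "analytic", "integrate"),
                                   dedup_tol = 1e-6) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  method <- match.arg(method)
  states <- NULL
  converged <- TRUE
  if (method %in% c("both", "analytic")) {
    st <- steady_states_analytic(model_class, params, B, F)
    states <- st[st$stable, c("B_I", "F_I", "B_T"), drop = FALSE]
  }
  if (method %in% c("both", "integrate")) {
    rhs <- build_rhs(model_class, params)
    for (w in c("off", "on")) {
      s <- integrate_to_steady(rhs, init_state(model_class, params, F, w), B, F)
      converged <- converged && attr(s, "converged")
      states <- rbind(states, data.frame(B_I = s[[1]], F_I = s[[2]],
                                         B_T = s[[3]]))
    }
  }
  states <- states[order(states$B_I), , drop = FALSE]
  ref <- max(states$B_I, 1e-12)
  keep <- c(TRUE, diff(states$B_I) > dedup_tol * ref)
  states <- states[keep, , drop = FALSE]
  rownames(states) <- NULL
  rhs <- build_rhs(model_class, params)
  residual <- max(apply(states, 1, function(s) max(abs(rhs(s, B, F)))))
  states$stable <- TRUE
  list(states = states, converged = converged, residual = residual)
}
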