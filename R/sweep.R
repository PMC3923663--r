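# Parameter-space sampling under the four linearity contexts, the
# property-change grid, balance scans of the CIPF loop, and the
# ultrasensitivity-hysteresis correlation.

#' Linearity context definitions
#'
#' Context 1: all links linear; 2: BMP/FGF core pathway nonlinear; 3:
#' inhibitory links nonlinear; 4: all links nonlinear. "Nonlinear" means Hill
#' exponent `nonlinear_n` (default 4); "linear" means exponent 1 (still
#' saturating).
#'
#' @param id Context id in 1:4.
#' @return List with `id`, `core_nonlinear`, `inhibitory_nonlinear`.
#' @export
linearity_context <- function(id) {
  stopifnot(id %in% 1:4)
  list(id = as.integer(id),
       core_nonlinear = id %in% c(2, 4),
       inhibitory_nonlinear = id %in% c(3, 4))
}

#' Default sampling ranges for parameter sweeps
#'
#' Sampling happens in the non-dimensionalised parameter space: species are
#' measured in units of their maximal steady level and time in units of the
#' (common) degradation rate, so all six rate constants are unity by default
#' (`rate = c(1, 1)`; widen to probe kinetic asymmetry). Ligand-facing
#' half-saturations (`K_tb`, `K_tf`) span two decades around unity (they set
#' each ligand's dose scale); the target-activation half-saturation `K_tbt`
#' spans the sub-unit decade `[0.2, 1]` so the target responds within the
#' intermediate's unit dynamic range; inhibitory strengths are uniform on
#' `[0.5, 0.99]`.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_sweep_ranges <- function() {
  list(rate = c(1, 1),          # per-species production = degradation
       halfsat = c(0.1, 10),    # K_tb, K_tf (ligand-facing)
       target_halfsat = c(0.2, 1), # K_tbt, relative to unit B_I level
       strength = c(0.5, 0.99))
}

#' Sample random parameter sets under a linearity context
#'
#' Draws `n` parameter sets in the non-dimensionalised parameter space: each
#' species' production/degradation ratio is unity (`kc1 = K_BI`,
#' `kc3 = K_FI`, `kc5 = K_BT`, the common rate drawn from `ranges$rate` --
#' degenerate at 1 by default, so every species' maximal steady level is 1
#' and all species share the unit relaxation timescale), and half-saturation
#' constants are drawn log-uniformly from their ranges.
#' Inhibitory strengths are uniform over the strength range; Hill exponents
#' are fixed at 1 or `nonlinear_n` according to the context flags. Fully
#' reproducible from `seed`; the global RNG state is restored on exit.
#'
#' @param context A context id (1-4) or a [linearity_context()].
#' @param n Number of sets, >= 1.
#' @param seed Integer seed.
#' @param ranges As [default_sweep_ranges()].
#' @param nonlinear_n Hill exponent used for nonlinear links.
#' @return List of `n` [model_params()] objects.
#' @export
sample_parameters <- function(context, n, seed,
                              ranges = default_sweep_ranges(),
                              nonlinear_n = 4) {
  if (is.numeric(context)) context <- linearity_context(context)
  stopifnot(n >= 1)
  if (any(vapply(ranges, function(r) length(r) < 2 || any(r <= 0),
                 logical(1))))
    stop("empty or non-positive sampling ranges")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rlog <- function(r) 10^stats::runif(1, log10(r[1]), log10(r[2]))
  n_core <- if (context$core_nonlinear) nonlinear_n else 1
  n_inh <- if (context$inhibitory_nonlinear) nonlinear_n else 1
  draw_link <- function() {
    p <- stats::runif(1, ranges$strength[1], ranges$strength[2])
    inhib_link(p, n = n_inh, form = "divisive")
  }
  lapply(seq_len(n), function(i) {
    r_b <- rlog(ranges$rate); r_f <- rlog(ranges$rate)
    r_t <- rlog(ranges$rate)
    model_params(
      kc1 = r_b, kc3 = r_f, kc5 = r_t,
      K_tb = rlog(ranges$halfsat), K_tf = rlog(ranges$halfsat),
      K_tbt = rlog(ranges$target_halfsat),
      K_BI = r_b, K_FI = r_f, K_BT = r_t,
      n1 = n_core, n2 = n_core, n3 = n_core,
      fb_link = draw_link(), bf_link = draw_link())
  })
}

#' Sweep a model class over sampled parameter space
#'
#' For each sampled parameter set, computes the with/without-FGF response
#' change (max, EC50, nH ratios) and -- for CIPF -- the bistability-window
#' width. FGF is applied at `K_tf` of each set (a fixed half-activating
#' dose, so that saturating BMP can out-compete the FGF side as observed).
#' Window widths are recorded in units of the set's `K_tb` so they are
#' comparable across sets whose dose scale differs. Sets that error out are
#' excluded and counted (more than 20% aborts); records whose with-FGF Hill
#' fit is flagged (poor fit, or EC50 pushed into the top half-decade of the
#' grid, i.e. a transition not resolved within the tested dose range) carry
#' `fit_ok = FALSE` and are skipped by the downstream summaries.
#'
#' @param model_class Model class label.
#' @param context Context id (1-4) or [linearity_context()].
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @param ranges Sampling ranges, as [default_sweep_ranges()].
#' @param fgf_factor FGF level as a multiple of each set's `K_tf`.
#' @return Data.frame of sweep records: `model_class`, `context`, `set`,
#'   `seed`, `max_ratio`, `ec50_ratio`, `nh_ratio`, `window_size` (units of
#'   `K_tb`; 0 when monostable or class acyclic), `fit_ok`, plus attribute
#'   `n_failed`.
#' @export
run_context_sweep <- function(model_class, context, n, seed,
                              ranges = default_sweep_ranges(),
                              fgf_factor = 1) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  if (is.numeric(context)) context <- linearity_context(context)
  sets <- sample_parameters(context, n, seed, ranges)
  rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    p <- sets[[i]]
    fgf <- fgf_factor * p$K_tf
    rec <- tryCatch({
      rc <- response_change(model_class, p, fgf_level = fgf)
      win <- if (model_class == "CIPF") {
        hy <- hysteresis_curves(model_class, p, fgf_level = fgf)
        hy$window_size / p$K_tb
      } else 0
      resolved <- rc$fit_fgf$ok && rc$fit_no_fgf$ok &&
        rc$fit_fgf$ec50 <= max(default_dose_grid(p)) / 10^0.5
      data.frame(model_class = model_class, context = context$id, set = i,
                 seed = seed, max_ratio = rc$max_ratio,
                 ec50_ratio = rc$ec50_ratio, nh_ratio = rc$nh_ratio,
                 window_size = win, fit_ok = resolved)
    }, error = function(e) NULL)
    if (is.null(rec)) n_failed <- n_failed + 1L else rows[[i]] <- rec
  }
  if (n_failed > 0.2 * n)
    stop("parameter sweep failed for ", n_failed, " of ", n,
         " sets (", model_class, ", context ", context$id, ")")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

#' Summarise sweep records into a qualitative property grid
#'
#' Frequency of each response property per (model class, context) cell:
#' maximum-level decrease (`max_ratio < 0.9`), EC50 increase
#' (`ec50_ratio > 1.1`), nH increase (`nh_ratio > 1.1`), hysteresis
#' (`window_size > 0`). Cells are labelled `absent` (frequency 0), `rare`
#' (below `rare_below`) or `present`.
#'
#' Records with `fit_ok = FALSE` (unresolved Hill fits) are skipped.
#'
#' @param records Row-bound sweep records from [run_context_sweep()].
#' @param rare_below Frequency below which a non-zero property is `rare`.
#' @param min_records Cells with fewer records are flagged undersampled.
#' @return Data.frame with `model_class`, `context`, `property`, `frequency`,
#'   `cell` and `undersampled`.
#' @export
summarize_grid <- function(records, rare_below = 0.10, min_records = 50L) {
  if ("fit_ok" %in% names(records)) records <- records[records$fit_ok, ]
  props <- list(max_decrease = function(r) r$max_ratio < 0.9,
                ec50_increase = function(r) r$ec50_ratio > 1.1,
                nh_increase = function(r) r$nh_ratio > 1.1,
                hysteresis = function(r) r$window_size > 0)
  cells <- unique(records[, c("model_class", "context")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- records[records$model_class == cells$model_class[i] &
                   records$context == cells$context[i], ]
    data.frame(model_class = cells$model_class[i], context = cells$context[i],
               property = names(props),
               frequency = vapply(props, function(f) mean(f(r)), numeric(1)),
               undersampled = nrow(r) < min_records)
  }))
  out$cell <- ifelse(out$frequency == 0, "absent",
                     ifelse(out$frequency < rare_below, "rare", "present"))
  rownames(out) <- NULL
  out
}

#' Balance scan of the CIPF loop
#'
#' Varies the two inhibitory-link strengths (or exponents) over a grid,
#' holding everything else fixed, and records whether the loop is bistable
#' anywhere on the dose axis and the nH fold-change upon FGF addition.
#' Reproduces the requirement that the loop be balanced (and at least one
#' link nonlinear) for hysteresis.
#'
#' @param params CIPF template [model_params()].
#' @param fb_values,bf_values Grid values for the F->B and B->F links.
#' @param vary `"strength"` (p) or `"exponent"` (n).
#' @param fgf_level FGF level; defaults to `K_tf`.
#' @return Data.frame `fb`, `bf`, `bistable`, `window_size`, `nh_ratio`.
#' @export
balance_scan <- function(params, fb_values, bf_values,
                         vary = c("strength", "exponent"),
                         fgf_level = NULL) {
  vary <- match.arg(vary)
  if (is.null(fgf_level)) fgf_level <- params$K_tf
  grid <- expand.grid(fb = fb_values, bf = bf_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    if (vary == "strength") {
      p$fb_link <- inhib_link(grid$fb[i], n = p$fb_link$n,
                              form = p$fb_link$form)
      p$bf_link <- inhib_link(grid$bf[i], n = p$bf_link$n,
                              form = p$bf_link$form)
    } else {
      p$fb_link <- inhib_link(p$fb_link$p, n = grid$fb[i],
                              form = p$fb_link$form)
      p$bf_link <- inhib_link(p$bf_link$p, n = grid$bf[i],
                              form = p$bf_link$form)
    }
    hy <- hysteresis_curves("CIPF", p, fgf_level = fgf_level)
    nh <- tryCatch(response_change("CIPF", p, fgf_level)$nh_ratio,
                   error = function(e) NA_real_)
    data.frame(fb = grid$fb[i], bf = grid$bf[i],
               bistable = hy$window_size > 0,
               window_size = hy$window_size, nh_ratio = nh)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ultrasensitivity-hysteresis correlation
#'
#' Pearson correlation between the nH fold-increase upon FGF addition and the
#' bistability-window width across CIPF sweep records. Both quantities are
#' fold-change-like and span orders of magnitude, so the correlation is
#' computed on log10 scales; monostable sets enter with window 0 through the
#' offset `window_floor`, the smallest window the default dose grid can
#' resolve (its lowest dose, `K_tb`/100, in the sweep's `K_tb` units).
#' Records with unresolved Hill fits (`fit_ok = FALSE`) are skipped.
#'
#' @param records Sweep records from [run_context_sweep()] (CIPF).
#' @param window_floor Additive offset for the log window scale.
#' @return Pearson r on log scales. Fewer than 30 usable records is an
#'   error; zero variance in either variable returns `NA` with a warning.
#' @export
correlate_dnh_window <- function(records, window_floor = 0.01) {
  if ("fit_ok" %in% names(records)) records <- records[records$fit_ok, ]
  if (nrow(records) < 30)
    stop("need at least 30 sweep records for a correlation")
  x <- log10(records$nh_ratio)
  y <- log10(records$window_size + window_floor)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}
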