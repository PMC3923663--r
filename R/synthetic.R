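# Synthetic datasets emulating the study's measurements: noisy Hill-shaped
# RT-qPCR dose responses (ddCt-style fold changes), washout time-course
# datasets, and exponential spatial gradient profiles. All noise is
# multiplicative lognormal (qPCR fold-change errors are multiplicative);
# every generator is deterministic under a fixed seed and restores the
# global RNG state.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Multiplicative lognormal noise model
#'
#' @param sigma Standard deviation of the log-scale noise, >= 0.
#' @return Object of class `"ms_noise"`.
#' @export
noise_model <- function(sigma = 0.1) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, distribution = "lognormal"),
            class = "ms_noise")
}

#' Generate a synthetic qPCR-style dose-response dataset
#'
#' Hill-curve fold changes `ymax * d^nH / (ec50^nH + d^nH)` with
#' multiplicative lognormal noise, replicated. Defaults mirror the measured
#' ultrasensitive target response (EC50 8.3 ng/ml, nH 3.7).
#'
#' @param ymax,ec50,nH True Hill parameters.
#' @param doses BMP doses in ng/ml (> 0), e.g. `c(1, 2, 4, 8, 16, 32, 64)`.
#' @param reps Replicates per dose, >= 2.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param condition Condition label stored with the dataset.
#' @return Data.frame with columns `condition`, `dose`, `replicate`, `value`,
#'   `seed`.
#' @export
gen_dose_response <- function(ymax = 1, ec50 = 8.3, nH = 3.7,
                              doses = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                              reps = 3L, noise = noise_model(), seed = 1L,
                              condition = "FGF+EGF") {
  stopifnot(all(doses > 0), reps >= 2)
  true <- ymax / (1 + (ec50 / doses)^nH)
  with_seed(seed, {
    eps <- stats::rnorm(length(doses) * reps, 0, noise$sigma)
    data.frame(condition = condition,
               dose = rep(doses, times = reps),
               replicate = rep(seq_len(reps), each = length(doses)),
               value = rep(true, times = reps) * exp(eps),
               seed = seed)
  })
}

#' Generate a synthetic washout dataset
#'
#' Runs [simulate_washout()] for the on- and off-pretreated populations and
#' overlays multiplicative lognormal noise on the replicated readouts.
#'
#' @param model_class Model class label (typically `"CIPF"`).
#' @param params An [model_params()] object.
#' @param protocol A [washout_protocol()].
#' @param fgf_level FGF level held throughout.
#' @param reps Replicates per condition/dose.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return Data.frame `condition` ("on"/"off" pretreatment), `dose`,
#'   `replicate`, `value`, `seed`.
#' @export
gen_washout_dataset <- function(model_class, params, protocol, fgf_level = 0,
                                reps = 3L, noise = noise_model(), seed = 1L) {
  base <- simulate_washout(model_class, params, protocol, fgf_level)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(condition = base$initial_state, dose = base$dose,
                 replicate = r,
                 value = base$response *
                   exp(stats::rnorm(nrow(base), 0, noise$sigma)),
                 seed = seed)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a noisy exponential gradient profile
#'
#' Samples `c(x) = A * exp(-x/lambda) + b` at `n_points` evenly spaced
#' positions with multiplicative lognormal noise. Defaults mirror the
#' measured pSmad gradient length scale (~290 um).
#'
#' @param A Amplitude (ng/ml).
#' @param lambda Length scale (um).
#' @param b Background.
#' @param x_max Span of positions (um); default `3 * lambda`.
#' @param n_points Number of positions, >= 5.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return Data.frame with columns `x`, `c`, `seed`.
#' @export
gen_gradient_profile <- function(A = 10, lambda = 290, b = 1, x_max = NULL,
                                 n_points = 20L, noise = noise_model(0.05),
                                 seed = 1L) {
  stopifnot(n_points >= 5)
  if (is.null(x_max)) x_max <- 3 * lambda
  x <- seq(0, x_max, length.out = n_points)
  true <- A * exp(-x / lambda) + b
  with_seed(seed,
    data.frame(x = x,
               c = true * exp(stats::rnorm(n_points, 0, noise$sigma)),
               seed = seed))
}
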