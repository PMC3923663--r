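# Config-driven pipeline: one entry point dispatching the analysis stages,
# writing CSV/JSON outputs and a run manifest so every stochastic result is
# reproducible from the manifest alone. A thin command-line wrapper lives in
# inst/scripts/run_pipeline.R.

#' Run an analysis stage from a configuration
#'
#' Dispatches one of the pipeline stages and writes its outputs (CSV tables,
#' JSON summaries) plus a `manifest.json` echoing the configuration, seed and
#' package version to `out_dir`.
#'
#' Stages and their config fields (all numeric unless noted):
#' \describe{
#'   \item{`enumerate`}{none -- writes `topologies.csv` and
#'     `class_counts.json`.}
#'   \item{`dose-response`}{`model_class`, optional flat `params` record,
#'     `fgf_level`; writes `dose_response.csv` and `hill_fit.json`.}
#'   \item{`sweep`}{`model_class`, `context`, `n`, `seed`; writes
#'     `sweep_records.csv` and `property_grid.csv`.}
#'   \item{`hysteresis`}{`model_class`, optional `params`, `fgf_level`;
#'     writes `hysteresis_curves.csv` and `window.json`.}
#'   \item{`washout`}{`model_class`, optional `params`, `fgf_level`, and
#'     protocol fields `prestim_dose`, `prestim_duration`, `residual_tau`,
#'     `inhibitor_applied` (logical), `reapplied_doses`, `readout_time`;
#'     writes `washout.csv`.}
#'   \item{`dual-ec50`}{optional `params`, named lists `loop_deltas` /
#'     `downstream_deltas`; writes `dual_ec50.json`.}
#'   \item{`tissue`}{`model_class`, optional `params`, gradient fields
#'     `bmp_A`, `bmp_lambda`, `bmp_b`, `fgf_A`, `fgf_lambda`, `fgf_b`, `L`,
#'     `n_cells`; writes `tissue.csv` and `border.json`.}
#'   \item{`synth`}{`kind` ("dose-response" or "gradient") plus the matching
#'     generator arguments and `seed`; writes `synthetic.csv`.}
#' }
#'
#' @param config A named list, or a path to a JSON file holding one. Must
#'   contain `stage`; stochastic stages require `seed`.
#' @param out_dir Output directory (created if missing).
#' @return (Invisibly) the list of files written.
#' @export
run_stage <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$stage))
    stop("config$stage is required")
  stage <- match.arg(config$stage,
                     c("enumerate", "dose-response", "sweep", "hysteresis",
                       "washout", "dual-ec50", "tissue", "synth"))
  stochastic <- stage %in% c("sweep", "synth")
  if (stochastic && is.null(config$seed))
    stop("config$seed is mandatory for stage '", stage, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  get_params <- function() {
    if (!is.null(config$params)) params_unflatten(config$params)
    else model_params(fb_link = inhib_link(0.9, k = 0.2, n = 4),
                      bf_link = inhib_link(0.9, k = 0.2, n = 4))
  }
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    files <<- c(files, path)
  }
  num <- function(field, default) {
    if (is.null(config[[field]])) default else config[[field]]
  }

  if (stage == "enumerate") {
    tab <- enumerate_topologies()
    attr(tab, "topologies") <- NULL
    put_csv(tab, "topologies.csv")
    put_json(as.list(table(tab$class_label)), "class_counts.json")
  } else if (stage == "dose-response") {
    p <- get_params()
    dr <- compute_dose_response(num("model_class", "CIPF"), p,
                                fgf_level = num("fgf_level", p$K_tf))
    put_csv(as.data.frame(dr), "dose_response.csv")
    f <- fit_hill(dr)
    put_json(list(ymax = f$ymax, ec50 = f$ec50, nH = f$nH, ok = f$ok),
             "hill_fit.json")
  } else if (stage == "sweep") {
    rec <- run_context_sweep(num("model_class", "CIPF"),
                             num("context", 3), n = num("n", 500),
                             seed = config$seed)
    put_csv(rec, "sweep_records.csv")
    put_csv(summarize_grid(rec, min_records = min(50, num("n", 500))),
            "property_grid.csv")
  } else if (stage == "hysteresis") {
    p <- get_params()
    hy <- hysteresis_curves(num("model_class", "CIPF"), p,
                            fgf_level = num("fgf_level", p$K_tf))
    put_csv(rbind(cbind(branch = "off", as.data.frame(hy$off_curve)),
                  cbind(branch = "on", as.data.frame(hy$on_curve))),
            "hysteresis_curves.csv")
    put_json(list(window_lo = hy$window_lo, window_hi = hy$window_hi,
                  window_size = hy$window_size), "window.json")
  } else if (stage == "washout") {
    p <- get_params()
    proto <- washout_protocol(num("prestim_dose", 64 * p$K_tb),
                              num("prestim_duration", 2),
                              num("residual_tau", 10),
                              isTRUE(config$inhibitor_applied),
                              num("reapplied_doses", default_dose_grid(p, 12)),
                              num("readout_time", 100))
    put_csv(simulate_washout(num("model_class", "CIPF"), p, proto,
                             fgf_level = num("fgf_level", p$K_tf)),
            "washout.csv")
  } else if (stage == "dual-ec50") {
    p <- get_params()
    dm <- dual_loop_model(p, loop_deltas = unlist(config$loop_deltas),
                          downstream_deltas = unlist(config$downstream_deltas))
    res <- dual_ec50_analysis(dm)
    put_json(list(ec50_ratio = res$ec50_ratio, max_ratio = res$max_ratio),
             "dual_ec50.json")
  } else if (stage == "tissue") {
    p <- get_params()
    L <- num("L", 1000)
    bg <- gradient_profile(num("bmp_A", 50), num("bmp_lambda", 270),
                           num("bmp_b", 0), L = L, decreasing = FALSE)
    fg <- gradient_profile(num("fgf_A", 50), num("fgf_lambda", 270),
                           num("fgf_b", 0))
    tis <- simulate_tissue(num("model_class", "CIPF"), p, bg, fg, L,
                           n_cells = num("n_cells", 200))
    put_csv(data.frame(x = tis$x, bmp = tis$bmp, fgf = tis$fgf,
                       bt_off = tis$bt_off, bt_on = tis$bt_on),
            "tissue.csv")
    put_json(list(border = tis$border,
                  relative_border = tis$border / L), "border.json")
  } else if (stage == "synth") {
    kind <- num("kind", "dose-response")
    df <- if (kind == "gradient") {
      gen_gradient_profile(A = num("A", 10), lambda = num("lambda", 290),
                           b = num("b", 1), n_points = num("n_points", 20),
                           noise = noise_model(num("sigma", 0.05)),
                           seed = config$seed)
    } else {
      gen_dose_response(ymax = num("ymax", 1), ec50 = num("ec50", 8.3),
                        nH = num("nH", 3.7), reps = num("reps", 3),
                        noise = noise_model(num("sigma", 0.1)),
                        seed = config$seed)
    }
    put_csv(df, "synthetic.csv")
  }

  put_json(list(config = config,
                package_version =
                  as.character(utils::packageVersion("morphoswitch")),
                r_version = R.version.string),
           "manifest.json")
  invisible(files)
}
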