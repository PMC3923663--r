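MODEL_CLASSES <- c("STI", "SUI", "CFF", "CIPF", "AUTOREG")

#' Parameter set for the cross-inhibition ODE models
#'
#' Bundles the kinetic parameters of the two three-tier pathways
#' (BMP -> B_I -> B_T and FGF -> F_I) together with the two cross-pathway
#' inhibitory links. The same container serves all model classes; which links
#' are wired in is decided by [build_rhs()].
#'
#' @param kc1,kc3,kc5 Maximum production rates of B_I, F_I and B_T
#'   (amount/time), > 0.
#' @param K_tb,K_tf,K_tbt Half-saturation constants of activation for
#'   BMP -> B_I, FGF -> F_I and B_I -> B_T (concentration), > 0.
#' @param K_BI,K_FI,K_BT Linear degradation rates of B_I, F_I, B_T (1/time),
#'   > 0.
#' @param n1,n2,n3 Hill exponents of the three activating links, >= 1.
#' @param fb_link F-to-B inhibitory link (an [inhib_link()]); in the
#'   representative models its input is F_I.
#' @param bf_link B-to-F inhibitory link; in the representative models its
#'   input is B_I.
#' @param auto_link Optional self-activation link on B_I for the
#'   auto-regulatory contrast model: a list with elements `kc` (extra maximal
#'   production), `K` (half-saturation) and `n` (exponent). `NULL` for the four
#'   cross-inhibition classes.
#' @return An object of class `"ms_params"` (a validated named list).
#' @export
model_params <- function(kc1 = 1, kc3 = 1, kc5 = 1,
                         K_tb = 1, K_tf = 1, K_tbt = 0.5,
                         K_BI = 1, K_FI = 1, K_BT = 1,
                         n1 = 1, n2 = 1, n3 = 1,
                         fb_link = inhib_link(0.88, n = 1),
                         bf_link = inhib_link(0.88, n = 1),
                         auto_link = NULL) {
  pos <- c(kc1 = kc1, kc3 = kc3, kc5 = kc5, K_tb = K_tb, K_tf = K_tf,
           K_tbt = K_tbt, K_BI = K_BI, K_FI = K_FI, K_BT = K_BT)
  if (any(pos <= 0))
    stop("all rates and half-saturation constants must be > 0: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  exps <- c(n1 = n1, n2 = n2, n3 = n3)
  if (any(exps < 1))
    stop("Hill exponents must be >= 1: ",
         paste(names(exps)[exps < 1], collapse = ", "))
  stopifnot(inherits(fb_link, "inhib_link"), inherits(bf_link, "inhib_link"))
  if (!is.null(auto_link)) {
    stopifnot(is.list(auto_link),
              all(c("kc", "K", "n") %in% names(auto_link)))
    if (auto_link$kc < 0 || auto_link$K <= 0 || auto_link$n < 1)
      stop("invalid auto_link: need kc >= 0, K > 0, n >= 1")
  }
  structure(list(kc1 = kc1, kc3 = kc3, kc5 = kc5,
                 K_tb = K_tb, K_tf = K_tf, K_tbt = K_tbt,
                 K_BI = K_BI, K_FI = K_FI, K_BT = K_BT,
                 n1 = n1, n2 = n2, n3 = n3,
                 fb_link = fb_link, bf_link = bf_link,
                 auto_link = auto_link),
            class = "ms_params")
}

#' @export
print.ms_params <- function(x, ...) {
  cat("cross-inhibition model parameters\n")
  cat(sprintf("  production kc1/kc3/kc5: %g / %g / %g\n", x$kc1, x$kc3, x$kc5))
  cat(sprintf("  activation K_tb/K_tf/K_tbt: %g / %g / %g (n = %g/%g/%g)\n",
              x$K_tb, x$K_tf, x$K_tbt, x$n1, x$n2, x$n3))
  cat(sprintf("  degradation K_BI/K_FI/K_BT: %g / %g / %g\n",
              x$K_BI, x$K_FI, x$K_BT))
  cat(sprintf("  F->B link: p = %.2f, k = %g, n = %g\n",
              x$fb_link$p, x$fb_link$k, x$fb_link$n))
  cat(sprintf("  B->F link: p = %.2f, k = %g, n = %g\n",
              x$bf_link$p, x$bf_link$k, x$bf_link$n))
  if (!is.null(x$auto_link))
    cat(sprintf("  B_I self-activation: kc = %g, K = %g, n = %g\n",
                x$auto_link$kc, x$auto_link$K, x$auto_link$n))
  invisible(x)
}

#' Flatten / restore a parameter set as a key-value record
#'
#' Serialisation helpers: `params_flatten()` turns an `ms_params` into a flat
#' named numeric vector (`fb_link.p`, `bf_link.k`, ...); `params_unflatten()`
#' inverts it. `write_params()` / `read_params()` round-trip one or more sets
#' through JSON or CSV (chosen by file extension).
#'
#' @param params An [model_params()] object.
#' @return `params_flatten()`: a named numeric vector.
#' @export
params_flatten <- function(params) {
  stopifnot(inherits(params, "ms_params"))
  out <- unlist(params[c("kc1", "kc3", "kc5", "K_tb", "K_tf", "K_tbt",
                         "K_BI", "K_FI", "K_BT", "n1", "n2", "n3")])
  out <- c(out,
           fb_link.p = params$fb_link$p, fb_link.k = params$fb_link$k,
           fb_link.n = params$fb_link$n,
           fb_link.divisive = as.numeric(params$fb_link$form == "divisive"),
           bf_link.p = params$bf_link$p, bf_link.k = params$bf_link$k,
           bf_link.n = params$bf_link$n,
           bf_link.divisive = as.numeric(params$bf_link$form == "divisive"))
  if (!is.null(params$auto_link))
    out <- c(out, auto_link.kc = params$auto_link$kc,
             auto_link.K = params$auto_link$K,
             auto_link.n = params$auto_link$n)
  out
}

link_form <- function(x, key) {
  if (key %in% names(x) && x[[key]] == 0) "saturating" else "divisive"
}

#' @rdname params_flatten
#' @param x A named numeric vector as produced by `params_flatten()`.
#' @export
params_unflatten <- function(x) {
  x <- unlist(x)
  x <- x[!is.na(x)]
  auto <- NULL
  if ("auto_link.kc" %in% names(x))
    auto <- list(kc = x[["auto_link.kc"]], K = x[["auto_link.K"]],
                 n = x[["auto_link.n"]])
  model_params(kc1 = x[["kc1"]], kc3 = x[["kc3"]], kc5 = x[["kc5"]],
               K_tb = x[["K_tb"]], K_tf = x[["K_tf"]], K_tbt = x[["K_tbt"]],
               K_BI = x[["K_BI"]], K_FI = x[["K_FI"]], K_BT = x[["K_BT"]],
               n1 = x[["n1"]], n2 = x[["n2"]], n3 = x[["n3"]],
               fb_link = inhib_link(x[["fb_link.p"]], x[["fb_link.k"]],
                                    x[["fb_link.n"]],
                                    form = link_form(x, "fb_link.divisive")),
               bf_link = inhib_link(x[["bf_link.p"]], x[["bf_link.k"]],
                                    x[["bf_link.n"]],
                                    form = link_form(x, "bf_link.divisive")),
               auto_link = auto)
}

#' @rdname params_flatten
#' @param params_list A list of `ms_params` objects (or a single one).
#' @param path Output/input file path ending in `.json` or `.csv`.
#' @export
write_params <- function(params_list, path) {
  if (inherits(params_list, "ms_params")) params_list <- list(params_list)
  rows <- lapply(params_list, function(p) as.list(params_flatten(p)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    cols <- Reduce(union, lapply(rows, names))
    filled <- lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- NA_real_
      as.data.frame(r[cols])
    })
    utils::write.csv(do.call(rbind, filled), path, row.names = FALSE)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}

#' @rdname params_flatten
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext == "csv") {
    utils::read.csv(path, check.names = FALSE)
  } else stop("unsupported extension: ", ext)
  if (is.data.frame(rows)) {
    lapply(seq_len(nrow(rows)), function(i) params_unflatten(rows[i, ]))
  } else {
    lapply(rows, params_unflatten)
  }
}

#' Non-dimensionalise a parameter set
#'
#' Rescales each intracellular species by its maximal steady level
#' (production/degradation ratio) and time by `1/K_BT`. Half-saturation
#' constants whose input is a rescaled species (K_tbt and the two inhibitory
#' links) are rescaled accordingly; ligand-facing constants (K_tb, K_tf) are
#' untouched. The dose-response shape (apparent Hill coefficient, EC50 on the
#' dose axis) is invariant; the maximal B_T level is divided by `kc5/K_BT`.
#'
#' @param params An [model_params()] object.
#' @return A rescaled `ms_params` with `kc5 = K_BT = 1`.
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "ms_params"))
  sB <- params$kc1 / params$K_BI   # scale of B_I
  sF <- params$kc3 / params$K_FI   # scale of F_I
  tau <- params$K_BT               # time scale 1/K_BT
  auto <- params$auto_link
  if (!is.null(auto))
    auto <- list(kc = auto$kc / (sB * tau), K = auto$K / sB, n = auto$n)
  model_params(kc1 = params$K_BI / tau, kc3 = params$K_FI / tau, kc5 = 1,
               K_tb = params$K_tb, K_tf = params$K_tf,
               K_tbt = params$K_tbt / sB,
               K_BI = params$K_BI / tau, K_FI = params$K_FI / tau, K_BT = 1,
               n1 = params$n1, n2 = params$n2, n3 = params$n3,
               fb_link = inhib_link(params$fb_link$p, params$fb_link$k / sF,
                                    params$fb_link$n),
               bf_link = inhib_link(params$bf_link$p, params$bf_link$k / sB,
                                    params$bf_link$n),
               auto_link = auto)
}
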