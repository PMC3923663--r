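#' Build the ODE right-hand side for a representative model class
#'
#' Wires the cross-pathway inhibitory links of a model class into the two
#' three-tier pathways and returns the time-derivative function of the state
#' `(B_I, F_I, B_T)` under constant ligand inputs `B` and `F`:
#'
#' \deqn{dB_I/dt = kc_1 h(B; K_{tb}, n_1) [\cdot I_F] - K_{BI} B_I}
#' \deqn{dF_I/dt = kc_3 h(F; K_{tf}, n_2) [\cdot I_B] - K_{FI} F_I}
#' \deqn{dB_T/dt = kc_5 h(B_I; K_{tbt}, n_3) [\cdot I_F] - K_{BT} B_T}
#'
#' where `h` is [hill_activation()] and the bracketed inhibition factors are
#' present per class: STI (F_I inhibits B_T), SUI (F_I inhibits B_I), CFF
#' (F_I inhibits B_T, B_I inhibits F_I), CIPF (F_I inhibits B_I, B_I inhibits
#' F_I). The AUTOREG contrast model is SUI-wired with an added B_I
#' self-activation term `kc_a h(B_I; K_a, n_a)` (no B-to-F link).
#'
#' @param model_class One of `"STI"`, `"SUI"`, `"CFF"`, `"CIPF"`, `"AUTOREG"`.
#' @param params An [model_params()] object; AUTOREG requires `auto_link`.
#' @return A function `(state, B, F) -> named derivative vector`, with `state`
#'   a numeric vector `c(B_I, F_I, B_T)`.
#' @export
build_rhs <- function(model_class, params) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  stopifnot(inherits(params, "ms_params"))
  if (model_class == "AUTOREG" && is.null(params$auto_link))
    stop("AUTOREG model requires params$auto_link")
  # unpack everything into closure locals: the returned function sits in the
  # integrator's inner loop
  kc1 <- params$kc1; kc3 <- params$kc3; kc5 <- params$kc5
  K_tb <- params$K_tb; K_tf <- params$K_tf; K_tbt <- params$K_tbt
  K_BI <- params$K_BI; K_FI <- params$K_FI; K_BT <- params$K_BT
  n1 <- params$n1; n2 <- params$n2; n3 <- params$n3
  inh_fb <- inhibition_fun(params$fb_link)
  inh_bf <- inhibition_fun(params$bf_link)
  is_autoreg <- model_class == "AUTOREG"
  if (is_autoreg) {
    kc_a <- params$auto_link$kc; K_a <- params$auto_link$K
    n_a <- params$auto_link$n
  }
  fi_on_bi <- model_class %in% c("SUI", "CIPF", "AUTOREG")
  bi_on_fi <- model_class %in% c("CFF", "CIPF")
  fi_on_bt <- model_class %in% c("STI", "CFF")
  # 1/(1+(k/x)^n) is hill_activation in an overflow-safe form (0 at x = 0,
  # 1 at x = Inf)
  hl <- function(x, k, n) 1 / (1 + (k / x)^n)
  function(state, B, F) {
    B_I <- state[[1]]; F_I <- state[[2]]; B_T <- state[[3]]
    prod_bi <- kc1 * hl(B, K_tb, n1)
    if (fi_on_bi) prod_bi <- prod_bi * inh_fb(F_I)
    if (is_autoreg) prod_bi <- prod_bi + kc_a * hl(B_I, K_a, n_a)
    prod_fi <- kc3 * hl(F, K_tf, n2)
    if (bi_on_fi) prod_fi <- prod_fi * inh_bf(B_I)
    prod_bt <- kc5 * hl(B_I, K_tbt, n3)
    if (fi_on_bt) prod_bt <- prod_bt * inh_fb(F_I)
    c(B_I = prod_bi - K_BI * B_I,
      F_I = prod_fi - K_FI * F_I,
      B_T = prod_bt - K_BT * B_T)
  }
}

# Fast closure evaluating a link's inhibition factor (no per-call checks;
# overflow-safe at x = 0 and x = Inf).
inhibition_fun <- function(link) {
  k <- link$k; n <- link$n
  if (link$form == "divisive") {
    function(x) 1 / (1 + (x / k)^n)
  } else {
    p <- link$p
    function(x) (1 - p) + p / (1 + (x / k)^n)
  }
}

#' Build the ODE right-hand side for an arbitrary two-link topology
#'
#' General six-node system (both pathways carried through their target tier)
#' with one F-to-B and one B-to-F inhibitory link attached at arbitrary tiers
#' (0 = ligand, 1 = intermediate, 2 = target). A link targeting the ligand
#' tier scales the effective ligand concentration entering the activation
#' term; a link sourced at the ligand tier uses the ligand concentration as
#' its inhibitor input. The F_T leg mirrors the B_T leg's kinetic parameters.
#'
#' @param topology A [topology()] object (see [enumerate_topologies()]).
#' @param params An [model_params()] object supplying the kinetic parameters;
#'   `fb_link`/`bf_link` supply strength, half-saturation and exponent of the
#'   F-to-B and B-to-F links respectively.
#' @return A function `(state, B, F) -> named derivative vector`, with `state`
#'   `c(B_I, F_I, B_T, F_T)`.
#' @export
build_topology_rhs <- function(topology, params) {
  stopifnot(inherits(topology, "ms_topology"), inherits(params, "ms_params"))
  p <- params
  sf <- topology$fb_source_tier; tb <- topology$fb_target_tier
  sb <- topology$bf_source_tier; tf <- topology$bf_target_tier
  function(state, B, F) {
    B_I <- state[[1]]; F_I <- state[[2]]
    B_T <- state[[3]]; F_T <- state[[4]]
    src_f <- switch(sf + 1L, F, F_I, F_T)  # inhibitor feeding the F->B link
    src_b <- switch(sb + 1L, B, B_I, B_T)  # inhibitor feeding the B->F link
    fac_fb <- inhibition_factor(src_f, p$fb_link)
    fac_bf <- inhibition_factor(src_b, p$bf_link)
    B_eff <- if (tb == 0L) B * fac_fb else B
    F_eff <- if (tf == 0L) F * fac_bf else F
    prod_bi <- p$kc1 * hill_activation(B_eff, p$K_tb, p$n1)
    if (tb == 1L) prod_bi <- prod_bi * fac_fb
    prod_fi <- p$kc3 * hill_activation(F_eff, p$K_tf, p$n2)
    if (tf == 1L) prod_fi <- prod_fi * fac_bf
    prod_bt <- p$kc5 * hill_activation(B_I, p$K_tbt, p$n3)
    if (tb == 2L) prod_bt <- prod_bt * fac_fb
    prod_ft <- p$kc5 * hill_activation(F_I, p$K_tbt, p$n3)
    if (tf == 2L) prod_ft <- prod_ft * fac_bf
    c(B_I = prod_bi - p$K_BI * B_I,
      F_I = prod_fi - p$K_FI * F_I,
      B_T = prod_bt - p$K_BT * B_T,
      F_T = prod_ft - p$K_BT * F_T)
  }
}
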