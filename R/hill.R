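#' Hill activation function
#'
#' Fractional activation `x^n / (k^n + x^n)` used for every activating link in
#' the pathway models (ligand -> intermediate -> target).
#'
#' @param x Input concentration(s), >= 0 (arbitrary concentration units).
#' @param k Half-saturation constant, > 0.
#' @param n Hill exponent, >= 1.
#' @return Fraction(s) in `[0, 1)`, monotone nondecreasing in `x`.
#' @examples
#' hill_activation(1, k = 1, n = 2)  # 0.5 at half-saturation
#' hill_activation(3, k = 1, n = 2)  # 9/10
#' @export
hill_activation <- function(x, k, n) {
  if (any(k <= 0)) stop("half-saturation constant `k` must be > 0")
  if (any(n < 1)) stop("Hill exponent `n` must be >= 1")
  if (any(x < 0)) stop("concentration `x` must be >= 0")
  # (x/k)^n form avoids overflow for large x and large n
  r <- (x / k)^n
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Inhibitory link between the two pathways
#'
#' A cross-pathway inhibition is parameterised by its strength `p` (the
#' "% inhibitory strength" scale: fractional suppression at unit inhibitor
#' concentration, the inhibitor's maximal non-dimensional level) and its Hill
#' exponent `n` ("linearity"; `n = 1` is a linear link, the nonlinear default
#' is 4).
#'
#' Two functional forms are supported. The default `"divisive"` form is the
#' classic toggle-switch repression `1 / (1 + (x/k)^n)`, with `k = 1/kc` the
#' half-suppression concentration; suppression is unbounded in the inhibitor.
#' When `k` is not given it is derived from the strength as `k = (1-p)/p`:
#' a linear "`p = 88%`" link suppresses its target by 88% when the inhibitor
#' sits at its unit maximal level, and a nonlinear link keeps the same
#' half-suppression point with a sharpened slope. The alternative
#' `"saturating"` form `1 - p * x^n/(k^n + x^n)` bounds suppression at `p`
#' (here `k` defaults to 1 and `p` is the maximal fractional suppression).
#'
#' @param p Strength in `[0, 1]`.
#' @param k Half-suppression concentration, > 0; default derived from `p`
#'   (divisive form) or 1 (saturating form).
#' @param n Hill exponent of the inhibition, >= 1.
#' @param form `"divisive"` (default) or `"saturating"`.
#' @return An object of class `"inhib_link"`.
#' @export
inhib_link <- function(p, k = NULL, n = 1,
                       form = c("divisive", "saturating")) {
  form <- match.arg(form)
  stopifnot(length(p) == 1, length(n) == 1)
  if (p < 0 || p > 1) stop("inhibitory strength `p` must lie in [0, 1]")
  if (n < 1) stop("Hill exponent `n` must be >= 1")
  if (is.null(k)) {
    k <- if (form == "divisive") {
      if (p == 0 || p == 1)
        stop("divisive form needs 0 < p < 1 to derive k (or give k directly)")
      (1 - p) / p
    } else 1
  }
  stopifnot(length(k) == 1)
  if (k <= 0) stop("half-saturation `k` must be > 0")
  structure(list(p = p, k = k, n = n, form = form), class = "inhib_link")
}

#' @export
print.inhib_link <- function(x, ...) {
  cat(sprintf("inhibitory link (%s): strength %.0f%%, k = %g, n = %g\n",
              x$form, 100 * x$p, x$k, x$n))
  invisible(x)
}

#' Multiplicative inhibition factor of a link
#'
#' The factor by which an inhibitor at concentration `x` scales the
#' production it targets: `1 / (1 + (x/k)^n)` for divisive links (in `(0, 1]`,
#' suppression unbounded) or `1 - p * x^n/(k^n + x^n)` for saturating links
#' (in `[1 - p, 1]`). Nonincreasing in `x`; equal to 1 at `x = 0`.
#'
#' @param x Inhibitor concentration(s), >= 0.
#' @param link An [inhib_link()].
#' @return Factor(s) in `(0, 1]`.
#' @export
inhibition_factor <- function(x, link) {
  stopifnot(inherits(link, "inhib_link"))
  if (link$form == "divisive") {
    1 - hill_activation(x, link$k, link$n)
  } else {
    if (link$p == 0) return(rep(1, length(x)))
    1 - link$p * hill_activation(x, link$k, link$n)
  }
}
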