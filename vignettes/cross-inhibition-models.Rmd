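---
title: "Modelling BMP-FGF cross-inhibition: from motifs to tissue borders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling BMP-FGF cross-inhibition: from motifs to tissue borders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoswitch)
```

## The biological question

In the developing dorsal forebrain, BMP and FGF morphogens form opposing
activity gradients, and BMP target genes such as *Msx1* switch on sharply —
ultrasensitively — at a dose threshold, even though the immediate BMP
readout (nuclear pSmad) is graded. `morphoswitch` implements a family of
mechanistic ODE models asking *where* mutual inhibition between the two
pathways must act to create that switch, and what signatures each placement
leaves in a dose-response experiment.

Each pathway is reduced to three tiers: extracellular ligand (BMP, FGF), an
intracellular intermediate ($B_I$, $F_I$), and a transcriptional target
($B_T$, $F_T$). Activating steps are Hill functions; one inhibitory link per
direction connects the pathways. With three possible source tiers and three
target tiers per link there are $3^4 = 81$ topologies, which fall into four
behavioural classes:

* **STI** — simple target inhibition: the F-to-B link lands directly on
  $B_T$ and no loop forms.
* **SUI** — simple upstream inhibition: the F-to-B link lands upstream of
  $B_T$; still one-way.
* **CFF** — coherent feedforward: the B-to-F link feeds back onto the
  inhibitor feeding the F-to-B link, without closing a cycle.
* **CIPF** — cross-inhibitory positive feedback, the classic toggle switch:
  the two links close a double-negative (net positive) loop.

`enumerate_topologies()` reproduces the 9/18/18/36 partition, and
`classify_topology()` is checked in the test suite against an independent
graph-reachability oracle.

## The representative models

For the four representative models (mutual inhibition attached at the
intermediates or the target), the state is $(B_I, F_I, B_T)$ with

$$\frac{dB_I}{dt} = kc_1\,h(B; K_{tb}, n_1)\,[I_F] - K_{BI} B_I,$$

and analogous equations for $F_I$ and $B_T$, where
$h(x;k,n) = x^n/(k^n + x^n)$ and $[I_F]$ denotes the inhibition factor wired
in per class (`build_rhs()`). An auto-regulatory contrast model (AUTOREG)
adds a self-activation term $kc_a\,h(B_I;K_a,n_a)$ to $B_I$ instead of a
B-to-F link; it is the motif against which irreversibility is contrasted.

### The inhibition factor

Two functional forms of an inhibitory link are implemented
(`inhib_link()`). The default is the divisive repression used by classic
toggle-switch models, $1/(1 + (x/k)^n)$: suppression deepens without bound
as the inhibitor accumulates. The "strength" $p$ of a link is the
fractional suppression it exerts when its inhibitor sits at the unit
(maximal, non-dimensional) level, so $k = (1-p)/p$ for a linear link;
nonlinear links keep the same half-suppression point and sharpen the slope
around it. A strength-bounded alternative, $1 - p\,h(x;k,n)$, is available
via `form = "saturating"`. We made the divisive form the default after
finding that the bounded form cannot reproduce the class signatures this
package is built to study: because its disinhibition is capped at
$1/(1-p)$, a toggle loop built from bounded links frequently cannot resolve
in favour of the BMP side at saturating BMP, so maximum levels drop and no
ultrasensitivity emerges — contrary to the defining behaviour of the
feedback class. The inhibition half-saturation constants also carry inverse
concentration units in the underlying kinetic scheme, which is natural for
the divisive form.

### Non-dimensionalisation

`nondimensionalize()` rescales each species by its maximal steady level
(production/degradation ratio) and time by the target's turnover rate. The
dose-response *shape* (EC50 on the dose axis, apparent Hill coefficient) is
invariant; the maximal level scales by $kc_5/K_{BT}$. Both invariances are
asserted in the tests.

## Steady states: closed forms, the open loop, and the race

The acyclic classes (STI, SUI, CFF) admit closed-form steady states by
sequential substitution (`closed_form_bt()`); the test suite holds them to
the numerical integrator within $10^{-6}$ relative. CIPF has no general
closed form. Its loop is analysed through the monotone open-loop
characteristic (`open_loop_characteristic()`): clamp the $B_I$ value
feeding the B-to-F inhibition at $u$, equilibrate $F_I$, and return the
$B_I$ the loop would produce, $g(u)$. Because $g$ is a composition of two
nonincreasing maps it is nondecreasing, fixed points of the closed loop are
crossings $g(u) = u$, crossings alternate stable/unstable, and bistability
is exactly three crossings.

Two experimental protocols pick out branches of a bistable system:

* **off**: every dose is approached from the zero state (nothing
  expressed). In a bistable regime the outcome is decided by the *kinetic
  race* between the two pathways as both switch on — resolved by numerical
  integration (`integrate_to_steady()`), then snapped to the nearest stable
  fixed point. With the default unit timescales the race is decided by the
  balance of drives rather than by kinetic asymmetry.
* **on**: the system is pre-stimulated at saturating BMP ($100 \times
  K_{tb}$) and each dose is approached from there; by monotonicity this
  follows the largest-fixed-point continuation whenever the pre-stimulus
  lands on the high branch.

`hysteresis_curves()` computes both branches and measures the bistability
window: the maximal dose interval over which they differ by more than 1%
relative (well above solver tolerance, well below any effect of interest),
with edges refined by bisection. A knife-edge caveat: at the single dose
where the race flips sides the trajectory passes arbitrarily close to the
saddle, and any integrator (or cell) may linger there; window edges are
defined by the branch-difference predicate, which is insensitive to this.

## Dose-response characterisation

`compute_dose_response()` evaluates steady $B_T$ on a 40-point log grid
spanning $[K_{tb}/100,\ 100\,K_{tb}]$ (wide enough to resolve apparent Hill
coefficients up to about 10). `fit_hill()` fits
$y = y_{max} d^{n_H}/(EC_{50}^{n_H} + d^{n_H})$ by bounded least squares
(three restarts at $n_H$ = 1, 2, 4; EC50 started at the interpolated
half-max crossing; lowest residual kept). A fit is flagged (`ok = FALSE`)
when the relative RMS residual exceeds 5% of the fitted maximum or the
curve is degenerate; flagged fits are excluded from ensemble summaries, the
analogue of logging and excluding failed fits in a screening pipeline.
`max_asymptotic()` evaluates the maximum at $10^4 \times K_{tb}$ rather
than the largest grid dose, to capture asymptotic behaviour.
`response_change()` reports the three with/without-FGF ratios (maximum,
EC50, $n_H$) that discriminate the classes.

## Parameter sweeps and the property grid

`sample_parameters()` draws parameter sets in the non-dimensionalised
space: production equals degradation per species (unit species scales;
timescales unit by default and configurable), ligand-facing
half-saturations $K_{tb}, K_{tf}$ log-uniform over $[0.1, 10]$ (they only
set each ligand's dose scale), the target-activation half-saturation
$K_{tbt}$ log-uniform over $[0.2, 1]$ — a target whose half-point sits far
above the intermediate's unit range never responds, and one far below reads
out only the foot of the loop — and link strengths uniform on
$[0.5, 0.99]$. Four linearity contexts set the Hill exponents: context 1
all links linear, 2 core nonlinear, 3 inhibitory links nonlinear, 4 all
nonlinear, with nonlinear exponent 4. FGF is applied at $K_{tf}$, a fixed
half-activating dose: a moderate tonic FGF input engages the loop while
still letting saturating BMP out-compete it, matching the observation that
FGF has negligible effect on the target at high BMP.

These ensemble choices were calibrated once against the qualitative class
signatures reported for this system — maximum-level decrease for STI,
widespread EC50 increases, ultrasensitivity gains only for CFF (nonlinear
inhibitory contexts) and CIPF, hysteresis only for CIPF, and the
balance-diagonal structure of the bistable region in strength-strength
scans — and then frozen. Known residual mismatches, stated openly: with
strengths sampled down to 0.5, all-linear (context 1) CIPF loops sharpen
the response in only a minority of sets rather than nearly always (weak
linear mutual inhibition is simply too soft a mechanism at these
strengths), and the context-2 gain frequency sits near the 10% presence
threshold. Reproducing near-universal linear-context gains would require
concentrating the strength distribution above roughly 0.9, an extreme
regime we did not adopt as the default.

`run_context_sweep()` produces one record per sampled set (ratios, window
width in units of $K_{tb}$ so widths are comparable across sets, and a fit
QC flag); `summarize_grid()` converts ensembles into the
present/rare/absent grid with a 10% presence threshold;
`balance_scan()` maps bistability over strength or exponent grids;
`correlate_dnh_window()` computes the ultrasensitivity-hysteresis
correlation on log10 scales (both quantities are fold-change-like and span
orders of magnitude) with the window offset by the dose grid's resolution
floor ($0.01\,K_{tb}$) so monostable sets enter at the floor.

## Memory and washout

`classify_memory()` distinguishes none / hysteretic / irreversible: drive
the system on at saturating BMP, remove BMP (FGF held), and compare the
long-horizon target level against the off-state baseline (irreversible if
it stays above ten times baseline). Mutual inhibition can never be
irreversible — at zero BMP the $B_I$ drive vanishes and the target must
decay — whereas the AUTOREG contrast model with strong self-activation is
bistable at zero input and latches.

`simulate_washout()` is the in-silico analogue of the washout experiments:
pre-stimulate (or not), wash out, re-apply a test dose, read out later.
Persistent receptor-level signalling is modelled minimally as an
exponentially decaying residual effective dose with configurable time
constant `residual_tau` (the underlying kinetics are not published);
co-applying a receptor inhibitor zeroes the residual. With a long residual
the pre-stimulated population stays high at every re-applied dose —
apparent irreversibility — while blocking residual signalling (or waiting
long enough) reveals the two genuine hysteresis branches. Note that the
washed-out "off" population has its FGF side equilibrated, so its low
state persists across the full analytically bistable band; the branches
rejoin only above it.

## Multiple thresholds and tissue borders

`dual_loop_model()` couples two target genes to toggle loops sharing all
parameters except designated multiplicative perturbations.
`dual_ec50_analysis()` shows the dissociation: perturbations downstream of
the loop ($kc_5$, $K_{BT}$, $K_{tbt}$) leave the EC50 ratio at 1 (the
threshold is set by the loop's flip, not the readout leg) while scaling the
maximum; loop-level perturbations (link gains or $K_{BI}$) of 1.5-fold or
more shift the second EC50 by more than 5%.

`simulate_tissue()` places independent cells (no coupling, per the
cell-intrinsic premise) along opposing exponential gradients
$c(x) = A e^{-x/\lambda} + b$. Naive cells develop from the zero state, so
each cell's fate is its local race outcome and the expression border forms
at the **equivalence point** where the two intermediate drives balance
(`equivalence_point()`); the border is read as the half-tissue-maximum
crossing of the profile, and agreement with the equivalence point within
one cell spacing is asserted in the tests. Because the border is set by a
*ratio* of signals from opposing sources, proportional rescaling of tissue
length and both gradient length scales leaves the relative border position
exactly invariant for background-free exponentials (`scaling_test()`;
rescaling the tissue alone is the negative control). The pre-exposed
(`init_policy = "on"`) history is also exposed, since the developmental
history of bistable tissue is genuinely ambiguous.

`fit_exponential_gradient()` fits $A e^{-x/\lambda} + b$ with unknown
background, and `threshold_lengthscale()` inverts two response thresholds
a known distance apart into the implied gradient length scale
$\lambda = \Delta x / \log(c_{high}/c_{low})$ — for thresholds of 22 and
32 concentration units separated by 100 µm, ~267 µm, i.e. ~270 µm to the
nearest ten.

## Synthetic data

`gen_dose_response()`, `gen_washout_dataset()` and
`gen_gradient_profile()` emulate the study's measurement types: replicated
qPCR-style fold changes over a BMP dose series (defaults: EC50 8.3, $n_H$
3.7), washout readouts for on/off-pretreated populations, and noisy spatial
gradient profiles (default $\lambda$ = 290 µm). Noise is multiplicative
lognormal (fold-change errors are multiplicative; default $\sigma$ = 0.1 on
the log scale, 0.05 for imaging-derived gradients), and every generator is
deterministic given its seed. What these generators deliberately do *not*
emulate: Ct-level qPCR chemistry, primer efficiencies, reference-gene
normalisation, cell-composition drift in long cultures, or spatial
correlation in imaging noise — so passing recovery tests demonstrates the
estimators' correctness and precision under the declared error model, not
robustness to every artefact of real data.

## Numerical choices

Steady states are accepted when $\max |d/dt| < 10^{-9}$ relative to the
production scale (race integrations use $10^{-6}$: only the basin matters,
and the endpoint is snapped to the nearest stable fixed point); horizons
double up to seven times before non-convergence is flagged, and are scaled
to the slowest relaxation rate. Fixed points of the 1D characteristic are
bracketed on a 256-point grid and refined by `uniroot`; duplicate roots are
merged at $10^{-8}$ relative and stability is read from the sign of
$g(u) - u$ on either side. Window edges are bisected for 12 iterations
(resolution far below the reporting floor). Degenerate inputs — zero
ligand, flat curves, gradients dominated by background — are flagged, not
fitted.

## Problem sizes

The shipped test suite runs the ensembles at the sizes used for the
reported results: 500 sets for the context-3 correlation, 200 sets per
(class, context) cell for the property grid, 500 sets per class for
hysteresis exclusivity, and 100-seed Monte-Carlo loops for estimator
recovery. These sizes give Monte-Carlo error comfortably below every margin
asserted; larger ensembles changed no conclusion during development.
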