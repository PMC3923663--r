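# morphoswitch

Toggle-switch models of BMP–FGF cross-inhibition and gene-expression border
formation in the developing forebrain.

## The problem

Cells in the dorsal forebrain sit in opposing gradients of two morphogens,
BMP and FGF. BMP target genes such as *Msx1* switch on **ultrasensitively**
at a dose threshold — far more sharply than the graded nuclear pSmad signal
that reads BMP out — and the switch shows **hysteresis**: whether a cell is
on depends on where it started. `morphoswitch` is for modellers and systems
biologists who want to ask *where* mutual inhibition between two signalling
pathways must act to produce such behaviour, and what each placement
predicts for a dose-response experiment.

Each pathway is reduced to ligand → intermediate → target
(BMP → B_I → B_T, FGF → F_I → F_T), with Hill-function activation

y = x^n / (k^n + x^n),

and one inhibitory link per direction between the pathways. The 81 possible
two-link topologies fall into four classes — simple target inhibition
(STI), simple upstream inhibition (SUI), coherent feedforward (CFF) and
cross-inhibitory positive feedback (CIPF, the toggle switch). The package:

* enumerates and classifies all 81 topologies (9/18/18/36);
* builds the class ODEs and computes steady states (closed forms for the
  acyclic classes; monotone open-loop analysis and integration for CIPF);
* characterises BMP dose responses by maximum level, EC50 and apparent
  Hill coefficient nH, with and without FGF;
* screens parameter space under four link-linearity contexts and
  reproduces the qualitative class-signature grid;
* measures bistability windows, classifies memory (none / hysteretic /
  irreversible) against an auto-regulatory contrast model, and simulates
  washout experiments with persistent receptor-level signalling;
* shows how two toggle loops sharing components give two distinct EC50s,
  and how borders form at BMP–FGF equivalence points in a 1D tissue and
  scale with tissue size;
* generates synthetic qPCR-style dose-response, washout and gradient
  datasets so every stage is testable without external data.

## Worked example

A balanced, strongly nonlinear toggle; FGF applied at its half-activating
dose:

```r
library(morphoswitch)

p <- model_params(K_tbt = 0.5,
                  fb_link = inhib_link(0.9, n = 4),   # F_I -| B_I, 90%
                  bf_link = inhib_link(0.9, n = 4))   # B_I -| F_I, 90%

rc <- response_change("CIPF", p, fgf_level = 1)
rc
#> FGF-addition response change: max x1, EC50 x3.18, nH x25

hy <- hysteresis_curves("CIPF", p, fgf_level = 1)
hy
#> hysteresis: bistable window [0.2474, 1] (width 0.7527)

classify_memory("CIPF", p, fgf_level = 1)
#> memory class: hysteretic
```

Adding FGF leaves the maximal response unchanged (`max x1`), shifts the
EC50 up, and makes the response strongly ultrasensitive (`nH x25`) — the
toggle-switch signature. The same parameters are bistable over roughly a
four-fold dose window, and the memory is hysteretic, never irreversible:
removing BMP always switches the target back off.

Border formation under opposing exponential gradients:

```r
L  <- 1000  # um
bmp <- gradient_profile(A = 50, lambda = 270, L = L, decreasing = FALSE)
fgf <- gradient_profile(A = 50, lambda = 270)

simulate_tissue("CIPF", p, bmp, fgf, L)
#> 1D tissue, 200 cells over 1000 um: border at 500.1 um (0.5 L) [bistable zone]
equivalence_point(bmp, fgf, p, L)
#> [1] 500
threshold_lengthscale(22, 32, 100)   # two thresholds 100 um apart
#> [1] 266.8848
```

The expression border forms at the point where the two pathway drives
balance; two response thresholds ~1.5-fold apart and 100 µm distant imply a
gradient length scale of ~270 µm.

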