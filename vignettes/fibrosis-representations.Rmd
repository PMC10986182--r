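---
title: "Modeling fibrosis representations and reentry at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling fibrosis representations and reentry at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibrosim)
```

## The problem

Non-ischemic cardiomyopathy patients with fibrosis visible on
late-gadolinium-enhancement (LGE) imaging are at elevated arrhythmia
risk, and computational models of their ventricles are used to probe how
the fibrotic substrate initiates reentry. The same LGE map, however, can
be turned into an electrophysiological substrate in very different ways.
`fibrosim` implements the two families this package is built to compare:

* **Cleft models** represent interstitial fibrosis by stochastically
  severing connections between neighboring mesh elements, creating
  microscopic no-flux boundaries that force wavefronts to zigzag.
* **Non-cleft models** threshold the LGE map into a dense *core*
  (non-conducting at `1e-7` S/m, or slowly conducting at `0.01` S/m, the
  conductivity of collagen) surrounded by a *border zone* with reduced
  conduction velocities.

Both families can additionally reduce regional conductivity step-wise
with LGE intensity and apply ionic remodeling to fibrotic myocytes. The
package generates synthetic substrates, runs programmed S1--S4 pacing on
an anisotropic monodomain solver, detects and back-traces reentry to its
initiation sites, and tests segment-level associations between fibrosis
burden and reentry counts.

## The cleft rule

A face between neighboring elements `a` and `b` is severed with
probability

$$p = p_{\max}\, I \, |\cos\theta|^{\alpha}$$

with `I` the face LGE intensity (mean of the two adjacent elements),
`theta` the angle between the face normal and the local fiber-sheet
normal, `p_max` the density scale and `alpha` the anisotropy sharpness.
Two renderings of the anisotropy term are defensible from the printed
formula (`alpha` as an exponent, or inside the cosine argument); the
package implements the exponent form as the default because an exponent
is the standard sharpening device in this class of cleft models, and
exposes `alpha_mode = "cos_arg"` for the alternative. On a 2D sheet the
sheet normal is the in-plane normal to the fiber vector, so clefts align
*along* fibers, which is the histological pattern interstitial fibrosis
follows. Ten `(p_max, alpha)` combinations, sorted by the number of
severed faces, define the global cleft-density index `fib_max` 0--9; the
exact combination grid behind the published index is supplementary
material that is not public, so the default ladder sweeps
`p_max = 0, 0.1, ..., 0.9` at `alpha = 2` and is fully configurable.

Elements isolated from all neighbors are removed from the model. The
no-flux contract is structural: a severed face contributes exactly zero
coupling in the assembled diffusion operator, which stays symmetric with
zero row sums (tested directly).

## Membrane model and remodeling

Every element carries a human ventricular myocyte model (ten Tusscher
2006 kinetics) with the late sodium current of the O'Hara--Rudy model
added to the total current. Two unstated choices matter and are pinned
as follows:

* **Transmural variant**: epicardial, because its steady-state APD90 at
  a 500 ms cycle length (275 ms here) is closest to the 280 ms healthy
  reference; `endo` and `M` are selectable.
* **Baseline late-sodium conductance**: the published endocardial value
  `g_NaL = 0.0075` mS/uF, exposed in `cell_params()`.

Fibrotic-region remodeling multiplies eight currents by factors measured
in hypertrophic cardiomyopathy myocytes (`hcm_remodeling_factors()`):
late sodium x2.07, L-type calcium x1.19, IKr x0.66, IKs x0.73, Ito
x0.15, IK1 x0.85, sodium-calcium exchange x1.34, SERCA x0.57. It is
applied *binarily* to every element with positive LGE intensity in
remodeled populations -- not graded with intensity -- matching the
modeling choice this package reproduces. After 1,000 pre-pacing beats at
500 ms the healthy and remodeled cells repolarize at 275 and 334 ms
(APD90), inside the +-10 ms band around the 280/330 ms references that
reflects the two pinned choices above.

Integration is Rush--Larsen for Hodgkin--Huxley gates and forward Euler
for voltage and concentrations at `dt = 0.02` ms (halving `dt` moves
steady-state APD90 by < 1 ms and cable velocity by < 1%). Tissue runs
evaluate rate constants from a fused lookup table on a 0.02 mV grid;
the table path is tested against direct evaluation (APD90 agreement to
0.1 ms) and reversal potentials are refreshed every 0.5 ms, two orders
of magnitude below the timescale on which concentrations move.

## Monodomain solver and conductivity calibration

The spatial discretization is a collocated finite-difference lattice:
one membrane node per element center at 530 um spacing, the element
scale of the anatomical meshes this desk-scale rebuild stands in for.
Face conductances combine the two adjacent elements' conductivity
tensors (`sigma_t + (sigma_l - sigma_t) f f'` projected on the face
normal) by harmonic mean. The monodomain constants are the standard
surface-to-volume ratio 1400 /cm and 1 uF/cm^2 capacitance; stimuli are
10 ms, 100 uA/uF pulses over ~1 mm^3 electrode element sets; activation
is the upward crossing of -40 mV (threshold configurable).

Conduction-velocity targets are translated to conductivities **only**
by calibration on a 10 cm, 530 um cable (`calibrate_conductivity()`,
bisection to 0.1 cm/s): the discrete lattice depresses slow velocities
well below the continuum square-root law (the x4-conductivity velocity
ratio is 3.3 at 530 um and 2.1 at 120 um), and active propagation fails
entirely below ~3.5 cm/s at 530 um, so analytic scaling would mistune
every fibrotic band. The shipped table (`default_conductivities()`)
covers healthy tissue (54.4 / 33.5 cm/s), the four cleft-model intensity
bands (transverse reduced 40% then 80%; longitudinal additionally
reduced 40% / 80% in the upper two bands), and the non-cleft border zone
(43.2 / 17.9 cm/s). Band edges are half-open `[lo, hi)` with the top
band closed, so an intensity of exactly 0.25 belongs to the 25--50%
band.

## Pacing protocol

The induction protocol delivers an S1 drive train (default 6 beats at
600 ms) and up to three extrastimuli. The published protocol's exact
timings live in unavailable supplementary material, so the package
implements the clinical-style family it cites: each stage scans its
coupling downward in 10 ms steps from 50 ms above the previous stage's
final coupling until capture is lost, and keeps the shortest captured
coupling. Capture means a configurable fraction (default 90%) of
conducting elements activates within one cycle; the 0.01 S/m core is
excluded from the denominator because it sits below the lattice's active
propagation threshold. No further extrastimuli are delivered once
reentry is detected, and every run ends with a 4,000 ms observation
window (or stops early once all activity has ceased). Tissue states are
initialized from single cells pre-paced 1,000 beats at the drive cycle
length.

Internally the protocol keeps a state checkpoint at the onset of the
next pending stimulus, so every coupling probe is an exact continuation
rather than a re-simulation of the drive train. For qualitative
desk-scale comparisons the scan can be replaced by explicit couplings
(`fixed_couplings_ms`), which removes the probe continuations that
otherwise dominate runtime without changing which substrate is more
inducible.

## Reentry identification and tracing

Reentry is any activation after the final pacing-induced activation of
an element: operationally, activations beyond the n-th (n captured
stimuli) or later than one cycle after the last stimulus (which catches
elements that missed paced beats through local block). Repeated
activations of the same element separated by less than 50 ms are merged
to the first -- isolated elements beside clefts re-register voltage
spillover without any reentrant wave -- and the rule is strict (`< 50`),
idempotent, and tested at the boundary.

Initiation tracing walks the merged reentrant pattern in 10 ms steps
(the voltage-frame resolution): an initiation cluster is a maximal
connected element set, first reactivated in the same step, all of whose
outside neighbors reactivate strictly later or never. Clusters are
confined to the earliest step at which they appear and must reach
`min_cluster` elements; the published 1,000-vertex floor presumes
~10-million-element meshes, so the default here scales as
`max(20, 1e-4 * n_elements)` and the absolute value is configurable.
The implementation is validated against a brute-force per-step oracle on
small meshes and against planted kinematic fixtures whose true sources
are known exactly (including a two-source fixture with onsets 30 ms
apart that must yield two clusters at distinct steps).

A reentry is *sustained* when reentrant activity persists into the final
frame of the observation window. Morphology is a feature heuristic, not
the visual classification it proxies: clusters whose surrounding 5 mm
mean LGE is below 10% are labeled Type 2 (functional rotors live at
healthy--fibrotic interfaces, whose local mean LGE ranged 0--9% in the
reference analysis), all others Type 1; outputs carry a
`morphology_source = "heuristic"` flag.

## Features and statistics

Around each initiation site, `local_lge_features()` summarizes the
Euclidean 5 mm ball: mean and maximum LGE (percent) and LGE volume (mL,
any element with positive intensity). Segment-level analysis tiles the
sheet into 17 contiguous equal-area segments (the desk-scale analogue of
the 17-segment ventricular parcellation), counts initiations per
segment, and fits a negative binomial regression of counts on a
covariate of interest adjusting for LGE volume. The published analysis
entered geometry, parameter level and segment as random effects; at
desk-scale sample sizes a mixed NB fit is fragile, so the default enters
them as fixed adjusters, with `backend = "mixed"` (lme4) available when
the design supports it. Recovery of a known slope, confidence-interval
coverage and null type-I error are exercised by simulation in the test
suite.

## What the synthetic generator does and does not emulate

The generator produces regular 2D sheets (or thin-3D slabs with linear
transmural fiber rotation) at 530 um spacing, with smooth radially
decaying LGE patches (dense core, gradual border; exactly zero outside),
optional clipped Gaussian intensity noise, contiguous segments, and
kinematic activation fixtures. One master seed forks deterministically
into per-stage streams (mesh / LGE / cleft / protocol offsets), so every
artifact is bit-reproducible.

It does **not** emulate patient anatomy: no biventricular geometry, no
rule-based transmural fiber fields beyond linear rotation, no imaging
segmentation noise structure, and sheet sizes two orders of magnitude
below anatomical meshes. Consequently the package reproduces the
*mechanistic* findings (conduction slowing with cleft density, core-size
effects, interface rotors vs channel meander, LGE-reentry association)
but not patient-specific reentry counts, which depend on the unavailable
imaging data and 10-million-element meshes.

## Numerical choices and problem sizes

* `dt = 0.02` ms, voltage frames every 10 ms, activation threshold
  -40 mV, quiescence stop when all voltages stay below -65 mV.
* Calibration tolerance 0.1 cm/s; APD tolerance of the acceptance band
  +-10 ms (unstated cell variant and baseline late-sodium conductance).
* Cluster tie-break: within-step ties join a cluster; the
  strictly-later condition on outside neighbors enforces earliest-step
  confinement.
* Degenerate inputs: all-zero LGE maps are valid healthy controls for
  cleft populations but rejected for non-cleft models (the core
  threshold is undefined); empty reentrant sets trace to empty cluster
  lists; capture failure at the first coupling ends a stage.
* Test problem sizes are chosen for a single-CPU desk run: unit tests
  use sheets up to 72 x 72; the qualitative induction comparisons run
  one 64 x 64 geometry (3.4 cm) with a 12 mm patch and the
  fixed-coupling protocol (360/330/305 ms after a 2-beat, 500 ms
  drive); activation-time trends use 40 x 40 sheets over five seeds.
  The full published design (5 geometries x 37 models x 17 sites =
  3,145 runs) is enumerated and schedulable through `run_study()` but
  not executed by the test suite.
* Desk-scale initiation kernels are one or two elements wide -- the
  re-exciting wave squeezes through individual cleft channels -- so the
  qualitative analyses trace with `min_cluster = 1` while the package
  default keeps the mesh-scaled rule above.
* At these sheet sizes no initiation site's 5 mm surround is dilute
  enough (mean LGE < 10%) to receive the Type 2 label: interface-block
  kernels sit a few millimeters inside the patch (mean LGE ~20-30%)
  versus deep-channel kernels (~45-80%). The morphology *contrast* the
  label encodes -- interface-mechanism reentry initiates in lower LGE
  than channel meander -- is preserved and tested on the features
  directly; the label itself becomes informative only on geometries
  large enough for rotors to stand off the fibrotic boundary.

## Known limitations

* Collocated finite differences on lattices, not finite elements on
  anatomical meshes; the cleft no-flux contract is
  discretization-independent, but absolute inducibility is not.
* At 3--5 cm sheet sizes the reentrant wavelength is comparable to the
  domain, so induction is rarer and less varied than on anatomical
  ventricles; the package treats induction comparisons as ordinal
  (more/less inducible), never as absolute rates.
* Morphology labels are an LGE-feature heuristic standing in for visual
  classification.
* The mixed-effects NB backend can fail to converge on small designs;
  the fixed-adjuster default trades some fidelity to the published
  model for robustness.
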