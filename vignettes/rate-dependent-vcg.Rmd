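---
title: "Rate-dependent vectorcardiogram analysis of ventricular scar: model and methods"
author: "vcgscar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-dependent vectorcardiogram analysis of ventricular scar: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcgscar)
```

## The problem

Patchy replacement fibrosis in non-ischaemic dilated cardiomyopathy (NICM)
rarely blocks electrical activation outright; wavefronts cross it slowly,
and the slowing grows at rapid pacing because partially refractory fibrotic
tissue recovers late. This *rate-dependent* conduction slowing is a marker
of arrhythmic risk, but measuring it directly requires invasive pacing
studies. The vectorcardiogram (VCG) — the trajectory of the net cardiac
dipole, reconstructable from a standard 12-lead ECG — offers a non-invasive
window: if a scar slows conduction more at a fast rate than at a slow one,
metrics of the QRS loop should differ between the two rates, and the
*pattern* of differences should depend on where the scar sits.

`vcgscar` implements that analysis chain end to end: a patch-dipole forward
model that synthesises 12-lead ECGs for parameterised scars at two pacing
rates, Kors VCG reconstruction, spatial-velocity QRS delimitation, a
QRS-loop metric suite with paired slow/fast differences, and scar
localisation (LV free wall vs septum) by per-metric ROC analysis and random
forests.

## The forward model

### Sources

The ventricles are discretised into `n_patches` equal-mass patches, each an
elementary current dipole oriented along the local endo-to-epicardial
direction (the predominant propagation direction of the activation
wavefront). The net dipole is a linear superposition,

$$\mathbf d(t) = \sum_i s_i\,\hat{\mathbf u}_i\, w(t - t_i),$$

where $t_i$ is patch $i$'s activation time and $w$ a Gaussian activation
waveform (standard deviation 8 ms — the width of an elementary
depolarisation contribution after low-pass filtering). Patches carry
universal ventricular coordinates (UVC): rotational $\varphi \in [-\pi,
\pi]$ (0 mid-septum, $\pm\pi$ LV free wall), transmural $\rho \in [0, 1]$
(0 LV endocardium, 1 the epicardial/RV-endocardial surface), apicobasal
$z \in [0, 1]$.

The geometry is a two-chamber idealised shell: a prolate half-ellipsoidal
LV (length 8 cm, basal radius 3 cm, wall 1 cm) plus an RV free wall —
a thinner shell segment wrapped around the septal side, one quarter of the
patch mass — that lies just outside the LV epicardium. Because the
activation root sites all sit on the LV endocardium, the RV depolarises
through *trans-septal* conduction; this matters below. RV patches carry
$\rho = 1$, the surface label the UVC convention assigns to the
epicardial/RV-endocardial sheet, which automatically keeps them outside
any midwall scar box.

### Activation

Activation times are shortest-path arrival times over a symmetrised
6-nearest-neighbour graph on patch positions, from a configurable set of
root sites (default 8) standing in for the Purkinje network, with
prescribed times staggered over ~10 ms. The sites span
$\varphi \in [-2.2, 2.2]$: the posterobasal free-wall seam has no direct
input and is therefore the last region to depolarise, as in normal hearts.
This detail is load-bearing: it gives the end-of-QRS dipole a coherent
direction. With rotationally symmetric roots the late basal ring's outward
dipoles cancel and the end-of-QRS dipole becomes a small, direction-unstable
residual.

The healthy conduction velocity (0.09 cm/ms) is set so that control total
activation is near 100 ms, matching physiological sinus activation.

### Scar

A scar is a box in UVC space. Following the observed density structure of
NICM scar it is stratified into a dense core (central 2/3 of the scar
interval on *every* axis), a boundary zone (central 5/6) and a low-density
outer region. Patches in the three zones are removed — replacement fibrosis
is non-conducting collagen — independently with probabilities
$(p_\text{dense}, p_\text{BZ}, p_\text{low}) = (0.9, 0.75, 0.6)$. Removed
patches contribute no dipole and do not conduct. The per-axis reading of
"central 2/3" (rather than a radial one) was chosen for separability and
testability; the zone of a point depends on each axis independently.

Surviving scar tissue conducts slowly: edge traversal times are multiplied
by 2 in the dense core and 4/3 elsewhere in the scar, surrogates for the
50% and 25% conduction-velocity reductions of dense and intermediate
fibrosis. Because the wall is only a couple of patch layers thick, a
naive endpoint-based rule lets endo-to-epi edges hop *over* midwall scar
between two healthy endpoints; the slowing factor therefore also samples
the zone at the edge midpoint, with trapezoid-with-midpoint weights
$(f_a + 2 f_\text{mid} + f_b)/4$. Without this the trans-septal delay is
rate-independent and the septal signature disappears.

Rate dependence enters as a multiplicative stress factor (default 3)
applied to the scar slowing factors at the rapid rate only (basic cycle
length < 450 ms). The underlying physiology — incomplete recovery of
fibrotic tissue at short cycle lengths — is out of scope; the surrogate
reproduces its directional consequences. The default stress makes the
largest LV scar prolong total activation by well over 30% versus control
at rapid pacing, while control activation is *identical* at both rates by
construction (the factor applies only inside scar).

### Leads

The eight independent leads (I, II, V1–V6) are generated as
$L\,\mathbf d(t)$ with $L$ the Moore–Penrose pseudo-inverse of the Kors
matrix, and the four dependent limb leads by their exact linear relations
(III = II − I, aVR = −(I+II)/2, aVL = I − II/2, aVF = II − I/2). Because
the Kors matrix has full row rank, applying the Kors transform to a
simulated ECG recovers $\mathbf d(t)$ to machine precision — the
generator's ground truth is available to every downstream test, and the
round trip is verified to ≤ 1e−9 relative error.

```{r roundtrip}
scen <- simulation_scenario(600, scar_definition("none"), seed = 1,
                            n_patches = 200)
ecg <- simulate_scenario(scen)
max(abs(kors_transform(ecg)$xyz - attr(ecg, "dipole")))
```

## QRS delimitation and metrics

The VCG components are low-pass filtered (zero-phase Butterworth, order 2,
40 Hz — the standard QRS bandwidth; the filter is configurable and can be
disabled for analytic work), differentiated by central differences
(one-sided at the boundaries), and combined into the spatial velocity
$\sqrt{v_x^2 + v_y^2 + v_z^2}$. QRS onset is the first sample whose
spatial velocity *strictly* exceeds 0.15 of its maximum; the end is found
the same way scanning backward. Indices are 1-based, the window closed,
and plateau ties at the maximum resolve to the first occurrence. Because
the threshold is relative, delimitation is invariant to uniform scaling,
and the window is monotone (shrinking) in the threshold fraction.

Over the QRS window the package computes: QRS duration; signed trapezoidal
areas of each component about a 0 mV baseline (the simulated signal is
isoelectric outside the QRS; a QRS-onset baseline is available by option)
combined as $\sqrt{A_x^2+A_y^2+A_z^2}$; the magnitude-weighted average
azimuth (circular mean, since azimuth wraps) and elevation (arithmetic
weighted mean on $[0^\circ, 180^\circ]$, measured from the +y axis); mean
and maximum dipole magnitudes with the time of the maximum (first
occurrence wins ties); and the dipole vectors at QRS start, mid-point
(floor of the index average) and end, the maximum-magnitude dipole, and
the mean weighted dipole (normalised vector sum; a unit-weighted variant
is available by option, as both weightings appear in the field).

Paired slow/fast (600 ms / 300 ms cycle length) differences use these
conventions, chosen to reproduce the signs reported for torso-scale
simulations of the same protocol: percentage deltas
$100\,(x_\text{fast}-x_\text{slow})/x_\text{slow}$ for magnitudes and
area; $\Delta QRSd = QRSd_\text{slow} - QRSd_\text{fast}$ (negative when
rapid pacing prolongs the QRS); angle differences between corresponding
dipole vectors via $\mathrm{atan2}(\lVert a\times b\rVert, a\cdot b)$ —
algebraically the arccos of the clipped normalised dot product, but exact
at 0° and 180°, so a scar-free pair reports *exactly* zero throughout.

## The synthetic cohort

The default cohort mirrors a systematic sweep of scar geometry and density
in the two locations most prevalent in NICM: per location, sweeps of
$\varphi$ (4 ranges LV, 5 septal), $\rho$ (5 ranges) and $z$ (4 ranges)
with the other coordinates at their maxima (LV: $\varphi\in[\pi/2,\pi]$,
septum: $\varphi\in[-1,1]$; $\rho\in[0.1,0.9]$; $z\in[0.3,0.9]$), plus
reduced-density variants of the largest scar (2 LV, 1 septal), giving 15
pairs per location — 30 scarred pairs plus one scar-free control pair,
each simulated at both rates with a shared scar realisation.

Because the surrogate control is exactly rate-neutral, the package also
provides *jittered control replicates*: control pairs whose rapid member
receives physiological beat-to-beat variability — Gaussian root-timing
jitter (5 ms), per-patch lognormal strength jitter (sdlog 0.1) and one
common-mode lognormal amplitude factor per beat (sdlog 0.05, the
respiratory/positional modulation that dominates beat-to-beat amplitude
variability in recorded ECGs). The common-mode term matters: independent
per-patch jitter cancels as $1/\sqrt{N}$ in the net dipole and would
misrepresent measured variability by an order of magnitude. These
replicates are the non-degenerate control distribution against which
scar-induced rate dependence is compared.

The mechanisms then separate locations the way the physiology predicts:
LV free-wall scar removes late-activated dipole mass, so the
spatial-velocity tail of its slowed survivors falls below the detection
threshold and the end-of-QRS dipole angle difference (dTQRSend) drops
*below* the control jitter floor; septal scar delays trans-septal (RV)
activation more at the rapid rate, pushing dTQRSend *above* it; and septal
scar barely perturbs the QRS area's rate response relative to control
variability. These are distribution-level orderings with overlap — on some
cohort realisations an individual ordering inverts, which is why the test
suite asserts them by majority vote over five cohort seeds.

## Classification

The feature table (one row per scenario pair, 12 delta metrics) feeds:

* `roc_curve()`: an explicit threshold sweep over the observed values,
  higher value = predicted positive, positive class fixed as LV free wall,
  AUC by trapezoidal integration. The orientation is never flipped, so an
  inverted metric legitimately scores below 0.5; AUC equals the
  Mann–Whitney concordance probability, which the tests verify
  exhaustively on small instances.
* `forest_classify()`: random forests (Gini splits, unrestricted depth,
  bootstrap sampling; 20 or 1000 trees in the reference protocol) for the
  two independent binary questions *is the scar in the LV free wall* and
  *is it in the septum*, with stratified 5-fold or leave-one-out
  cross-validation, seeded (default 42) for exact reproducibility.
  Stratification of the 5-fold split is this package's choice (the
  reference protocol does not state it); fold assignment deals shuffled
  within-class indices round-robin, and empty folds are dropped.
  Importances are the normalised total Gini impurity decreases of a forest
  trained on the full table, matching the convention of reporting a single
  importance chart. Control rows are excluded from localisation by default
  (includable by flag); with them excluded the two questions are
  complements, and their importance rankings correlate accordingly.

```{r forest, eval = FALSE}
cohort <- make_cohort(seed = 42)
features <- cohort_features(cohort)
forest_classify(features, target = "lv", n_trees = 1000,
                cv_scheme = "n_fold", seed = 42)
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_patches` | 1000 | – | resolves directional effects above discretisation noise at interactive cost |
| `waveform_sd` | 8 | ms | width of an elementary activation contribution |
| `sampling_rate` | 1000 | Hz | standard high-fidelity ECG sampling |
| `duration` | 500 (cohort) | ms | covers the slowest scarred activation plus waveform tails |
| `conduction_velocity_cm_ms` | 0.09 | cm/ms | control total activation ≈ 100 ms |
| `rate_stress` | 3 | – | largest LV scar ≥ +30% activation time at rapid pacing |
| `slow_factor_dense` / `_intermediate` | 2, 4/3 | – | 50% / 25% conduction-velocity reduction |
| `p_dense, p_bz, p_low` | 0.9, 0.75, 0.6 | – | replacement-fibrosis densities by zone |
| `threshold_fraction` | 0.15 | – | spatial-velocity QRS threshold |
| filter | Butterworth 2, 40 Hz | – | QRS bandwidth; zero-phase to preserve timing |

## Numerical choices and degenerate inputs

Strict `>` at the QRS threshold; first occurrence wins ties at the
spatial-velocity and dipole maxima; mid-point index uses floor; signed
(not absolute) component areas enter the Euclidean combination; angles via
`atan2` as above. Root sites that land on removed patches re-seed to the
nearest survivor in UVC distance; surviving patches disconnected from
every root are flagged, excluded from the ECG, and warned about. All-zero
windows, single-class ROC inputs, zero slow-pacing denominators and
too-short recordings raise informative errors rather than propagating
NaN. Every operation is a pure function of its inputs and seed; the
global RNG state is never disturbed.

## What the generator does and does not emulate

It reproduces: dipole-mass loss and its effect on loop morphology;
rate-dependent conduction slowing confined to scar; trans-septal RV
activation; the two-rate paired protocol; stochastic scar realisations.
It does not contain ionic dynamics, wavefront curvature or fractionation,
torso inhomogeneity, atrial activity or T-waves, measurement noise beyond
the jitter model, or a personalised torso lead field — the lead projection
is the algebraic pseudo-inverse of the Kors matrix, chosen so that
reconstruction is exact rather than anatomically calibrated. Passing tests
therefore demonstrate correctness of the analysis chain and directional
fidelity of the mechanisms, not quantitative agreement with tissue-scale
simulation or patients; printed magnitudes (e.g. a −42 ms control ΔQRSd
under global rate stress) are outside the surrogate's remit.

Problem sizes used by the test suite — 1000 patches, 31 + 15 scenario
pairs per cohort, five cohort seeds, 200 removal realisations, forests of
up to 1000 trees — were chosen as the smallest at which the Monte-Carlo
checks have comfortable statistical margins.

## Known limitations

The LV-vs-control dTQRSend ordering is a statement about overlapping
distributions; single cohorts can invert it. The UVC box scar is convex
and axis-aligned — real NICM scar geometry is not. The jitter model is a
stand-in for all sources of control rate dependence (notably global
refractoriness at short cycle lengths, which real control hearts show and
the rate-neutral surrogate deliberately omits). Scar enlargement is
guaranteed monotone in removed mass only for concentric enlargements:
because removal draws are coupled through one uniform per patch,
off-centre growth can demote a patch's zone and resurrect it.
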