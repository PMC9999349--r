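---
title: "Quantifying membrane-bound actin networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-bound actin networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macnet)
```

# The measurement problem

A minimal actin cortex is a quasi-2D network of actin filaments coupled to
a supported lipid bilayer through a linker protein (ezrin in its active
form). Fluorescence micrographs of such networks are analyzed for four
families of quantities:

1. **architecture** — how much filament is on the membrane (skeleton
   network density), how interconnected it is (node density), and how
   bundled (relative bundling factor);
2. **orientational order** — the scalar nematic order parameter
   `q = 2⟨cos²θ − 1/2⟩` of the local filament orientations;
3. **contractile dynamics** — how the network reorganizes after myosin II
   binds: correlation traces, velocity fields, and a three-state call
   (contracting / partially contracting / noncontracting);
4. **interface physics** — layer thickness from optical-thickness steps
   and lipid mobility from FRAP recovery.

All estimators run on images; since raw experimental data of this kind is
rarely shared, the package also generates synthetic micrographs with
known ground truth, and its test suite is built around recovering that
truth.

# The synthetic-data generator

Filaments are straight segments by default: the persistence length of
actin (~10 µm and far larger for bundles) exceeds the filament lengths at
this field of view, so curvature within one filament is a second-order
effect. An optional per-vertex direction jitter (`bend_sd_rad`) produces
gently curved polylines when needed. Polyline vertices are spaced 0.5 µm
apart so that prescribed flows can bend filaments.

Orientations respect the nematic (headless) symmetry: the doubled angle
`2θ` is drawn from a von Mises law about the doubled local director and
halved, so `orientation_kappa = 0` gives exactly uniform orientations on
`[0, π)` and large κ collapses onto the director. Directors are constant
within `n_director_domains` Voronoi domains. Bundles are rendered as
intensity multiples on a single centerline — matching how the bundling
factor reads intensity at skeleton pixels — rather than as resolvable
parallel filaments. Each filament contributes a Gaussian ridge
(line-spread SD `psf_sigma_um`, default 0.2 µm, a realistic confocal
line-spread); the camera model is Poisson shot noise on signal plus
background followed by Gaussian read noise, the standard CCD/sCMOS
cascade. Ground-truth nodes are the exact pairwise segment
intersections.

Contraction series are kinematic: filament vertices within
`capture_radius_um` of their nearest aster move toward it at a constant
speed `v0_um_per_s`, never overshooting the center, while the myosin
channel accumulates Gaussian puncta at the aster centers and the whole
frame bleaches geometrically. No force balance or motor kinetics is
modeled — the pipeline reads out flow signatures, not mechanics, so
prescribing the flow gives exact ground truth at negligible cost.
`mode = "partial"` confines the flow to the left image half;
`mode = "none"` forces zero flow.

Default study conditions (used by the tests and analysis scripts): 128²
px at 0.2 µm/px (a 25.4 µm field), 60 filaments of mean length 5 µm,
22 frames at 10 s, `v0 = 0.08 µm/s` and a 10 µm capture radius — speeds
and time scales in the range reported for reconstituted actomyosin
contraction, chosen so that collapse completes within the series while a
background network persists (full-field capture empties the frame and
leaves nothing for late-time velocimetry). The generator emulates the
*statistical structure* the estimators assume — ridge-like filaments,
π-periodic orientations, inward flows, punctate myosin — but not optical
aberrations, uneven illumination, filament treadmilling or out-of-plane
motion; passing its tests therefore validates estimator correctness, not
robustness to every artifact of real data.

FRAP traces solve free 2D diffusion of the mobile pool after a
uniform-disc bleach exactly in time on a fine periodic grid (heat-kernel
multiplication in Fourier space), with the domain sized beyond the
diffusion length; the immobile pool keeps its bleached profile. The
binding traces are piecewise-constant optical-thickness levels plus
Gaussian readout noise.

# Skeletonization (tube filter)

Stages: CLAHE (via EBImage, tile 64 px, clip limit 2) → Gaussian
pre-filter (σ = 1 px) → Hessian of the corrected image at
derivative-of-Gaussian scale σ (default 2 px, ~half the rendered filament
width, the matched-filter optimum; both stage orders CLAHE↔smooth are
selectable, equalize-first being the default) → per-pixel score
`max(−λ₂, 0)` with λ₂ the algebraically smaller eigenvalue, so a bright
ridge (strongly negative curvature across, ~zero along) scores high while
blobs and valleys score zero → adaptive threshold against a
Gaussian-weighted local mean (block 51 px) plus an offset → a 3×3
morphological closing of the mask (equalization flattens the bright
plateau where filaments cross, which dents the response and can punch a
small hole right at the junction) → topology-preserving thinning →
4 iterations of spur pruning. Thinning is two-pass (Zhang–Suen) to its
fixed point followed by a sequential pass that deletes every pixel whose
removal neither breaks local 8-connectivity nor shortens a branch —
Zhang–Suen alone leaves 4-connected staircases on diagonals whose corner
pixels would masquerade as junctions. The result is deterministic,
preserves 8-connected components, and is idempotent. Reflective padding
avoids spurious border ridges.

After thinning, connected components smaller than `min_object_px`
(default 14 px, ~1.4 µm of filament) are discarded: specks of that size
are exactly what camera noise leaves behind once CLAHE has amplified a
signal-free region to full contrast, and at matched size they are
indistinguishable from real fragments. This gives the pipeline a
detection floor — structures shorter than ~1.5 µm (including sub-2 µm
stubs of border-clipped filaments) do not survive — in exchange for a
skeleton density on blank noisy frames of a few 10⁻³ or less.

The threshold offset deserves a note. The literal rule
"response > local mean" marks roughly half of all pixels foreground in
any signal-free region, because the response is non-negative and noise
fluctuates about its local mean; CLAHE makes this worse by amplifying
pure background noise to full contrast. Because thresholding happens
*after* contrast equalization, the response lives on a normalized scale
whose noise floor is set by the smoothing and derivative scales, not the
camera gain, so a fixed offset is meaningful across images. The default
0.006 balances two failure modes that were measured directly: larger
offsets delete substantial stretches of the weakest ridges in busy tiles
(CLAHE compresses their equalized contrast) and with them the junctions
they form, while smaller ones let blank noisy frames pass a dense
speckle of noise. The small-object floor above removes what noise still
gets through. `offset = 0` restores the literal rule.

# Network metrics

Skeleton density is the foreground fraction of the thinned mask. Node
pixels are skeleton pixels with more than two foreground 8-neighbors; an
X-crossing typically flags a small cluster of adjacent node pixels, so
8-connected clusters are merged to one intersection (centroid) — the
per-pixel rule alone over-counts crossings. Both the raw node-pixel
count and the merged intersection count are reported, since either
convention appears in practice. Nodes within 2 px of the border are
discarded (thinning artifacts), and junction clusters closer than 4 px
are fused: thinning necessarily splits an X-crossing into two Y-joints
about one ridge width apart, which would otherwise double-count. The
localization of detected intersections is limited by the optics, not the
estimator: two Gaussian ridges crossing at angle θ merge into a single
ridge over roughly `2w/tan θ` pixels (w the rendered ridge width), so
junctions of shallow crossings are erased before any pixel rule can see
them — on synthetic truth, crossings at ≥60° localize to within 3 px
essentially always, while the hit rate decays below ~40°. The bundling
factor subtracts a
per-image background (median of non-skeleton pixels; option `off` to
mirror the bare masked mean) before averaging intensity over skeleton
pixels and normalizing by the reference condition's mean, so the
reference scores exactly 1 and the factor is invariant to additive
background.

# Nematic order

Per-window orientations come from the window's structure tensor
(Gaussian-derivative gradients at σ = window/4; the orientation of least
gradient variance is the ridge direction). Gradients within reach of the
border padding are dropped. A window is valid only if its gradient
energy clears 5% of the median window energy (background tiles) and its
tensor anisotropy (coherence) reaches 0.3 — windows mixing several
directions, e.g. at filament tips, carry no single orientation.

The local `q` aggregates the valid orientations in a 5×5 block of
adjacent windows. The textbook plug-in estimator — project each angle on
the director (principal axis of the mean nematic tensor) and average —
equals the resultant length `R` of the doubled angles. It is exactly 1
for aligned fields but cannot reach its isotropic limit of 0 on finite
kernels: with 25 samples its expectation under uniform orientations is
`≈ √π/2 / √25 ≈ 0.18`. The package's default is therefore the unbiased
pairwise U-statistic

  `q = mean_{i≠j} cos 2(θᵢ − θⱼ) = (n²R² − n) / (n(n−1))`,

which is exactly 1 for aligned kernels, has expectation exactly 0 under
isotropy (its slight negative floor is −1/(n−1)), and increases
monotonically with the generator's concentration κ. It estimates the
*square* of the population order parameter, so values between the limits
sit below the plug-in scale; both estimators are exposed and all limit
properties are tested. Windows with fewer than 3 valid kernel members
are undefined and excluded from `q_mean` (an opt-in mode counts them as
zero instead). The window-size sweep picks the smallest window in the
1–2 µm band where `|Δq_mean|` per step drops below 0.02 — a plateau
rule standing in for an unstated "optimal window" criterion — and is
overridable by a fixed size.

# Dynamics

Registration is rigid translation only (thermal drift), estimated
against the running registered reference by whole-frame FFT
cross-correlation with 3-point parabolic sub-pixel interpolation, and
applied by bilinear resampling. Correlation traces are plain Pearson
coefficients over pixels, frame-to-next-frame within a channel and
same-frame across channels.

PIV defaults: two passes with 64 → 32 px interrogation windows, 50%
overlap, displacement search limited to a third of the window,
normalized FFT cross-correlation, 3-point Gaussian sub-pixel peak fit,
and normalized-median-test validation (threshold 2, ε = 0.1). On pure
translations of textured noise the error stays below 0.2 px. The lag
defaults to 10 s.

The three-way contraction call makes the qualitative phenomenology
operational. From the lag-1 trace: dip depth (early maximum minus
minimum) and recovery (final minus minimum). From the velocity fields:
the high-speed weight (fraction of early speeds above the 90th
percentile of pooled late speeds) and the contracting-area fraction —
the share of the valid grid in measurably converging flow, i.e.
divergence below minus a floor estimated from the late (static) fields
and speed above a late-field floor. The divergence floor matters:
registration of a partially moving scene injects spatially uniform
apparent flow into the static half, which has near-zero divergence and
must not count as contraction. Thresholds (`d1 = 0.05`, `d2 = 0.03`,
`w0 = 0.2`, `f_hi = 0.5`, early/late = 3 lags) are configuration, with
the seeded synthetic suite as their calibration surface; on 60 held
series (20 per mode) the call is ≥ 90% correct.

# Interface physics

`ot_to_thickness` is the identity `d = ΔOT / n_prot` with the standard
protein-film refractive index 1.455 (6.0 nm → 4.1 nm, 4.7 nm → 3.2 nm at
two significant figures). Binding amplitudes are median-vs-median
differences between disjoint baseline and plateau windows.

The FRAP fitter uses the closed-form uniform-disc recovery
`f(t) = e^{−2τ/t}[I₀(2τ/t) + I₁(2τ/t)]`, `τ = r²/4D`, inside
`F(t) = 1 − depth·(1 − (1 − α)·f(t))`, fit by Levenberg–Marquardt
(minpack.lm) for depth, immobile fraction α and τ. This spot-averaged
model replaces a frequency-domain image-based method that needs full
image stacks; the observables (D and α) are the same, and the trace is
assumed pre-normalized and acquisition-bleaching-corrected. Flat
post-bleach traces (recovery below 3× the point noise) are flagged
unidentifiable: D is `NA` and the immobile fraction 1, rather than a
spurious fit. The fitter, the spectral generator and the test suite's
explicit-Euler oracle are three independent routes to the same physics;
round-trip bias in D stays within 10% over 1–10 µm²/s at 2% noise.

# Numerical choices and degenerate inputs

Convolutions use reflective padding; derivative kernels are sampled
Gaussians truncated at 4σ. Constant images: CLAHE returns a constant,
the Hessian response is zero, orientation fields are entirely invalid
(guarded against accumulated float residue), and `correlation_2d`
signals an error on zero variance rather than returning `NaN`. Empty
skeletons make the bundling factor an error, not a silent `NaN`. Thinning
resolves ties by the fixed two-subiteration order, so skeletons are
reproducible bit for bit. All randomness flows through explicit seeds;
identical seeds give identical geometry, images and traces.

Problem sizes in the tests — 128–512 px images, 60-series classification
suites, 10-seed density grids, 10⁶-angle isotropic checks — are chosen
so the whole suite validates every contract while remaining a
routine-length run on a laptop.

# Known limitations

* The tube filter reports a single-scale response; networks mixing very
  different filament widths would need a multi-scale extension.
* Node counts undercount shallow-angle crossings (see the merge-zone
  argument above); architecture comparisons across conditions are
  unaffected as long as the orientation statistics are comparable, but
  absolute intersection counts are lower bounds.
* The pairwise q estimator reports the squared order between its exact
  limits; comparisons across studies should use one estimator
  consistently.
* PIV assumes locally uniform displacement per window; strong
  deformation near aster cores decorrelates windows, which the median
  test then discards.
* The classifier's thresholds are calibrated on the synthetic suite;
  applying them to experimental series should start from a re-calibration
  on labeled examples.
* Filament length statistics and labeling density of real preparations
  are free parameters of the generator, not calibrated to any specific
  dataset.
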