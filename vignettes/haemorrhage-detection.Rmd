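---
title: "Detecting brain haemorrhage from raw EIT measurement frames: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting brain haemorrhage from raw EIT measurement frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electrical impedance tomography (EIT) injects small alternating currents
between pairs of surface electrodes and measures the resulting voltages on
other pairs. Haemorrhagic blood is markedly more conductive (~0.7 S/m at
50 kHz) than brain parenchyma (~0.3 S/m), so a bleed perturbs the measured
voltages. Image reconstruction from a single, static frame is notoriously
ill-posed; this package instead treats the complete measurement frame — all
208 injection/measurement combinations of a 16-electrode ring under a
"skip 2" protocol — as a feature vector and asks a binary classifier to
decide *bleed* (+1) versus *no bleed* (−1) directly.

`eitbleed` provides the whole simulation pipeline: parametric two-layer
head models, a complete-electrode-model (CEM) finite-element forward
solver, SNR-controlled measurement noise, SVM and neural-network
classifiers with ROC-based operating points, and seeded study runners that
quantify how noise, lesion location, lesion size, electrode placement and
head anatomy affect detection.

## Head geometry

The head is a two-layer nested model: an outer shell of aggregate tissues
(scalp, skull, CSF pooled; 0.1 S/m) around a brain compartment (0.3 S/m).
Both surfaces are ellipsoids:

* head semi-axes (0.095, 0.115, 0.120) m,
* brain semi-axes (0.070, 0.085, 0.075) m, centre raised 0.010 m,

which are realistic adult magnitudes. The coordinate convention is +Y
anterior ("north"), +X right ("east"), +Z superior; lengths are SI metres
internally and millilitres only at the lesion interface. Anatomical
variability is modelled by scaling either organ by ±5% along each axis
separately or all three together, giving nine variants per organ, 81
head–brain combinations and, with three electrode-ring heights (−2, 0,
+2 mm), 243 normal models; combining each with a 30 or 60 ml lesion at
four cardinal locations gives 1,944 lesion models.

Lesions are spheres of 5–60 ml placed in the plane of the electrode ring
on a cardinal axis, with their surface a configurable 2 mm inside the
brain surface. The clearance is unreported in comparable experimental
work, so it is a configuration parameter rather than an asserted constant;
2 mm keeps every volume in the 5–60 ml range placeable in every anatomy
variant. Placement errors (a sphere that would cross the brain centreline
or protrude through the brain surface) are reported with the violated
clearance.

## Forward model

The conduction problem is $\nabla\cdot(\sigma\nabla u) = 0$ with
complete-electrode-model boundary conditions: each electrode $l$ has a
contact impedance $z$ and an unknown potential $U_l$ with
$u + z\,\sigma\,\partial u/\partial n = U_l$ on the patch, a prescribed
total injected current, and zero current flux elsewhere. Discretised with
linear tetrahedra, the coupled $(u, U)$ system is symmetric positive
definite once one electrode is grounded; one sparse Cholesky factorisation
per conductivity map serves all 16 injections, and the symbolic analysis
is reused across models because the mesh topology never changes. A frame
stores voltage *magnitudes* $|U_{m+}-U_{m-}|$ in canonical
injection-major, measurement-minor order (skip-2 with measurements on
injecting electrodes excluded: 13 channels per injection, 208 in total).

Choices a user should know about:

* **Injected current** is 1 mA. Any value works by linearity; it is fixed
  so that frame tables are bit-comparable.
* **Contact impedance** defaults to 0.05 Ω·m², i.e. ~640 Ω for a 5 mm
  patch — typical of gelled EEG-style electrodes at 50 kHz. Much smaller
  values (say 1e-3 Ω·m², a 13 Ω contact) would make each patch an almost
  perfect conductor whose current density is singular at the patch edge,
  which linear elements resolve poorly; the default is both more physical
  and numerically benign.
* **Electrode patches** are not sharp discs. Each boundary facet receives
  a weight from a raised-cosine contact profile (full contact inside
  0.7 r, tapering to zero at 1.3 r, then normalised to the nominal area
  $\pi r^2$), modelling the gel fringe of a real electrode. A smooth
  profile also makes the effective patch independent of the facet layout,
  so refining the mesh does not move or reshape the electrodes.
* **Conductivity assignment** is by region membership of the element
  centroid (outer/brain/lesion → 0.1/0.3/0.7 S/m); the lesion is not
  meshed conformally. At the coarse preset a 60 ml sphere is captured to
  well within 10% of its volume.
* **Single real conductivity per tissue** at a nominal 50 kHz operating
  point; no complex impedance.

## Meshing

The mesher is structured: a latitude–longitude–radius lattice on the unit
ball, scaled componentwise onto the head ellipsoid. The azimuthal grid is
aligned with the 16 electrode centres, the latitude grid is refined in a
band around the electrode-ring latitude, and radial layers grade towards
the surface. Lattice cells are split into tetrahedra with the Kuhn
convention (conforming across cells and across the azimuthal wrap; polar
caps use prisms split compatibly). Because every head variant only scales
node coordinates, normal and lesioned frames from the same anatomy differ
through the conductivity map alone, and anatomy variants share one mesh
topology — discretisation error largely cancels in the *differences* that
carry the classification signal.

Presets: `coarse` (~61k elements, ~0.5 s per factorisation) is the study
workhorse; `medium` and `fine` are nested midpoint refinements (~246k and
~493k elements) used for convergence checks. On the homogeneous model,
coarse and fine agree to 1.4% on the mean channel; a known limitation is
the set of "interleaved" channels whose measurement pair straddles the
injection pair: their values are ~5× smaller than typical through partial
cancellation, which amplifies a ~0.3%-of-scale absolute field error into
up to ~4% relative disagreement, and this does not fall below ~2–3% at any
desk-scale resolution with linear elements. Quadratic elements would fix
this at roughly an order of magnitude more compute per solve.

## Measurement noise and SNR

Noise is independent Gaussian per channel with standard deviation
proportional to the channel's noiseless magnitude,
$\mathrm{sd}_c = |v_c|\,10^{-\mathrm{SNR}/20}$, and the noisy frame is
re-clamped to magnitudes by absolute value (at 20 dB and above the clamp
is essentially never active, since a sign flip would be a 10σ event).
Under this rule the *frame-level* expected power ratio
$20\log_{10}(\mathrm{rms}(v)/\mathrm{rms}(n))$ equals the nominal SNR, and
the frame-repetition estimator used for hardware characterisation — per
channel $20\log_{10}(|\bar v_c|/s_c)$, averaged over channels — recovers
the injected level to well within 1 dB. A per-frame normalisation (equal
absolute noise on every channel) would satisfy the first property but not
the second whenever channels span decades, which they do; that asymmetry
is why the per-channel convention was adopted.

## Classifiers and operating points

Linear-kernel and RBF-kernel SVMs are fitted with libsvm (via e1071) on
the raw 208-channel frames (volts; an optional z-scoring switch exists).
The box constraint, and for the RBF kernel the kernel scale, are searched
log-uniformly in $10^{-3}..10^{3}$ by a small Gaussian-process Bayesian
optimiser (Latin-hypercube initial design, expected-improvement
acquisition, default budget 30 evaluations) minimising 10-fold
cross-validated misclassification. Posterior probabilities are calibrated
on cross-validated decision scores: overlapping classes get a Platt
sigmoid; perfectly separated classes get the degenerate limit of that
fit — a step map equal to 0 below the normal scores, 1 above the bleed
scores and exactly 0.5 inside the separation gap. The 0.5 plateau matters
scientifically: a test case unlike anything in training (a lesion at an
unseen location, or smaller than any trained size) tends to fall between
the two training clusters, becomes a 50/50 tie, and the two operating
points then disagree about it by design — the default tie rule calls it
normal, the adjusted tie rule calls it a bleed. That single mechanism
produces the characteristic rescue of unseen-location and unseen-size
lesions at the adjusted point. The training ROC/AUC is computed from the
decision scores (calibration is rank-equivalent but its step branch
introduces ties).

Two operating points act on the posterior probability of the *normal*
class, $q = P(-1\,|\,x)$:

* **default**: classify normal when $q \ge 0.5$ — a 50/50 case is called
  normal;
* **adjusted**: raise the threshold to the first training-ROC point with
  true-positive rate 1.0 (in closed form,
  $\tau = \max(0.5, \max_i q_i)$ over training bleeds) and flip the tie
  rule, so a case with $q$ exactly at the threshold is called a bleed.
  This maximises sensitivity at a quantified cost to specificity; raising
  the threshold is provably monotone (sensitivity non-decreasing,
  specificity non-increasing), which the test suite asserts on random
  score sets.

The neural network is a single hidden layer of ten logistic units trained
with `nnet` (quasi-Newton optimisation with weight decay 1e-3 — a
scaled-conjugate-gradient trainer is not available in R) on an internal
70/15/15 split; the 15% validation slice selects the stopping iteration
from {40, 80, 160}. For comparability the network is evaluated on the same
held-out folds as the SVMs rather than on its internal 15% test slice.

## Studies and scaled-down execution

Each runner reproduces one experiment protocol as a pure function of its
configuration and a master seed (per-purpose seed streams are derived by
hashing, so studies never share randomness; everything is
bit-reproducible). Default frame budgets follow the original protocols:
noise (train 250+125+125, test 100+50+50, at 80/60/40/20 dB), location
(test 120 normals + 20 frames from each of six off-north lesion models),
size (train 300+4×75, test 80+4×20, both directions), electrode (train
640, test 80+80 at ±2 mm), anatomy and the pooled overall study.

The pooled grid studies are scaled down by design: the full protocol
(139,968 training frames over 2,187 models) needs thousands of forward
solves, so the default pooled grid is the 3×3×3 sub-grid — head and brain
in {−5% XYZ, base, +5% XYZ} × three ring heights: 27 normal models plus
their 216 lesion variants — with 16/2 frames per normal/lesion model
(864 frames, classes exactly balanced and equal frames per model within
each class, mirroring the full design's balance invariants). The
classifier comparison keeps the ten-fold 90/10 scheme on this pooled set
(sorted frames, default operating point) with two desk-scale economies:
the hyper-parameter search (budget 8) runs once per classifier/SNR cell
on the first fold's training split and is reused across the ten folds, and
features are z-scored per fold — the $10^{-3}..10^{3}$ kernel-scale range
presumes order-one features, which raw volt-scale frames are not.

Anatomy-study defaults test the 3×3 XYZ anatomy sub-grid minus the
training anatomy; the full 80-anatomy grid is available by passing
`test_anatomies`. The runner also reports a diagnostic: the point-biserial
correlation between each test model's outer-to-brain volume ratio and the
predicted label, quantifying how anatomy confounds the classifier.

## What the generator does and does not emulate

The synthetic data reproduce the *structure* of the original study —
conductivity contrasts, model grids, frame budgets, SNR levels — on an
ellipsoidal surrogate of the head and brain surfaces. They do not emulate
realistic cortical folding, separate skull/CSF layers, electrode drift or
day-to-day contact variation, channel-correlated noise, or multi-frequency
effects. Consequences worth keeping in mind:

* Passing studies show the *pipeline logic* behaves as designed (sorting
  confers location invariance; the adjusted point trades specificity for
  sensitivity; anatomy variation defeats a single-anatomy classifier).
  They do not certify performance on real heads or hardware.
* The surrogate's lesion contrast is somewhat stronger relative to noise
  than in anatomically detailed models: at 20 dB SNR, where the original
  study reports chance-level accuracy, these simulations degrade but
  remain above chance (~0.63–0.84 accuracy depending on the study),
  because a linear classifier can pool a few-percent signal across 208
  channels each carrying 10% noise. The qualitative ordering across SNR
  levels (80 ≈ 60 ≫ 40 > 20 dB) is preserved.

## Numerical details and degenerate inputs

* Ties in `max_diff_channel` break to the lowest channel index.
* ROC curves collapse tied scores; the trapezoidal AUC equals the
  Mann–Whitney U statistic to 1e-9 (asserted against an independent
  oracle).
* The forward solver rejects non-positive or non-finite conductivities
  and mismatched conductivity vectors; SNR is undefined (an error) for an
  all-zero frame and for fewer than two frames in the estimator; constant
  channels are excluded from the SNR estimate and reported.
* `make_dataset` shuffles rows deterministically under its seed and keeps
  train/test disjoint by construction (distinct realisation draws).
* All helpers that consume randomness save and restore the caller's RNG
  state.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
every dataset from scratch at the seed given and recomputes the study
quantities end to end (noise study at 60 dB; location generalisation with
sorted frames at the adjusted point; size generalisation trained on 60 ml
and tested at 10 ml; training AUC trained on 5 ml; and the RBF/linear
comparison cells at 80/60/20 dB on the pooled scaled-down grid).
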