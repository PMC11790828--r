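---
title: "Bounding-box regression losses and detection blocks for cardiac MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding-box regression losses and detection blocks for cardiac MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isdiou)
```

Detecting cardiac pathology on MRI slices is a bounding-box problem with
unusually fuzzy target boundaries: the heart's size and shape vary strongly
across patients and pathologies (dilated ventricles, hypertrophic walls,
infarcted tissue), and surrounding organs clutter the field of view.  This
package implements, in plain R, the numeric building blocks of a detection
pipeline tuned for that setting — a bounding-box regression (BBR) loss, two
feature-processing blocks, the standard evaluation metrics, and a desk-scale
simulator — so that each component's mathematical behaviour can be studied,
tested and compared in isolation, without a GPU, a deep-learning framework,
or any dataset download.

## The iSD-IoU loss

For a predicted box $a = (x_c, y_c, w, h)$ and a ground-truth box
$b = (x_c^{gt}, y_c^{gt}, w^{gt}, h^{gt})$ (center/size parametrization,
pixel units, $y$ increasing downward), the loss is

$$L = \bigl(1 - \mathrm{IoU}^{in}\bigr) + \Delta + \Omega.$$

**Inner IoU.**  $\mathrm{IoU}^{in}$ is the IoU of *auxiliary* boxes sharing
the originals' centers with all sides scaled by a ratio $r \in [0.5, 1.5]$.
Shrunken auxiliary boxes ($r < 1$) sharpen the loss surface for high-overlap
pairs; enlarged ones ($r > 1$) widen the basin of attraction for low-overlap
pairs.  At $r = 1$ the inner IoU is exactly the plain IoU — the package
asserts this identity on $10^4$ random pairs.  Intersection extents are
clamped at zero before multiplying; without clamping, disjoint boxes would
produce a spurious positive product of two negative extents.

**Distance term.**  With $(w^c, h^c)$ the width/height of the minimum box
enclosing both inputs,

$$\Delta = k \sum_{t \in \{x,y\}} \bigl(1 - e^{-\rho_t}\bigr), \qquad
\rho_x = w_1 \Bigl(\tfrac{x_c - x_c^{gt}}{w^c}\Bigr)^2, \quad
\rho_y = h_1 \Bigl(\tfrac{y_c - y_c^{gt}}{h^c}\Bigr)^2,$$

where the weights $w_1 = 2(w^{gt})^s / ((w^{gt})^s + (h^{gt})^s)$ and
$h_1 = 2 - w_1$ tilt the penalty toward the ground-truth box's dominant
axis.  $\Delta \in [0, 2k]$ and is zero for concentric boxes.  The enclosing
*diagonal* $c$ is also computed and exposed (it is the normalizer of the
DIoU/CIoU penalties) but is not used by this loss, whose normalizers are
$w^c$ and $h^c$ per axis.

**Shape term.**

$$\Omega = \tfrac12 \sum_{t \in \{w,h\}} \bigl(1 - e^{-w_t}\bigr)^{\Theta},
\qquad
w_w = h_1 \tfrac{|w - w^{gt}|}{\max(w, w^{gt})}, \quad
w_h = w_1 \tfrac{|h - h^{gt}|}{\max(h, h^{gt})}.$$

Note the *crossed* weight pairing — the width mismatch is weighted by the
vertical weight $h_1$ and vice versa.  That pairing is implemented as the
default faithfully; because a direct pairing (w-with-$w_1$) is the
equally natural reading, `isd_config(shape_weight_pairing = "direct")`
keeps the alternative testable.  The two only differ for non-square ground
truths.

**Hyperparameters and defaults.**  `ratio = 1.0` (center of the admissible
range; reduces the inner IoU to IoU), `k = 0.5`, `theta = 4` (midpoint of
$[2,6]$), `s = 1.0`.  Only ranges, not values, are prescribed for these
parameters, so the package picks the range midpoints as defaults and
exposes every one of them in `isd_config()`, which enforces
$r \in [0.5, 1.5]$, $k \in (0, 1]$, $\Theta \in [2, 6]$, $s \ge 0$ and
rejects violations with a config error (exit code 3 at the command line).
The lower bound of $k$ is exclusive as printed ("between 0 and 1"); $k = 1$
is admitted for convenience.

Because every ingredient is a ratio of lengths (or a difference normalized
by one), the total loss is invariant under joint translation and joint
positive scaling of both boxes — a property test over $10^3$ random pairs
asserts this at $10^{-9}$.  The loss is *not* symmetric in its arguments:
the weights follow the ground truth.

## SPPMC: multi-channel spatial pyramid pooling

The receptive field of a stride-1 convolution/pooling stack grows as
$R_1 = k_1$, $R_n = R_{n-1} + (k_n - 1)\prod_{i<n} s_i$.  The SPPMC block
runs six parallel branches whose receptive fields ladder up evenly:

| branch   | layers                         | receptive field |
|----------|--------------------------------|-----------------|
| shortcut | 1×1                            | 1               |
| local    | 1×1 → 3×3 → 3×3                | 5               |
| pool 5   | 1×1 → 3×3 → 1×1 → maxpool 5    | 7               |
| pool 9   | … → maxpool 9                  | 11              |
| pool 13  | … → maxpool 13                 | 15              |
| pool 17  | … → maxpool 17                 | 19              |

The four pooling kernels form an arithmetic progression (common
difference 4), so the receptive fields do too — the design intent is a
*uniformly varying* receptive field that covers small lesions and whole-organ
context alike.  The exact wiring downstream of the branches is a design
choice of this package: the local and pooled outputs are concatenated on the
channel axis, fused by 1×1 → 3×3 convolutions, re-concatenated with the
shortcut, and projected back to the input channel count by a final 1×1
convolution, with SiLU after every convolution.  This is the minimal
CSP-style topology that realizes the stated receptive-field set
{1, 5, 7, 11, 15, 19}; `sppmc_params(init = "passthrough")` replaces every
convolution by an identity-like center-tap (linear activation) so tests can
verify the wiring — under it, each pooled branch output equals
`max_pool_same(x, k)` exactly.

Max pooling is stride-1 with symmetric half-window padding whose padded
positions never win (−∞ semantics); convolutions zero-pad.  Both therefore
preserve spatial shape, as the residual use of the block requires.

## UECA: joint channel and coordinate attention

The block runs two gating branches in parallel on an input
$X \in \mathbb{R}^{C \times H \times W}$:

- **SE branch** (channel): $z_c$ = global mean of channel $c$;
  $s_1 = \sigma(M_1\, \mathrm{ReLU}(M_2 z))$ with $M_2: C \to C/r_{se}$,
  $M_1: C/r_{se} \to C$.
- **CA branch** (coordinate): per-channel row means $z^h$ and column means
  $z^w$ are concatenated along the spatial axis, mixed by a shared 1×1
  reduction $F_1: C \to C/r_{ca}$ with ReLU, split back, and restored by
  $F_h, F_w$ into gates $g^h = \sigma(F_h v^h)$ ($C \times H$) and
  $g^w = \sigma(F_w v^w)$ ($C \times W$); $s_2 = g^h \otimes g^w$.

The combination is the attention-gated **sum**
$Y = X \odot s_1 + X \odot s_2$.  The source equations, read literally,
nest the input once more ($Y = X \odot (X \odot s_1 + X \odot s_2)$); that
reading lacks standard attention semantics (the output would scale
quadratically in $X$), so the sum is the default and
`ueca_forward(combine = "product")` keeps the literal form available.  The
dimension labels of the two SE mixing matrices are likewise stated
inconsistently with matrix–vector composition and are implemented in the
only composable order (squeeze then restore), matching the original
squeeze-excitation design.  The nonlinearity between mixings is ReLU as
stated (the coordinate-attention original uses h-swish).  Whether the
"weighted parallel" combination carries learnable scalar weights is not
specified; the package implements the unweighted sum.

Defaults $r_{se} = 16$ and $r_{ca} = 32$ follow the conventions of the
squeeze-excitation and coordinate-attention literature; both must divide
$C$ (enforced as a config error).  All gates are sigmoid outputs, hence
strictly inside $(0, 1)$, and under the sum combination
$|Y| \le 2\max|X|$.  Weights are inference-only: `ueca_params()` and
`sppmc_params()` draw deterministic seeded uniforms (or zeros /
pass-through identities for oracle tests); nothing in the package trains.

## Detection metrics

Matching is greedy within each (image, class): detections in descending
score order claim the unmatched ground-truth box of highest IoU at or above
the threshold, ties to the lowest ground-truth index.  Greedy matching is
prefix-consistent (a detection's fate never depends on lower-scored ones),
which makes the single-pass precision–recall construction equivalent to
re-matching at every score cut — a property the tests exercise against an
exhaustive threshold-enumeration oracle at $10^{-9}$.

AP integrates the precision envelope at the 101 recalls
$0.00, 0.01, \dots, 1.00$ (the COCO convention, chosen because the
surrounding detector ecosystem uses it; the metric names alone do not pin
down an interpolation).  mAP0.5 averages per-class AP at IoU 0.5;
mAP0.5-0.95 additionally averages over thresholds $0.5, 0.55, \dots, 0.95$.
Conventions for degenerate counts: $P$, $R$, $F1$ are 0 when their
denominators vanish; AP for a class with no ground truth is *undefined*
(`NA`, excluded from means), not 0.  The evaluation confidence cut defaults
to 0.55, the operating point of the detector setting this package mirrors;
whether F1 should instead be reported at the F1-optimal cut is left to the
caller via `score_threshold`.

Ties in scores deserve a note: two detections with exactly equal scores
cannot be separated by any threshold, so threshold-sweep and per-detection
PR constructions legitimately differ there.  The package orders tied
detections by a content-based key (so metrics are permutation-invariant),
and the oracle comparison is performed on tie-free (continuous) scores,
where the two constructions provably coincide.

## The BBR simulator

`convergence_experiment()` compares losses by descending a population of
anchor boxes onto targets: 1×1 ground-truth boxes on a 7×7 grid (spacing 3;
all losses are translation/scale invariant, so units are arbitrary), nine
anchors per target on a ring of radius 1.5 — aspect ratios {0.5, 1, 2} ×
scales {0.5, 1, 2}, ring angles seeded-uniform — descended for 200 steps.
This layout follows the simulation designs customary in the BBR-loss
literature; no specific protocol is prescribed for it, and the choice was
fixed once before any comparative runs.

Descent operates on $(c_x, c_y, \log w, \log h)$ — the log parametrization
keeps sizes positive without projection — with central finite-difference
gradients (half-width $10^{-6}$), so no per-loss gradient code exists.
Gradient components below $10^{-8}$ are zeroed: the IoU-family losses have
kinked (V-shaped) minima, and float-level finite-difference noise would
otherwise push an exactly converged anchor into a small limit cycle.  The
step size 0.05 was chosen so plain fixed-step descent is stable for all
four losses at the unit target scale.  Curves are compared *normalized*
(divided by their step-1 mean) because absolute scales differ across loss
families; the normalized curves of CIoU and iSD-IoU cross late in the
descent, and the comparison is read at the final step.  Two behaviours are
asserted on the default seed: the iSD-IoU normalized final loss ends below
CIoU's, and — structurally, for any seed — anchors that start disjoint from
their target, where plain IoU loss has exactly zero gradient, reach high
final IoU under iSD-IoU (≈0.91) and stay at 0 under the IoU loss.

## Phantom fixtures

`generate_phantoms()` emits seeded grayscale images (dark background,
additive Gaussian noise, 1–3 bright ellipses) whose tight boxes become
ground-truth records labeled from the five-class cardiac vocabulary (NOR,
MINF, HCM, DCM, ARV); class conditions the ellipse geometry — size,
eccentricity and wall thickness (hollow cores for the hypertrophic and
dilated classes) — so classes are statistically distinguishable.  Ellipses
whose box would cross the border are resampled, never clipped.
`perturb_detections()` turns ground truth into scored detections with
center/size jitter, drops and spurious boxes; scores decay with realized
jitter so the zero-noise round trip is a perfect detector (mAP0.5 = 1).

These phantoms are an acknowledged surrogate: they contain no MRI physics,
no anatomy, no inter-slice structure, and no annotation noise.  Tests
passing on them demonstrate the *metrics'* and *losses'* correctness, not
detector performance on real cardiac MRI; the headline mAP figures of
trained detectors on real data are outside what this package can or tries
to reproduce.

## Problem sizes and numerical choices

The shipped tests run the simulator at its default size (441 anchors × 200
steps × 4 losses, about ten seconds) and smaller; feature-tensor tests use
channels ≤ 8 and spatial extents ≤ 8, where the pure-R convolutions are
instant and every result is checkable against a brute-force double loop.
Tolerances: exact (`identical`) agreement for pooling vs. its oracle;
$10^{-12}$ for algebraic identities; $10^{-9}$ for invariance and AP-oracle
properties, which accumulate float error over sums.

## Limitations

- Forward semantics only: no gradients through the blocks, no training.
- The SPPMC fusion wiring realizes the stated receptive-field set but other
  wirings could too; conclusions about the block concern this topology.
- The simulator measures loss-surface geometry at desk scale, not detector
  training dynamics; its final-step CIoU/iSD comparison is seed-sensitive
  because both losses converge well within 200 steps.
- Phantoms are statistical stand-ins, not medical images.
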