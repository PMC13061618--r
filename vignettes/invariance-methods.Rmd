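---
title: "Characterizing receptive-field invariance in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing receptive-field invariance in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(veiscope)
```

## The problem

A visual neuron's *most exciting input* (MEI) — the single image that
maximally drives a predictive model of the neuron — summarizes what the cell
prefers, but not what it *tolerates*. Many cortical neurons respond equally
well to a whole manifold of images. `veiscope` characterizes that manifold
three ways:

1. **Varied exciting inputs (VEIs)** — a set of images that all keep the
   response above a floor (85% of the MEI response) while being as mutually
   dissimilar as possible;
2. a **diversity index** that places each neuron's VEI dispersion on a
   calibrated scale anchored by the two classical extremes, the phase-locked
   *simple cell* (index 0) and the phase-invariant energy-model *complex
   cell* (index 1);
3. a **bipartite receptive-field model** that parameterizes the VEIs as a
   *fixed* subfield (content taken directly from the MEI) plus a *variable*
   subfield (random crops of an optimized texture), and summarizes the
   neuron's partial shift invariance by the **bipartite invariance index
   (BII)**.

Everything operates on any differentiable image-to-rate predictor through a
small contract (`model_neuron`): a deterministic nonnegative response and
its pixel gradient. Analytic Gabor cells supply ground truth; an ensemble of
linear–nonlinear Poisson encoders (`fit_digital_twin`) stands in for a
fitted predictive model of recorded neurons; any user model can be wrapped
the same way.

## Models and conventions

**Grid.** Images are `36 x 64` matrices (rows x columns, row 1 at top), 2
degrees of visual angle per pixel by default. All synthesized images are
standardized to mean 0 and RMS contrast 0.25, then clipped.

**Gabor cells.** The filter is the Gaussian-windowed cosine grating

\[
  I(x, y) = \exp\!\Big(-\frac{(x-\mu_x)^2 + (y-\mu_y)^2}{2\sigma^2}\Big)
            \cos\!\Big(\frac{2\pi(x\cos\theta + y\sin\theta)}{\lambda} + \psi\Big),
\]

with the envelope s.d. \(\sigma\) drawn uniformly from \([4.4, 10.9]\)
degrees for population studies, orientation and phase uniform, and the
wavelength drawn uniformly from \([\sigma, 2\sigma]\) so that the period
never exceeds twice the envelope s.d. A *simple cell* responds with
\(\max(0, \langle I, G\rangle)\); a *complex cell* with
\(\sqrt{a^2 + b^2}\) where \(a, b\) are inner products with a quadrature
pair (\(\psi\) and \(\psi + \pi/2\)). Poisson spiking is emulated by
`sample_poisson_responses` with a default gain of 10.

**Digital twins.** `fit_digital_twin` minimizes the Poisson loss
\(\tfrac1m\sum_i (\hat r_i - r_i \log \hat r_i)\) with the output
nonlinearity \(\mathrm{ELU}(z) + 1\) (always positive, so the log is safe).
Members differ only in their random initialization; the ensemble predicts
the member mean. The encoder is linear–nonlinear rather than convolutional:
the package's ground truth rests on the analytic cells, and a single
regularized filter map is the transparent choice at this scale. The weight
map carries the usual receptive-field smoothness prior (a squared discrete
Laplacian penalty, default `1e-3`) plus a weak ridge; fitting is full-batch
L-BFGS, which is deterministic given the seed. On 2,000 naturalistic
images this recovers a noiseless simple cell at held-out correlation
above 0.9. Twin quality is reported as CC\(_{abs}\) (correlation with
repeat-averaged responses), CC\(_{max}\) (the reliability ceiling estimated
from repeat variance), and their ratio CC\(_{norm}\).

## Stimulus synthesis

**MEI.** Gradient ascent from white noise: 1,000 steps, learning rate 1.0,
the gradient blurred with a \(\sigma = 1\) pixel Gaussian, and the image
re-standardized (projected) after every step. The receptive-field mask is
computed from the MEI by pixel z-scoring, thresholding \(|z| > 1.5\)
(both polarities contribute to a receptive field), binary closing, keeping
the largest connected component, filling its convex hull, and smoothing with
\(\sigma = 1.5\). If the initial gradient vanishes — a rectified cell below
threshold — the starting noise is redrawn.

**VEIs.** Twenty images initialized as the MEI plus Gaussian noise
(s.d. 0.05 in standardized units) minimize

\[
  L = \frac1n \sum_i \max\Big(c - \frac{r_i}{r_{\mathrm{MEI}}},\, 0\Big)
      \;-\; \lambda\, \min_{i,j}\, d(I_i, I_j), \qquad c = 0.85,
\]

where \(d\) is the Euclidean distance weighted by the MEI mask (the
weighted-mask reading; a binary-support variant is a one-line change in
`masked_distance`). The minimum (not the mean) pairwise distance prevents
the set from splitting into clusters. Optimization runs 3,000 steps with
learning rate 1,000 decayed to 100 for the final third, blurred gradients
and per-step standardization. One subtlety matters in practice: a strictly
one-sided hinge equilibrates a hair *below* the floor under the persistent
diversity push (the pull only engages after the floor is crossed), which
would disqualify every diversity-achieving \(\lambda\). The activation term
therefore engages within a small safety margin (`floor_margin`, default
0.02) *above* the floor during optimization; the selection rule itself
still requires exactly \(c\). The diversity weight \(\lambda\) is swept over
a log-spaced grid on \([10^{-4}, 5\times 10^{-2}]\) and the returned set is
the one with the *largest* \(\lambda\) whose minimum activation ratio still
meets the floor; the sweep therefore runs from the largest \(\lambda\)
downward and stops at the first qualifying set (a full sweep mode exists
for inspecting the whole trade-off). If no \(\lambda\) qualifies the
smallest-\(\lambda\) set is returned with `violated = TRUE`.

**Controls.** `synthesize_distance_controls` produces images whose masked
distance to the MEI matches the VEIs' minimum distance (`d_target`) while
maximizing mutual dissimilarity; a final radial projection guarantees no
control exceeds the budget. `sample_natural_controls` filters a crop pool to
distances within 80–100% of `d_target`. A caution for ideal-cell work: for
an analytic energy-model cell the response loss at distance `d_target` in a
*random* direction numerically matches the 85% VEI floor, so control and
VEI activations are nearly equal in silico; the separation between them is
a property of real neurons (and their fitted models), not of the analytic
cells.

**Representational-space variant.** `neuronal_space_distance` measures
stimulus dissimilarity as the negative Pearson correlation between
model-predicted population response vectors (RF centers aligned to the
target neuron by integer-pixel translation), and
`build_latent_basis`/`representational_similarity` implement the
PCA-latent cosine similarity (components retained to 95% variance).

## The diversity index

For ideal cells the VEIs can be found exactly: `exhaustive_gabor_veis`
enumerates a dense Gabor bank centered on the cell's own parameters (16
orientations x 16 phases x 5 wavelengths x 5 positions, all scaled by the
cell's \(\sigma\)), keeps candidates above 85% of the maximal response, and
greedily selects 20 maximizing the minimum pairwise masked distance,
starting from the most activating candidate. A simple cell admits only a
tight phase/position jitter; a complex cell admits the entire phase circle.
`calibrate_diversity_bounds` runs this over 60 simple and 60 complex cells
and takes the population medians as \(d_{\mathrm{lower}}\) and
\(d_{\mathrm{upper}}\); the diversity index of any neuron is then

\[ D = \frac{d - d_{\mathrm{lower}}}{d_{\mathrm{upper}} - d_{\mathrm{lower}}}. \]

By construction the calibration populations anchor at 0 and 1, and because
all images share one fixed mean/RMS, the per-cell distances are essentially
parameter-independent (coefficient of variation of a few percent).

One property of the analytic cells deserves emphasis: a *free-form* (Eq.-4
style) VEI set for an ideal rectified-linear simple cell is **not** tight.
The model is genuinely invariant to any within-mask content orthogonal to
its filter, and the synthesis exploits that freedom, so free-form simple-cell
VEIs land mid-scale on the diversity axis. The collapse of simple cells onto
\(d_{\mathrm{lower}}\) is a statement about the Gabor-constrained search that
defines the calibration — which is how the package tests it. Fitted models
of real neurons do not share this pathology because their nonlinearities
suppress off-manifold content.

## The bipartite model and BII

From the VEI set, the pixel-wise variance map (within the MEI-mask support,
binarized at 0.3) defines a series of variable-subfield masks: pixels are
added in descending variance order until 20–60% of the total variance is
enclosed (steps of 0.05 by default); the fixed subfield is the in-mask
complement, and both inherit the MEI mask's weights so
\(m_V + m_F = m_{\mathrm{MEI}}\).

For each series member a texture canvas \(T\) (the variable subfield's
bounding box dilated by 50% per side) is optimized so that the *mean*
response to composites \(m_V\,\mathrm{crop}(T) + m_F\,\mathrm{MEI}\) over
random crop offsets is maximal (16 crops per step, 1,000 steps, blurred
gradients). Unlike the image synthesis — where the paper-style projected
(post-gradient) standardization is used — the canvas gradient is
backpropagated *through* the per-crop standardization and clipping: the
pre-standardization response is linear in crop amplitude, so a projected
gradient would grow the canvas without bound and crush the fixed subfield.
With the exact chain rule the crop amplitude self-balances against the MEI
content; the canvas is initialized at the RMS contrast of the MEI content
it replaces.

Each member's 20 rendered composites give a mean activation ratio and mean
pairwise masked distance; normalizing both by their maxima over the series,
the member maximizing the harmonic mean \(H = 2\bar r \bar d/(\bar r + \bar
d)\) defines the partial-texture VEIs. Setting \(m_V = m_{\mathrm{MEI}}\)
gives the full-texture model (global shift invariance).

The **BII** is the area under a quadratic smoothing spline of the mean
activation *ratio* versus the variable subfield's *relative area*
(binarized at 0.3), evaluated on 101 uniform points of \([0, 1]\) with
activations clamped to \([0, 1]\) and integrated by the trapezoid rule. Two
anchors are appended before fitting: size 0 (the pure MEI, ratio 1 by
definition) and size 1 (the full-texture model). Ratios are used rather
than raw activations, and the spline is an `mgcv` P-spline of degree 2 with
GCV smoothing, a deliberately compact basis (5 functions) that keeps the
fit identified when the series' sizes cluster at small values — as they do
when the VEI variance map follows a Gaussian envelope — and a *first-order*
difference penalty: shrinking toward local constancy means no slope is
extrapolated from the sampled small-size branch into the unsampled middle
of the size axis, where a curvature penalty produces severe undershoot. A
caveat follows from the same geometry: for a neuron whose activation would
stay high across the unsampled middle but collapse at full texture (the
planted bipartite ground truth is exactly such a cell), the spline fills
the gap from the two ends and the BII under-estimates the true area; the
index is comparative, not absolute.

Two control parameterizations probe the necessity of the spatial division:
`two_variable_veis` treats both subfields as shift-invariant textures, and
`no_spatial_division_veis` mixes a full-field texture with the whole MEI at
weights \((1-c, c)\), reporting spline-interpolated
activation-at-matched-diversity and diversity-at-matched-activation against
the nonparametric VEIs. `subfield_manipulation` masks out or swaps subfield
content (swaps are moment-matched within the substituted region; masking
keeps the complementary subfield bit-identical and restricts edge smoothing
to the outside). `subfield_median_frequency` compares the two subfields
indirectly: the partial-texture VEIs versus the same images with the fixed
subfield replaced by texture crops, each set summarized by the median of
its 10-bin radial power spectrum.

## Segmentation alignment and connectomics

`bipartite_mask` ternarizes the subfield division (+1 variable, −1 fixed)
and `matching_score` compares it with an object/background segmentation:
the raw statistic \(\sum m_{\mathrm{bip}} m_{\mathrm{seg}} / \sum
|m_{\mathrm{bip}}|\) spans \([-1, 1]\) and is rescaled to \([0, 1]\) so that
1 means the variable subfield coincides with the object and 0 the exact
reversal (the raw value is kept as an attribute). `boundary_crop_filter`
requires at least 20% of each class inside the RF (strictly, per the
robustness variants also 10%/30%); `compose_grating_scene` builds
object/background grating scenes (high band 5.83–15.55, low band
15.55–58.3 degrees/cycle, boundary blurred at \(\sigma = 1.5\));
`screen_crops` ranks mask-standardized crops by model response.

The connectomics module operates on pair tables (presynaptic neuron,
postsynaptic neuron, connected flag, synapse count, axon–dendrite co-travel
distance, functional metrics). `adjust_pairwise_metric` removes
per-presynaptic offsets and restores the regional mean (pairs weighted
equally); `adjust_synapse_counts` normalizes by per-presynaptic synapse
conversion rates while conserving totals; `conversion_rate_by_bin` bins
pairs by a metric (equal-count octiles among connected pairs by default),
keeps bins with more than ten connected pairs and at least 2.5% of all
connected pairs, and attaches bootstrap standard deviations;
`bootstrap_mean_difference` implements the weighted two-sided bootstrap
with p floored at 1/resamples; `fit_exponential_decay` fits
\(a e^{-bx} + c\) by Levenberg–Marquardt with \(R^2\) about the mean.
Significance of conversion-rate trends uses a Poisson regression with
presynaptic fixed effects and log co-travel offset — a deliberate
simplification of a mixed model, adequate for tens of presynaptic neurons.

## Synthetic fixtures

All tests run without external data. `naturalistic_images` draws
\(1/f^\gamma\) noise (random phases, standardized); it emulates the spatial
power spectrum of natural scenes but none of their phase structure, so
passing tests say nothing about object-level statistics.
`blob_segmentation_masks` thresholds smoothed Gaussian fields into single
4-connected objects occupying 20–80% of the frame.
`planted_bipartite_neuron` provides a ground-truth bipartite cell,
\(h(\langle m_F I, F\rangle)\,(1 + E_V(I))\, g(I)\): a Lorentzian tuning
curve \(h\) peaked at the calibrated drive of the fixed low-frequency
template (two-sided, so neither synthesis nor the diversity push can drift
the fixed-pattern match, with heavy tails that keep gradients alive far
from the peak); a texture term \(E_V\) that pools quadrature-pair carrier
energy over six local tiles of the variable subfield (every carrier shift
is a phase change, so the invariance is a continuous manifold, and
re-phasing part of the subfield leaves other tiles' drives untouched); and
a divisive-normalization factor \(g\), the pattern-aligned fraction of
within-RF energy, which makes off-pattern content suppressive rather than
merely ignored. Each ingredient exists for a reason discovered the hard
way: a neuron that is merely *insensitive* to off-pattern content lets
gradient-based diversity fill its VEIs with response-neutral junk; discrete
shift templates are separated by response barriers no gradient can cross;
and a global (untiled) energy detector phase-cancels sub-region
replacements. `synthesize_mei` offers best-of-`n_starts` restarts because
the tuned landscape has local optima. `synthetic_connectome` plants the three effects the
connectomics statistics are meant to detect — like-to-like connectivity
(similarity coefficient 2 on the connection log-odds), a diversity
hierarchy (+0.15 for connected postsynaptic partners), and an exponential
decay of the conversion rate with presynaptic diversity (rate 1.5) — with
the intercept calibrated so the expected connected-pair count matches the
target (700 of 10,000 by default, the scale of a modern electron-microscopy
functional-connectomics sample). Effect sizes were chosen once to be
clearly detectable at that sample size.

## Numerical choices and problem sizes

* Clip bounds default to \(\pm 2\) (8 RMS units). This clips well under 1%
  of pixels on standardized naturalistic images and leaves Gabor-like
  optima essentially unsaturated; a tighter bound turns analytic-cell MEIs
  into saturated bang-bang images, which distorts both MEI recovery and the
  VEI variance map. (A display with a genuinely narrow dynamic range can be
  emulated by passing tighter bounds.)
* Gradient blurring uses a truncated (3\(\sigma\)), edge-renormalized
  separable Gaussian.
* Masked distances weight pixel differences by the mask *values*; switch to
  a binarized mask by thresholding the mask first.
* \(\lambda\) selection ties cannot occur under floating point; the
  descending sweep stops at the first qualifying \(\lambda\), which is
  exactly the largest qualifying one.
* Degenerate inputs fail loudly: zero-variance images cannot be
  standardized, empty suprathreshold sets raise "no RF found", an empty
  binarized MEI mask rejects ternarization, and zero-weight bootstraps are
  errors.
* Population studies run at a documented reduced scale chosen for
  single-CPU turnaround: 20 cells per class, an 800-step VEI schedule with
  a three-point \(\lambda\) grid, variance fractions 0.2–0.6 in steps of
  0.1, and 500-step texture optimizations with 12 crops per step
  (`bii_population` defaults). Single-neuron analyses use the full
  schedules given above. The calibration populations use the full 60 cells
  per class.

## Known limitations

* The digital twin is linear–nonlinear; neurons with strong nonlinear
  spatial interactions need a user-supplied predictor (any differentiable
  model satisfying the `model_neuron` contract works).
* Analytic rectified-linear simple cells are invariant to filter-orthogonal
  content, so their free-form VEI diversity exceeds the Gabor-calibrated
  lower bound by construction (see above); diversity indices of free-form
  sets are meaningful relative to the calibration only for models without
  that degeneracy.
* The BII spline interpolates between small sampled subfield sizes and the
  size-1 anchor; with strongly non-monotone activation profiles in the
  unsampled range the AUC inherits interpolation error.
* RF-center alignment uses integer-pixel translation; sub-pixel alignment
  is out of scope.
* Behavioral modulators, pupil-position shifters, and video (dynamic)
  models are out of scope.
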