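# veiscope

In-silico characterization of visual receptive-field invariance: synthesis
of most exciting inputs (MEIs) and varied exciting inputs (VEIs) against
differentiable neuron models, a calibrated diversity index, bipartite
(fixed + shift-invariant) receptive-field parameterizations with a
bipartite invariance index (BII), segmentation-boundary alignment scoring,
and functional-connectomics statistics — all runnable offline with built-in
synthetic fixtures.

## Who this is for

Visual neuroscientists who fit predictive models ("digital twins") to
neuronal recordings and want to ask, beyond the single optimal stimulus,
*which manifold of images* drives a neuron: how diverse that manifold is,
whether it decomposes into a fixed spatial pattern plus a shift-tolerant
texture, how that division aligns with object boundaries in scenes, and
whether it relates to synaptic connectivity.

## The core quantities

With a differentiable response model \(r(I)\):

* **MEI** — gradient ascent on \(r\) from white noise, with blurred
  gradients and per-step standardization of the image to mean 0 / RMS
  contrast 0.25.
* **VEIs** — 20 images minimizing
  `L = mean_i max(c − r_i/r_MEI, 0) − λ · min_{i,j} d(I_i, I_j)`, with
  activation floor `c = 0.85` and `d` the Euclidean distance weighted by
  the MEI mask; the set with the largest λ still meeting the floor is kept.
* **Diversity index** — `D = (d − d_lower)/(d_upper − d_lower)`, the mean
  pairwise VEI distance normalized between noiseless simple-cell
  (`D = 0`) and energy-model complex-cell (`D = 1`) populations whose VEIs
  are found by exhaustive search over Gabor parameters.
* **BII** — VEIs are re-parameterized as `m_V · crop(T) + m_F · MEI`
  (variable-subfield crops of an optimized texture plus fixed MEI content)
  for a series of subfield sizes; the BII is the spline-fit area under the
  activation-versus-subfield-size curve on [0, 1]. Simulated simple cells
  score low, complex cells high.
* **Matching score** — alignment between the ternary bipartite mask and an
  object/background segmentation, scaled so 1 = variable subfield on the
  object, 0 = the exact reversal.
* **Connectomics statistics** — per-presynaptic corrections of pairwise
  metrics and synapse counts, binned synapse conversion-rate curves with
  bootstrap s.d., weighted bootstrap mean differences, and exponential
  decay fits, on plain pair tables (CSV).

Details, assumptions and numerical choices are in the methods vignette
(`vignettes/invariance-methods.Rmd`).

## Worked example

Synthesize the MEI and VEIs of an analytic energy-model complex cell and
fit the bipartite texture model (population-study scale):

```r
library(veiscope)

cell <- complex_cell(gabor_params(sigma = 6, theta = 0.7,
                                  wavelength = 10, phase = 1.2))
cfg  <- synthesis_config(seed = 7, vei_iters = 800,
                         lambda_grid = c(1e-4, 2e-3, 5e-2))

mei  <- synthesize_mei(cell, cfg)
mei
#> <mei> complex cell (sigma=6.00, lambda=10.00, theta=0.70)
#>   activation: 42.28  mask area: 131 px (>0.3)

veis <- synthesize_veis(cell, mei, cfg)
veis
#> <vei_set> 20 images, lambda = 0.002
#>   min activation ratio: 0.867
#>   pairwise masked distance: min 7.98 mean 9.723

fit  <- fit_bipartite(cell, mei, veis, cfg,
                      fractions = seq(0.2, 0.6, 0.1), iters = 500, K = 12)
fit
#> <bipartite_fit> complex cell (sigma=6.00, lambda=10.00, theta=0.70)
#>   BII: 0.751
#>   selected member: 6 of 6 (size 1.00, activation ratio 0.97)
```

Reading the output: every VEI keeps at least 86.7% of the MEI response
while the set spreads widely over the receptive field (the diversity weight
lambda = 0.002 is the largest on the grid that preserves the 85% floor);
the texture model keeps a 0.97 activation ratio even when the *entire*
receptive field is treated as shift-invariant (the selected size-1.00
member), and the activation-vs-size curve integrates to a BII of 0.751 —
the signature of a shift-invariant, complex-like cell. A rectified-linear
simple cell run through the same pipeline scores near 0.55 and loses over
half of its response at full texture.

`plot(mei)` shows the image; `plot(fit)` draws the activation-versus-size
series with its spline and BII.

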