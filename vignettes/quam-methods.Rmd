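---
title: "Quantitative automated microscopy of heterogeneous neuron cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative automated microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(quamr)
```

## The problem

Dissociated dorsal-root-ganglion (DRG) cultures are extremely heterogeneous:
soma diameters span roughly 14-32 um, marker expression is continuous rather
than bimodal-by-eye, and the per-cell baseline of a phospho-signal such as
pErk1/2 varies with a coefficient of variation near 180%. Calling cells
"marker-positive" or "responding" by eye is therefore poorly defined, and
culture-mean readouts hide subgroup-restricted responses. `quamr` implements
a quantitative automated microscopy workflow on single-cell
immunofluorescence images: rule-based neuron identification, exposure- and
area-normalized intensity quantification, histogram-intersection subgroup
classification, and a virtual-well analysis that converts measured cell
numbers into sensitivity bounds.

Because no public image sets exist for this kind of culture, the package
ships a ground-truthed synthetic culture generator. Every claim the test
suite makes is checked against that generator's truth tables, not against
wet-lab data.

## The synthetic culture model

`generate_population()` draws per-cell quantities from the following model;
all defaults are the conditions the workflow is designed for.

* **Baseline phospho-intensity**: lognormal with mean 1 (control-mean scale)
  and CV 1.80. Only the mean scale and the 180% SD of the real cultures are
  known; the lognormal is the standard non-negative heavy-tailed choice and
  reproduces the ~100-fold spread seen in single-cell scatter plots.
  Parameterization is by mean and CV (`meanlog = log(m) - sdlog^2/2`,
  `sdlog^2 = log(1 + cv^2)`).
* **Stimulus response**: multiplicative. Responders (50% of cells by
  default) multiply their baseline by `responder_fold_change` (default 10)
  times a lognormal noise term with CV 0.20; non-responders keep their
  baseline exactly. A multiplicative model keeps intensities non-negative
  and matches fold-change reporting. The noise CV is a generator choice
  (the parametric form of the stimulated distribution is not known); 0.20
  is small against the 1.80 baseline CV and does not drive any result.
* **IB4 channel**: two-component lognormal mixture, 71% positive by
  default. The low component (mean 1, CV 0.6) models unspecific lectin
  binding and is exactly the distribution a blocked control is drawn from;
  the high component (mean 15, CV 1.0) is broad, matching a "shallow but
  widespread" specific-binding tail. Component means are generator choices
  set for clear but overlapping bimodality.
* **Geometry**: IB4(+) somata draw diameters uniformly from 22-32 um,
  IB4(-) from 14-24 um; shapes are mildly elliptic (aspect 1.0-1.3).
* **Nuisance structure**: 16% of neurons sit in touching pairs, 3% are cut
  by the field border; glia (dim, irregular, 10-25% contrast) and debris
  (bright specks under 150 um2) are placed per field at configurable
  densities.

`render_fields()` rasterizes a laid-out population into 1280 x 1024 px,
12-bit camera images at 0.645 um/px (a typical 10x configuration; the pixel
size is configurable because it is hardware-specific). Somata get a
hemispheric (chord-depth) radial profile — a flat disc would be an intensity
plateau, which both looks wrong and defeats intensity-maxima cluster
detection — and the pixel weights are rescaled so the integrated
background-excess of each object equals `intensity x mask area x exposure x
gain` exactly before noise, rounding and clipping. That makes render-truth
recovery exact for noise-free renders, which the tests exploit. Saturation
is hard clipping at `2^bit_depth - 1`. No point-spread-function optics,
photobleaching or 3-D structure is simulated: the generator validates the
measurement logic, not microscope physics, so passing tests say nothing
about e.g. out-of-focus light in real images.

## Neuron identification

`detect_objects()` thresholds the pan-neuronal marker channel at
`1 + contrast_min` times the global background (image median — objects are
sparse), labels connected components, and computes per object:

* **Area** from the pixel count; accepted range 150-1500 um2.
* **Aspect ratio** as longest/shortest caliper (Feret) diameter of the
  boundary convex hull, computed by rotating calipers — following the
  "ratio of longest to shortest diameter" reading, not fitted-ellipse axes.
  The shortest caliper is floored at one pixel so thin masks do not divide
  by zero. Threshold 2.
* **Concavity depth** as the maximum distance from the convex hull boundary
  to the object boundary, divided by the equivalent diameter. The published
  threshold 0.25 comes from proprietary software whose normalization is
  unpublished; dividing by the equivalent diameter makes the rule
  scale-free, which we consider the only defensible reading (an absolute
  pixel threshold would change meaning with magnification). A rasterized
  convex disc shows an apparent depth below ~1 px / diameter.
* **Contrast** as the median object pixel over the median of a 10-um-wide
  annulus around the object (other objects excluded; global fallback),
  minus one. Threshold 30%. The published rule names only "30%"; we read it
  as a local-background rule because widefield backgrounds drift.
* **Border contact**: any mask pixel in the first/last row or column
  (0-based coordinates in all emitted tables).
* **Cluster flag**, two prongs: (i) at least two regional intensity maxima
  (on a sigma = 2 px smoothed image; connected plateau pixels count as one
  maximum) whose centroids lie more than half the shortest caliper apart;
  (ii) merging with another above-minimum-size object after a one-pixel
  dilation. Clusters are rejected, not split: cells in contact behave
  differently and watershed splitting would quantify them anyway.

`filter_neurons()` records *every* failed rule per object, so rejection
statistics are interpretable, and accepts exactly the objects passing all
enabled rules. Detection is fully deterministic.

One measurement consequence worth knowing: the pixel threshold erodes the
dim rim of a soma, so segmentation masks of faint cells are up to ~10-15%
smaller than the true footprint and their normalized intensities biased
high by a similar amount. The same effect exists in any threshold-based
screening software. Tests that need exact recovery therefore measure with
ground-truth masks; tests of the segmentation path use tolerances that
include this bias.

## Quantification

`measure_cell()` integrates background-subtracted pixel values over the
mask and divides by area (um2) and exposure (s); negative integrals are
clamped at zero. Background subtraction reuses the object's local annulus
estimate. `select_exposure()` picks the longest candidate exposure
(default 0.96, 0.48, 0.24 s, maximum 0.96 s) whose saturated-pixel count
stays within budget. The published budget, 1000 saturated pixels per
100 um2, cannot be exceeded at 0.645 um/px where 100 um2 holds ~240 pixels;
we keep it as the configurable default and provide a per-field absolute
mode, without asserting which the original software meant. The pipeline
segments once on the marker channel and reuses the mask on every channel
and exposure; under that convention normalized intensities are
exposure-invariant up to quantization, which the tests verify at 0.48 s
versus 0.96 s.

`normalize_to_control()` rescales every channel by its control-condition
mean, making the control mean exactly 1 and treatment values fold-of-control.

## Histogram-intersection classification

```{r gate-example}
stained <- generate_population(scenario_config(n_cells = 20000, seed = 1),
                               layout = FALSE)
blocked <- generate_population(
  scenario_config(n_cells = 5000, ib4_positive_fraction = 0, seed = 2),
  layout = FALSE)
g <- intersection_gate(blocked$intensity_ib4, stained$intensity_ib4)
g
```

`intersection_gate()` bins control and test intensities on shared edges
(100 bins over the pooled 0.1-99.9 percentile range), smooths both
densities with a Gaussian kernel (Silverman bandwidth), and takes as cutoff
the crossing — between the control mode and the test mode — beyond which
the test density dominates for at least 3 consecutive bins. Binning is on
the **log scale by default**: with a 180% CV the low mode occupies one or
two linear bins and the crossing cannot be located (on our synthetic IB4
scenario linear binning recovers ~65% positive against a 71% truth, log
binning ~69%). Linear binning remains available via `scale = "linear"`.
The rule is direction-aware — if the test mode lies below the control mode
the sides mirror — so swapping control and test inverts which side is
"positive". Ties at the cutoff classify negative; together with the
crossing rule this makes the positive fraction a conservative estimate of
the truly shifted class, and the recovered 69% above reflects exactly that
bias. Edge cases: indistinguishable densities report `"no_responders"`
(fraction 0); a test sample lying wholly beyond the control sample reports
`"complete_shift"` and gates every cell.

When culture identifiers are present, `classify_responders()` reports the
responder fraction per culture with its across-culture SD — the natural
reading of "x +/- y%" subgroup quotes — alongside the across-cell binomial
SE, since the original convention is not stated.

`subgroup_profiles()` summarizes subgroups (counts, per-channel mean and
SEM, 2-um diameter histograms matching the usual figure granularity) and
compares two subgroups with a one-tailed unpaired Student t-test;
`summarize_timecourse()` reports n / mean / SEM per time or dose group with
no curve fitting.

## Virtual wells and sensitivity

```{r wells-example}
pop <- lognormal_population(49503, mean = 1, cv = 1.8,
                            method = "stratified", seed = 3)
vw <- sample_virtual_wells(pop, 250, n_wells = 10000, seed = 4)
vw
detectable_effect(vw, k = 2, subgroup_fraction = 1 / 5,
                  round_percent = TRUE)
```

`sample_virtual_wells()` resamples wells of n cells and summarizes the SD
of the well means; `detectable_effect()` converts it into the smallest
change callable at k SDs (k = 2 by default), and divides by the subgroup
fraction for subgroup-restricted responses (an 11% SD at 250 cells gives a
22% whole-culture bound and 110% within a one-fifth subgroup).

Two deliberate choices:

* **Without replacement by default.** The published verbal description
  allows repeated picks, but the five published SDs at N = 49,503 match
  the finite-population-corrected closed form `sd/sqrt(n) x
  sqrt((N-n)/(N-1))` to under 1% at every n, while the with-replacement
  form deviates by up to ~23% at n = 20,000. Both modes are implemented;
  `closed_form_sd()` is the oracle either way.
* **Stratified reference population.** For a fixed reference population
  with stated moments, `lognormal_population(method = "stratified")` places
  one cell at the conditional mean of each 1/N quantile stratum and
  shuffles. A plain random lognormal draw of 49,503 values with CV 1.8 has
  ~5% sampling noise in its own SD (the lognormal's excess kurtosis is in
  the hundreds), which would swamp the well-to-well sampling error under
  study; the stratified construction has an exact mean and an SD within
  ~0.3% of nominal while keeping the lognormal shape. Random draws remain
  the default `method = "sample"`.

`compare_conditions()` runs the one-tailed unpaired t-test on well means
used for treated-versus-control calls, with the degenerate equal-constant
case fixed at p = 0.5 and flagged.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the virtual-well table at the
full published scale (N = 49,503; 10,000 wells for each of five well
sizes), the detection-rate fixture at ~650-700 neurons over five to six
rendered fields, and classification recovery at 40,000 + 5,000 cells (IB4)
and 4,000 + 4,000 cells (responders) averaged over 10 seeds — sizes chosen
to keep Monte-Carlo error well inside the tolerances being tested.
Throughout: seeds make every stochastic output bit-reproducible; histogram
densities integrate to one by construction (out-of-range values fall into
the end bins); all pixel coordinates in emitted tables are 0-based,
row-major.

## Known limitations

* The renderer has no optics model; detection rates on real widefield
  images with out-of-focus halos may differ from the synthetic ones.
* Threshold erosion biases segmentation-mask intensities of faint cells
  high (see above); measurements with matched masks are unbiased.
* The intersection cutoff assumes a dominant unshifted mode in the control;
  multimodal controls can make the chosen crossing ambiguous (the
  diagnostics expose the number of crossings).
* Cluster rejection discards real neurons (16% at default density), which
  is the intended, conservative behavior, not a loss the software tries to
  recover.
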