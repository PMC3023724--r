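# quamr — quantitative automated microscopy for heterogeneous neuron cultures

Dissociated dorsal-root-ganglion (DRG) cultures mix neurons of wildly
different sizes, marker intensities and signalling states with glia, debris
and cell clusters. Classifying cells "marker-positive" by eye is
ill-defined, and culture-mean readouts miss responses confined to a
subgroup. `quamr` is an R implementation of a quantitative automated
microscopy (QuAM) workflow for such cultures, aimed at anyone quantifying
per-cell immunofluorescence in adherent primary cells:

1. **Neuron identification.** Objects in the pan-neuronal marker channel
   (e.g. PGP 9.5) are accepted as single intact neurons only if they pass
   size (150–1500 µm²), shape (Feret aspect ratio ≤ 2; relative convex-hull
   concavity depth ≤ 0.25) and contrast (≥ 30% over local background)
   rules; border-cut objects and cell clusters are rejected.
2. **Quantification.** For each accepted neuron and channel, the integrated
   background-subtracted pixel intensity is normalized by soma area and
   exposure time, `I = raw / area / exposure`, with the exposure
   auto-selected under a saturation budget (max 0.96 s); intensities are
   rescaled so the control-condition mean is 1.
3. **Subgroup classification.** Marker-positive and stimulus-responsive
   cells are separated at the intersection of the control and test
   intensity histograms (shared log-scale bins, Gaussian-smoothed); the
   resulting positive fraction is a conservative estimate of the truly
   shifted class.
4. **Sensitivity.** "Virtual wells" of n cells resampled (without
   replacement) from the measured population give the SD of the well mean,
   `σ/√n · √((N−n)/(N−1))`, and hence the smallest detectable intensity
   change `k·SD` — e.g. an 11% SD at 250 cells per well means changes below
   22% cannot be called, and a response confined to 1/5 of the cells must
   exceed 110% within that subgroup.

A ground-truthed synthetic culture generator (lognormal baseline with CV
1.80, bimodal IB4 mixture with 71% positives, 50% responders, clustered and
border-cut neurons, glia/debris distractors) renders multi-channel
1280×1024 fields so the whole chain is testable without microscope data.

## Worked example

```r
library(quamr)

## 1. simulate and render a ground-truthed culture
sc  <- scenario_config(n_cells = 300, seed = 11)
fs  <- field_spec()
pop <- generate_population(sc, fs)
fields <- render_fields(pop, fs, exposure_s = 0.96, seed = 11)

## 2. identify neurons and quantify every channel
cells <- do.call(rbind, lapply(fields, function(f) {
  obj <- segment_field(f$images$marker)
  measure_field(obj, f$images, exposure_s = 0.96, condition = "control",
                field_id = f$field_id, gain = fs$gain)
}))
nrow(cells)
#> [1] 241

## 3. classify IB4(+) cells against a blocked-lectin control
blocked <- generate_population(
  scenario_config(n_cells = 5000, ib4_positive_fraction = 0, seed = 12),
  layout = FALSE)
intersection_gate(blocked$intensity_ib4, cells$intensity_ib4)
#> Histogram-intersection cutoff: 2.805 (ok, positive above)
#>   positive fraction: test 75.1%, control 1.7% (n = 241 / 5000)

## 4. virtual-well sensitivity at 250 cells per well
popw <- lognormal_population(49503, 1, 1.8, method = "stratified", seed = 13)
vw <- sample_virtual_wells(popw, 250, n_wells = 10000, seed = 14)
vw
#> Virtual wells: 10000 wells of 250 cells (N = 49503, without replacement)
#>   mean of means 1.0006, SD of means 0.1140 (closed form 0.1132)
detectable_effect(vw, k = 2, subgroup_fraction = 1/5, round_percent = TRUE)
#> $sd_percent ........ 11
#> $whole_culture_percent ... 22
#> $within_subgroup_percent . 110
```

What the numbers mean: 241 of the 300 simulated neurons survive the
identifier (the rest are clustered, border-cut, or fail a rule — the truth
table in `pop` says which); the intersection cutoff at intensity 2.8 calls
75.1% of the accepted cells IB4-positive against 76.3% ground truth in this
draw, with only 1.7% of the blocked control above the cutoff; and a
250-cell well carries an 11% SD on its mean, so only intensity changes
above 22% of the culture mean (110% within a one-fifth subgroup) are
detectable at 2 SD.

The methods vignette (`vignettes/quam-methods.Rmd`) documents the
statistical model behind the generator, each identifier rule, the cutoff
algorithm, and the design decisions.

A thin command-line front end is installed at
`system.file("cli", "quam.R", package = "quamr")` with subcommands
`simulate | segment | quantify | classify | wells | run` over the same
pipeline (`run_pipeline()` writes CSV artifacts plus a manifest with seeds
and checksums).

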