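# smstoich

Single-molecule TIRF stoichiometry and colocalization analysis in R.

## What problem this solves

In single-molecule TIRF microscopy, surface-captured protein complexes
appear as diffraction-limited fluorescent foci. Because every fluorophore
photobleaches irreversibly and independently, a focus's intensity trace
decays in discrete steps, and the brightness of one dye — calibrated from
those steps — converts intensities into molecule counts. Two-colour
imaging then reveals whether two labelled species are bound: their foci
colocalize. `smstoich` implements this measurement chain end to end for
people quantifying complex composition (e.g. amyloid-β oligomers and
their binding partners) from TIRF movies:

1. **Detection** — candidate spots per frame; sub-pixel centroids by
   iterative Gaussian masking; summed intensity over a small square ROI
   corrected for the local (border-ring) background; acceptance requires
   signal-to-noise ratio strictly above 0.4.
2. **Tracking** — frame-to-frame nearest-neighbour linking with optimal
   per-frame-pair assignment; tracks must last longer than 3 frames.
3. **Stoichiometry** — Chung–Kennedy edge-preserving filtering,
   photobleach step detection, single-dye calibration
   (kernel-density mode of single-dye intensities), and for tracks
   starting in the first 10 frames the photobleach-corrected initial
   intensity from an OLS line through the first 4 points:
   *S* = *I*₀ / *I*₁.
4. **Colocalization** — green/red pairs scored by the normalized Gaussian
   overlap integral
   *O* = [2σ_Aσ_B/(σ_A²+σ_B²)]·exp(−d²/(2(σ_A²+σ_B²))) ∈ [0, 1],
   colocalized when strictly above 0.75; per-field colocalized
   proportion; stoichiometry stratified by colocalization with a
   two-sided Student *t* test.
5. **Tissue workflow** — Otsu segmentation of the nuclei channel, hole
   filling and removal of objects under 50 px, a 100-px square ROI per
   nucleus, per-cell channel-pair Pearson correlation and summed
   background-corrected intensities.
6. **Synthetic data** — a simulator with integrated-Gaussian PSF,
   binomial-thinning photobleaching, Poisson shot noise and Gaussian read
   noise, with full ground truth, so every stage is testable by parameter
   recovery.

## Worked example

Simulate a two-colour field with six green complexes of known composition
(1, 2, 3, 5, 8, 10 fluorophores), half of which receive a red partner,
then run the full pipeline:

```r
library(smstoich)

spots <- data.frame(
  x = c(20.3, 60.7, 100.2, 140.6, 20.9, 60.4),
  y = c(20.6, 20.2, 20.8, 20.4, 60.3, 60.8),
  n_fluor = c(1, 2, 3, 5, 8, 10),
  channel = "green")

cfg <- sim_config(image_width = 160, image_height = 80, n_frames = 100,
                  photon_scale = 5000, bleach_prob = 0.05,
                  background_rate = 20, read_noise_sigma = 2,
                  spot_specs = spots, colocalized_fraction = 0.5,
                  partner_n_fluor = 3, seed = 1234)

res <- run_pipeline(cfg)
res$stoichiometry[, c("track_id", "start_frame", "initial_intensity",
                      "i_single", "stoichiometry", "n_steps")]
#>   track_id start_frame initial_intensity i_single stoichiometry n_steps
#> 1        1           0         10128.245 5045.643      2.007325       1
#> 2        2           0         24268.242 5045.643      4.809742       3
#> 3        3           0          5232.616 5045.643      1.037056       0
#> 4        4           0         15121.005 5045.643      2.996844       2
#> 5        5           0         41113.334 5045.643      8.148285       5
#> 6        6           0         48353.169 5045.643      9.583153       4

res$coloc$proportion
#> [1] 0.1666667
```

The single-dye intensity calibrated from the traces (5,046 counts) is
within 1 % of the simulated per-fluorophore brightness (5,000), and the
six stoichiometries (1.04, 2.01, 3.00, 4.81, 8.15, 9.58) recover the six
true compositions within the expected photobleaching/shot-noise scatter.
With this seed the Bernoulli(0.5) pairing happened to give exactly one of
six green spots a red partner, and the estimated colocalized proportion
(1/6) matches that realized truth. `run_pipeline(cfg, out_dir = "out/")`
additionally writes `foci.csv`, `tracks.csv`, `stoichiometry.csv`,
`steps.csv`, `colocalization.csv`, `summary.csv`, the resolved
configuration and a log; identical configuration and seed reproduce every
file byte for byte.

For tissue images:

```r
ti <- simulate_tissue_image(n_nuclei = 8, alpha = 0.6, seed = 3)
cells <- analyze_tissue(ti$channels, "nuclei")
```

gives one row per segmented nucleus with ROI correlation (`r_chA_chB`)
and summed corrected intensities (`sum_chA`, `sum_chB`).

A thin command-line wrapper over these functions lives at
`inst/scripts/smstoich-cli.R`
(`simulate | detect | track | stoich | coloc | tissue | run`).

## Method details

See the methods vignette (`vignettes/smstoich-methods.Rmd`) for the image
formation model, the filter and estimator definitions, the reconstruction
decisions taken where the original analysis is underspecified, and known
limitations.
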