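# motorpaint

Motor-based super-resolution mapping of microtubule polarity, as a fully
synthetic, ground-truthed R pipeline.

In the motor-PAINT assay, purified plus-end-directed kinesin motors are
added to a chemically fixed cytoskeleton. Each motor binds a microtubule
and walks unidirectionally toward its plus end; localizing and tracking
thousands of these runs reconstructs the microtubule array at tens of
nanometers resolution *and* reports the polarity of every microtubule,
because the walking direction is the polarity. In neurons this resolves
which dendritic microtubules point minus-end out (a plus-end-directed motor
on them moves inward, toward the soma) and which point plus-end out.

`motorpaint` implements the complete computational side of this assay for
users who want to study, validate, or extend the analysis without access to
raw movies:

* **Synthetic data** — ground-truthed microtubule networks (radial asters,
  dendrite-like mixed-polarity bundles, parallel arrays), stochastic motor
  kinetics (Poisson landing, truncated-normal speeds of 750 ± 300 nm/s,
  exponential run lengths, bleaching), and a camera forward model
  (integrated Gaussian PSF, Poisson shot noise, read noise, optional drift)
  written as multi-page 16-bit TIFF at 64 nm pixels and 10 Hz.
* **Localization** — Mexican-hat (Laplacian-of-Gaussian) spot detection,
  2D Gaussian fitting by unweighted Levenberg–Marquardt least squares,
  Thompson-style precision estimates, and drift correction from
  cross-correlated intermediate reconstructions.
* **Tracking** — nearest-neighbor linking with a 3-pixel (~192 nm)
  frame-to-frame limit, no frame gaps, a 3-frame minimum, and whole-track
  rejection when any inter-segment angle exceeds 75°.
* **Polarity** — orientation classes from the track's total displacement
  (quadrant scheme) or from projected arclength along a neurite axis
  (outward/inward scheme), plus 15-nm track interpolation for display.
* **Reconstruction and statistics** — per-orientation super-resolved
  rendering, cross-section FWHM measurement, the overlap correlation
  `C = Σ i_a i_b / √(Σ i_a² Σ i_b²)` versus rendering pixel size with its
  odd/even-localization control, and minus-end-out fractions in 5-µm axis
  segments.
* **Transport model** — the closed-form steady state of plus-end-directed
  cargo on a mixed-polarity bundle, `c(x) = c₀ e^{αx}` with
  `α = (p₊ − p₋)/l` for outward-run probability `p₊` and switching run
  length `l`, its cumulative count `n(x) = (e^{αx} − 1)/α`, the median
  position `L₅₀`, and a Monte-Carlo twin with reflecting boundaries.

## Worked example

Transport model: with a 2-fold plus-end-out enrichment (`p₊ = 2/3`) and a
2.05 µm switching run length on a 20 µm bundle,

```r
library(motorpaint)
m <- transport_model(p_plus = 2/3, p_minus = 1/3, l = 2.05, L = 20)
l50_fraction(m)                       # fraction of bundle beyond the median cargo
pos <- simulate_cargo(m, n_motors = 1e5, n_steps = 100, seed = 1)
mc_density_slope(pos, L = 20)         # Monte-Carlo estimate of alpha
```

prints `0.201` and `0.1632` (closed-form α = 0.1626 /µm): half of the
cargoes accumulate in the distal 20% of the bundle, and the simulated
steady state decays at the predicted exponential rate.

Full pipeline on a synthetic dendrite with 66% minus-end-out microtubules:

```r
cfg <- default_config(seed = 1)
cfg$network$params$minus_end_out_fraction <- 0.66
res <- run_pipeline(cfg, out_dir = "out")
res$segment$frac_minus_out
```

For this seed the movie yields 2,543 localizations and 162 filtered,
orientation-classified tracks, and the recovered minus-end-out fraction in
a 5-µm segment is `0.734` against a ground truth of `0.667` (single-seed
recoveries scatter by roughly ±0.06; the 5-seed mean lands within ±0.05 of
the truth). `out/` then contains the movie, localization and track tables,
per-orientation reconstructions, and a JSON report with counts at every
filter stage.

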