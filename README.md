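# striation

Quantitative analysis of laser-induced striation patterns in cell nuclei.

A laser-scanning microscope run at very low scan resolution (e.g. 32 x 32
pixels) with slow bidirectional scanning keeps its laser on between points
and therefore draws a pattern of collinear horizontal stripes across the
whole field. With a UV laser this micro-irradiates every nucleus in the field
at once; with a bleaching laser it bleaches the same geometry. `striation` is
for researchers who use this striping approach to follow DNA-damage-response
(DDR) reporters (e.g. MDC1-GFP, 53BP1-GFP) or FRAP reporters (e.g. H2B-GFP)
in live cells, or stripe-associated stains (e.g. phospho-H2AX) in fixed
samples, and who need per-nucleus, statistically testable readouts from
hundreds of cells per experiment.

## The measure at the core

For one nucleus at one time point, with the stripe bands of gauge `D`
(distance between stripe centers, in pixels), offset `P` and fixed width `w`
fitted inside the nucleus mask, the **Measure of Striation** is the relative
excess signal integrated density (SID) in the bands:

```
MS = (J_meas - J_expt) / J_expt,      J_expt = totalSID * stripeArea / maskArea
```

`J_meas` is the measured SID inside the bands; `J_expt` is what those bands
would hold if the nucleus were homogeneous. `MS = 0` means no stripes,
positive values mean recruitment into the damage stripes, negative values
(bounded by -1) mean bleaching. MS is invariant to the nucleus' total
brightness. The pipeline around it:

* **Segmentation** of the pre-irradiation frame by a cascade of decreasing
  thresholds with size/solidity gates (single global thresholds fail because
  baselines vary ~10-fold between nuclei);
* **Tracking** by local vicinity re-segmentation (striped nuclei can fall
  below any global threshold between their stripes);
* **Orientation** by Radon transform on a 1-degree grid, **fitting** of
  `(D, P)` by exhaustive integer grid search per nucleus and frame;
* **Curve parameters** per nucleus: `Amp` (peak MS; minimum for FRAP),
  `Tpeak` (minutes to the peak), `Relax` and `Relax30` (post-peak /
  late-window linear slopes);
* **Group statistics**: Kruskal-Wallis tests of each parameter against the
  pooled mock-treated control at alpha = 0.05, with an effect reported only
  when both biological replicates agree (`up` / `down` / `ns` coding);
* A seeded **synthetic scene generator** with exact ground truth, used to
  validate every stage.

## Worked example

Simulate a DDR striping experiment (20 nuclei, 32 lines per 512 px field,
10-fold baseline spread, detector noise), analyze it end to end, and
summarize:

```r
library(striation)

scene <- renderScene(sceneConfig(seed = 7))
scene$stack
#> FrameStack: 9 frame(s) of 512 x 512 px, t = 0, 2, 5, 10, 15, 20, 30, 45, 60 min
#>   channel: synthetic-DDR

res <- analyzeStack(scene$stack, analysisConfig("live_ddr"))
res$log
#> nuclei_found  tracks_lost fit_failures
#>           20            0            0

head(res$params[, c("nucleus_id", "amp", "tpeak_min", "relax", "peaked")], 3)
#>   nucleus_id       amp tpeak_min        relax peaked
#> 1          1 0.9275512        15 -0.010536112   TRUE
#> 2          2 1.3514915        15 -0.015299120   TRUE
#> 3          3 0.9016089        15 -0.009718665   TRUE

medianCurve(res$ms)[1:4, ]
#>   time_min  median_ms  n
#> 1        0 0.01718748 20
#> 2        2 0.44584071 20
#> 3        5 0.82982668 20
#> 4       10 1.03272855 20
```

Reading the output: every one of the 20 planted nuclei was found and tracked;
per-nucleus amplitudes (`amp`) estimate the planted peak MS (drawn between
0.8 and 1.4), the time-to-peak lands on the frame grid around the analytic
peak at 12.8 min, and the post-peak slopes (`relax`, MS/min) are negative as
the reporter disperses again. The median curve is the group-level readout:
zero striation before irradiation, a rise to ~1 within 10-15 minutes, then
relaxation. Compare a treated against a mock condition with
`compareToMock()` and tabulate a screen with `screenSummary()`.

The same pipeline runs from the shell via `inst/scripts/striation-cli`
(`simulate`, `analyze`, `compare` subcommands), and `runSimulate()` /
`runAnalyze()` / `runCompare()` read and write TIFF stacks, frame-time
sidecars and CSV tables on disk.

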