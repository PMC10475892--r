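# hisbeat

Beat-by-beat extraction of His bundle signals (HBS) from the PR interval of
cardiac time series.

## The problem

The His bundle fires between atrial and ventricular activation; its surface
signature is a ~100 Hz bi/triphasic deflection of very low amplitude hidden
in the PR segment, and the HV interval (His onset to QRS onset, normally
35–50 ms) is a key index of atrio-ventricular conduction. Outside invasive
electrophysiological studies, the HBS is usually only visible after
signal-averaging 100–200 beats in magnetocardiography (MCG) or body surface
potential mapping (BSPM) — which destroys all beat-to-beat information. The
obstacles to single-beat extraction are the ramp-like atrial repolarization
(PTa) waveform that overlaps the PR segment and beat-level noise.

`hisbeat` implements a two-stage method that recovers the His deflection in
*every* beat, for signal processors and electrophysiology researchers
working with MCG/BSPM-like recordings or simulations of them:

1. **Interval-dependent wavelet thresholding (IDWT).** Each PR epoch is
   decomposed with the `coif5` wavelet in five levels. Detail coefficients
   are soft-thresholded at the fixed-form (universal) level
   `t_j = σ_j √(2 ln N_j)`, *except* inside manually chosen time intervals
   around the His deflection, which pass through untouched; the two
   deepest detail levels, which carry no His energy at 1 kHz, are removed
   entirely. The interval/threshold set is built once from an annotated
   signal-averaged template and stored as a reusable "threshold function"
   applied to every raw epoch.
2. **Signal space projection (SSP).** The thresholded epochs are
   over-smoothed with a cubic Savitzky–Golay filter (23 ms frame), which
   keeps only the atrial content (P wave + ramps). The SVD of the smoothed
   epoch matrix gives an orthonormal atrial basis `U_n`; projecting each
   epoch through `P⊥ = I − U_n U_nᵀ` removes the atrial subspace and leaves
   the per-beat His signal `b_HB(t) = P⊥ b_PR(t)`.

The package also provides QRS-onset detection and PR epoching, the four
objective multichannel criteria for identifying a His bump on averaged
traces, a synthetic PR-epoch generator (three PTa types, calibrated white
Gaussian noise referenced to the P-wave peak, known HV ground truth),
quality metrics (peak SNR, band-limited signal-to-error ratio, Pearson
correlation, first-downward-deflection HV measurement), agreement
statistics (Spearman's ρ, Bland–Altman limits of agreement), inter-beat
contour matrices, and a CLI (`inst/cli/hisbeat`).

## Worked example

Simulate 200 PR epochs with a Type 1 atrial repolarization ramp (one third
of the P amplitude, opposite polarity), a His deflection at HV = 60 ms, and
20 dB SNR; then run the full pipeline and measure what comes out:

```r
library(hisbeat)

cfg  <- sim_config(pta_type = "type1", snr_db = 20, hbs_hv = 60,
                   n_epochs = 200, seed = 1)
sim  <- simulate_pr_epoch(cfg)
tpl  <- annotation_from_truth(sim$stack, sim$ground_truth,
                              hbs_dur_ms = cfg$hbs_dur)
spec <- build_threshold_spec(tpl, epochs = sim$stack)
spec
#> <threshold_spec> coif5, 5 levels, epoch length 350 @ 1000 Hz
#>   d1: threshold 0.3224, 13/176 coefficients preserved
#>   d2: threshold 0.2983, 8/88 coefficients preserved
#>   d3: threshold 0.2814, 5/44 coefficients preserved
#>   d4: threshold   Inf, 0/22 coefficients preserved (level zeroed)
#>   d5: threshold   Inf, 0/11 coefficients preserved (level zeroed)

hbs <- run_pipeline(sim$stack, spec)

ref <- sim$ground_truth$clean_hbs
r   <- apply(hbs$epochs, 1, pearson_corr, b = ref, window = 285:310)
hv  <- apply(hbs$epochs, 1, function(e) {
  nf <- sqrt(mean(e[1:40]^2))          # residual floor before the P wave
  measure_hv(e, 350, 1000, noise_floor = nf)
})
mean(r)                                #> 0.738
median(hv)                             #> 60  (truth: 60 ms)
```

The mean Pearson correlation between each extracted beat and the clean
reference deflection is 0.74 at 20 dB (it rises to ~0.93 at 28 dB), and the
median per-beat HV lands on the true 60 ms. Band-limited signal-to-error
ratios on the averaged traces show the intended selectivity — the His band
is preserved orders of magnitude better than the P-wave and noise bands:

```r
raw_avg <- signal_average(sim$stack); ext_avg <- signal_average(hbs)
ser(raw_avg, ext_avg, c(5, 30))        #> 2.4e-06   (P-wave band, suppressed)
ser(raw_avg, ext_avg, c(75, 100))      #> 0.0127    (His band, retained)
ser(raw_avg, ext_avg, c(150, 200))     #> 0.00054   (noise band, suppressed)
```

`interbeat_contour(hbs)` arranges the extracted beats as a beats × time
matrix (time in ms relative to the QRS onset) for heatmap display of the
His deflection's alignment across beats.

The same workflow is scriptable from a shell via the CLI:

```sh
inst/cli/hisbeat simulate --pta-type 1 --snr-db 20 --n-epochs 200 --seed 1 --out stack.csv
inst/cli/hisbeat template --in stack.csv --t1-ms 282 --t2-ms 312 \
    --hbs-onset-ms 289 --preserve 284:309 --out spec.json
inst/cli/hisbeat extract  --in stack.csv --spec spec.json --out hbs.csv
inst/cli/hisbeat evaluate --raw stack.csv --hbs hbs.csv \
    --truth stack.csv.truth.json --out report.json
```

## Vignette

`vignettes/hisbeat-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, the numerical choices (boundary
handling, threshold estimation, rank selection, onset rules), and known
limitations.
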