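# ckcnet

Detection of movement-evoked steady-state EEG responses (corticokinematic
coherence, CKC) and analysis of the directed cortical networks they
recruit — with a synthetic-data module that lets the entire pipeline run
and validate itself without any clinical recording.

## Who this is for

Clinical neurophysiologists and methods researchers working with
repetitive-movement (proprioceptive) stimulation paradigms — e.g. a
pneumatic actuator flexing a newborn's fingers at a constant rate while
scalp EEG is recorded — who need an automated, statistically principled way
to answer two questions per recording:

1. *Is there a phase-locked cortical response?*
2. *How far does the response spread through the cortical network, and how
   symmetric / lateralized is it?*

## The model in brief

Stimulation at rate f₀ = 1.78 Hz evokes two afference volleys per cycle
(flexion + extension), so the analysis is pinned to the first harmonic
f = 2f₀ = 3.56 Hz. After zero-phase 0.5–30 Hz filtering, resampling to
250 Hz, non-overlapping trigger-locked epoching (−200…+900 ms, local-mean
detrend) and a reference-free spherical-spline CSD transform (m = 3,
λ = 0), each channel's instantaneous phase θₙ(t) at the pinned wavelet bin
gives the inter-trial phase coherence over N epochs

    ITC = | (1/N) Σₙ exp(i θₙ) |

The channel's **CKC** is the mean ITC over epoch time 0–700 ms; its
significance comes from the Rayleigh closed form

    P = exp( √(1 + 4N + 4N²(1 − ITC²)) − (1 + 2N) )

averaged over the same window, thresholded at α = 0.01 with
Benjamini–Hochberg FDR across channels (q = 0.01).

Cortical parcel signals (58 parcels, supplied via any linear projection)
are band-limited to 3.56 ± 0.3 Hz (order-626 Hamming FIR,
forward–backward), reduced to Hilbert phases, and every parcel pair is
scored with directed phase transfer entropy

    dPTE_xy = PTE_xy / (PTE_xy + PTE_yx)        (0.5 = no preferred direction)

On top of the per-subject interaction matrices the package computes
group-level **Consistent Networks** (per-subject top-k edges, exact
binomial tests, FDR), and per-subject **Spreading Index** (percentage of
control-referenced significant outbound edges from the hemisphere's 4
strongest source parcels), plus **laterality** (100·contra/(contra+ipsi))
and **symmetry** (100·min/max) ratios.

## Worked example

Simulate a 125 s recording with a phase-locked response on C3/C4 (per-trigger
phase jitter SD 1.0 rad, response RMS equal to the in-band background RMS),
then run the full detection pipeline on its first 100 epochs:

```r
library(ckcnet)

rec <- generate_scalp_recording(duration = 125, phase_jitter_sd = 1.0, seed = 1)
rec
#> <eeg_recording> 21 channels x 31250 samples @ 250 Hz (125.0 s), 223 triggers

res <- run_detection_pipeline(rec, max_epochs = 100)
res
#> <ckc_result> wavelet method, 100 epochs @ 3.56 Hz: peak CKC 0.428 (C3), 3/21 significant

dplyr::filter(tidy(res), significant)
#> # A tibble: 3 × 5
#>   channel   ckc             p       p_adj significant
#>   <chr>   <dbl>         <dbl>       <dbl> <lgl>
#> 1 C3      0.428 0.0000000735  0.000000772 TRUE
#> 2 Cz      0.332 0.0000319     0.000223    TRUE
#> 3 C4      0.424 0.00000000860 0.000000181 TRUE
```

The planted response channels (C3, C4, plus the adjacent midline Cz, which
picks up the CSD sidelobes) are detected; the other 18 channels are not.
`ckc = 0.428` is the mean inter-trial phase coherence at 3.56 Hz — the
phase-jitter ceiling for σ = 1.0 rad is exp(−σ²/2) ≈ 0.61, and in-band
noise at SNR 1 brings it down to ≈ 0.4. `p` is the aggregated Rayleigh
probability of that coherence arising from uniform phases; `p_adj` is its
BH-adjusted value across the 21 channels.

Hemispheric summary of the same result:

```r
ckc_laterality(res, stim_side = "right")
#> # A tibble: 1 × 3
#>   contra  ipsi laterality
#>    <dbl> <dbl>      <dbl>
#> 1  0.428 0.424       50.2
```

A bilateral synthetic response gives laterality ≈ 50 %; a purely
contralateral one gives 100 %. `autoplot(res)` draws the per-channel CKC
bar map, and `epoch_count_sweep()` traces detection as epochs accumulate.

For networks: `generate_parcel_signals()` plants known directed coupling,
`dpte_matrix()` estimates the 58×58 interaction matrix,
`consistent_network()` aggregates subjects, and
`reference_distribution()` → `edge_zscores()` → `spreading_index()`
computes the SI against a control recording.

A thin command-line front end over the same functions ships at
`inst/cli/ckcnet.R` (subcommands `simulate`, `detect`, `sweep`, `network`,
`si`).

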