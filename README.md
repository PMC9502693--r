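# cardiovoice

Trinary cognitive-workload classification from two unobtrusive
psychophysiological signals: beat-by-beat cardiovascular measures and
formant-track voice features, fused at the level of individual
heartbeats. The package is aimed at human-factors and psychophysiology
researchers who monitor mental demand with hemodynamic monitors and
speech — for example workload assessment of pilots or air-traffic
controllers — and who need the full pipeline from raw per-beat /
per-frame files to leave-one-screen-out confusion tables.

## The method

A session consists of 21 task screens per participant at three
difficulty levels (7 low / 6 medium / 8 high, Stroop-style colour
naming). Two time-indexed feature streams are extracted:

* the per-heartbeat 10-vector `c_n` (heart rate, systolic/diastolic/mean
  pressure, pulse interval, stroke volume, left-ventricular pressure
  energy, cardiac output, total peripheral resistance, maximum
  steepness), optionally expanded with regression-based delta and
  acceleration dynamics over a ±2-beat window to `c_n^(δ,a)` (30-dim);
* the first three formant frequencies every 10 ms, optionally expanded
  at frame level to 9 tracks, then synchronised to heartbeats: beat `n`
  owns the half-open frame window `(τ_n − Δ_n/2, τ_n + Δ_{n+1}/2]`
  (`Δ_n = τ_n − τ_{n−1}` the pulse interval), and every track in the
  window is summarised by 10 statistics — quadratic-fit coefficients on
  beat-centred time, min, max, mean, median, sd, skewness, kurtosis —
  giving `φ_n` (30-dim) or `γ_n` (90-dim).

Feature-level fusion concatenates the beat-aligned blocks, e.g.
`x_n = [γ_n^T, c_n^(δ,a)T]^T` (120-dim). Per participant, three linear
one-vs-rest maximum-margin classifiers (soft score = signed boundary
distance) or a 100-tree bootstrap ensemble (soft score = vote
proportion) produce an `N × 3` score matrix `Y`; the beat decision is
the row argmax and the screen decision is the argmax of the column sums
`y_k(X) = Σ_n y_k(x_n)`. Leave-one-screen-out evaluation accumulates
3×3 confusion tables, from which per-class misclassification rates
(MCR, row off-diagonal share), mistrust rates (MTR, column off-diagonal
share) and the overall MCR are derived.

A synthetic Stroop-style cohort generator (level-shifted heart rate and
pressures with AR(1) beat noise; vowel-template formant tracks with
level-shifted means and paced level-3 segment timing) makes the whole
pipeline testable end to end without any recordings.

## Worked example

Simulate one participant's 21-screen session, extract the fused
120-dimensional feature set, and evaluate it leave-one-screen-out:

```r
library(cardiovoice)

cfg <- simulationConfig(nParticipants = 1, seed = 7)
manifest <- simulateCohort(cfg, file.path(tempdir(), "demo"))
screens <- participantScreenFeatures(manifest, "p001", "gamma+c_da")
screens[[1]]
#> BeatFeatureMatrix 'gamma+c_da': 42 beats x 120 features, labelled

res <- losoEvaluate(screens, classifierConfig("margin_ovr", seed = 1))
res$sequenceConfusion
#>       classified
#> actual L1 L2 L3
#>     L1  7  0  0
#>     L2  0  6  0
#>     L3  0  0  8
#> overall MCR: 0.00%

res$beatConfusion
#>       classified
#> actual  L1  L2  L3
#>     L1 275  15   0
#>     L2  52 149  56
#>     L3   0  17 342
#> overall MCR: 15.45%
```

Each screen (~42 heartbeats at this participant's ~84 bpm) receives one
sequence decision — here all 21 screens are classified correctly once
the per-beat soft scores are summed — while individual heartbeats are
noisier (15.45% of beats misclassified, mostly into adjacent levels).
Metrics work on any 3×3 confusion table, e.g. a published one:

```r
t3 <- ConfusionTable(rbind(c(569, 65, 45), c(51, 454, 77), c(23, 48, 705)))
round(mtrPerClass(t3), 2)
#>    L1    L2    L3
#> 11.51 19.93 14.75
round(overallMcr(t3), 2)
#> [1] 15.17
```

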