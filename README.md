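# subica

Removal of muscular (EMG) artifacts from short, high-density EEG segments by
**electrode-neighborhood subspace ICA**, for EEG researchers and engineers who
need artifact cleaning on segments too short — relative to the channel count —
for ordinary ICA.

## The problem and the method

ICA-based artifact removal estimates an unmixing `s = B x` of the
channels-by-samples record `x`, zeroes the components classified as muscle
artifact (retention matrix `Q`), and reconstructs `x_clean = B^{-1} Q B x`.
On short segments of dense montages this *overlearns*: with `M` channels and
only `N ~ fs` samples the estimated components degenerate into spurious
transient bumps and artifacts cannot be isolated. Yet short segments are
exactly what is needed, because the spatial mixing of a muscle artifact is
only near-stationary for about a second.

`subica` runs ICA never on all `M` channels but on `M` overlapping
**neighborhood subspaces**: for each electrode `k`, the `L` nearest
electrodes (default `L = 12`) are extracted by a binary selection matrix
`P_k`, separated by FastICA (`B_k`), classified, cleaned
(`C_k = B_k^{-1} Q_k B_k`) and recombined through the Moore–Penrose
pseudoinverse of the stacked projection:

    x_clean = P⁺ C P x = D x,   P = [P_1; …; P_M],  C = blockdiag(C_1 … C_M)

Because each `P_k` selects channels, `P` has orthogonal columns and
`P⁺ = diag(1/c_j) Pᵀ` — each channel is an average over the neighborhoods
containing it. If nothing is classified as artifact, `D` is exactly the
identity: clean data are not distorted, unlike PCA-based dimension reduction.

Components are classified by the band-power ratio
`α = min(P(3–30 Hz)/P(60–90 Hz), P(3–30 Hz)/P(110–140 Hz))`; `α < 2.5`
marks a muscular artifact (EMG is broadband, brain rhythms are
low-frequency).

The package also provides the standard comparison methods (plain ICA,
high-pass and AR-prefiltered ICA, PCA reduction, PCA + regression), a
synthetic EEG/EMG ground-truth simulator with an exact artifact-to-EEG
energy-ratio control `ξ`, and a benchmark that scores reconstructions by the
average channel correlation `r` against the known clean signal.

## Worked example

```r
library(subica)

m  <- standard_montage("1010")          # packaged 61-channel layout
gt <- simulate_trial(m, xi = 4, seed = 7)  # artifacts 4x stronger than EEG
gt$mixed
#> <eeg_record> 61 channels x 1024 samples @ 1024 Hz (1 s)

mean_correlation(gt$mixed$data, gt$clean$data)
#> [1] 0.638      # unprocessed mixture vs clean truth

res <- process_record(gt$mixed, m, removal_config(seed = 7))
res
#> <removal_result> 1 segment(s), 64 component(s) zeroed, mean effective rank 50

mean_correlation(res$cleaned$data, gt$clean$data)
#> [1] 0.7263     # after subspace cleaning
```

The mixture correlates with the clean truth at `r = 0.64`; after cleaning,
`r = 0.73`. Of the 61 × 12 subspace components, 64 were classified as
muscular and zeroed, yet the removal operator `D` still keeps 50 of 61
dimensions at 99% singular-value energy — the rank cost is localized to
where the artifact actually is. For a systematic comparison across methods
and `ξ` use `run_benchmark()`; for the dependence on the subspace dimension
use `sweep_L()`.

A command-line wrapper ships at `inst/cli/subica.R`
(`subica clean | baseline | simulate | benchmark | sweep-l`), a thin layer
over the functions above.

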