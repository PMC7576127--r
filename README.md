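# hyperspike

Hyperacuity spike-time inference from two-photon calcium-imaging traces.

Calcium imaging reports neuronal spiking through a slow, noisy, sometimes
non-linear fluorescence proxy sampled at 5–100 Hz, while the underlying
action potentials are millisecond events. `hyperspike` reconstructs spike
times at a resolution *finer than the imaging frame interval* by combining

1. a **generative calcium response model** — a double-exponential
   single-spike transient
   `g(t, T) = (1 − e^((T−t)/τ₁)) e^((T−t)/τ₂)` for `t ≥ T`, superposed
   linearly over spikes with amplitude `a`, baseline `b₀` and Gaussian
   noise `σ`, estimated from training data by EM-style alternating updates
   with latent sub-frame onsets and a coordinate grid search over
   `(τ₁, τ₂)`;
2. **classifier-based detection** — a matched-filter *coincidence score*
   (trace derivative ⊛ kernel derivative) proposes threshold-crossing
   candidates, and a radial-basis SVM trained on labelled candidate
   segments separates spikes from false crossings, with threshold and
   segment length optimized on training F1;
3. **vernier timing refinement** — each accepted detection's *sampling
   jitter* is found on a grid ten times finer than the frame interval by
   minimizing the model-prediction residual, after subtracting preceding
   spikes' modelled transients; the refined time is `TT = PT + SJ`.

A fully **unsupervised mode** estimates the model, firing rate and spike
candidates directly from the trace by penalized greedy maximum likelihood,
then trains the classifier on self-simulated data.

The package also ships the benchmark **simulator** (Poisson spiking,
power-law burst nonlinearity, SNR-calibrated noise) and the **evaluation
stack**: windowed one-to-one spike matching, sensitivity/precision/F1,
Victor–Purpura-style weighted spike distance, the CosMIC overlap score,
the hyperacuity index (sampling interval / mean absolute timing error over
hits), and a leave-one-out cross-validation harness.

It is aimed at experimenters with simultaneous imaging + electrophysiology
(supervised mode), at anyone with imaging-only data (unsupervised mode),
and at methodologists benchmarking spike-inference timing precision.

## Worked example

Simulate six cells at 30 Hz (1 Hz Poisson firing, SNR 5, τ₂ = 0.5 s),
train on the first half, test on the second:

```r
library(hyperspike)

cfg <- SimulationConfig(firingRate = 1, nCells = 6, spikesPerCell = 30,
                        tau2 = 0.5, alpha = 1, snr = 5, samplingRate = 30,
                        seed = 42)
ds  <- generateDataset(cfg)
run <- runSupervised(ds[attr(ds, "train")], ds[attr(ds, "test")])

run$model
#> CaSpikeModel: tau1 = 0.009675 s, tau2 = 0.4942 s, a = 0.9987, b0 = 0.008644, sigma = 0.1833
#>   single-spike peak 0.9066 at 0.03824 s after onset
run$config
#> DetectionConfig: threshold 1 robust SD, segment -1/+4 frames, vernier 1/10, window 0.05 s
run$reports[[1]]
#> EvalReport (window 0.05 s)
#>   hits 30, misses 1, false positives 2
#>   sensitivity 0.968, precision 0.938, F1 0.952
#>   spike distance 0.270 (inverse 3.701), CosMIC 0.816
#>   hyperacuity index 3.721
```

The fitted model recovers the generating parameters (true τ₁ = 0.01 s,
τ₂ = 0.5 s, a = 1, σ = a·ĝ_peak/SNR ≈ 0.18). On the first test cell, 30 of
31 true spikes are detected with 2 false positives (F1 0.95), and the mean
absolute timing error of the hits is the frame interval divided by the
hyperacuity index — (1/30 Hz)/3.72 ≈ 9 ms, i.e. almost four times finer
than the 33 ms sampling grid.

Unsupervised, on a bare trace:

```r
est <- unsupervisedPipeline(ds[[5]]$trace, seed = 1)
evaluateSpikes(ds[[5]]$spikes, est, samplingRate = 30)  # truth used for scoring only
```

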