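# teamfuse

Multi-level fusion of asynchronous multi-athlete wearable-sensor streams,
and a collaborative-dynamics indicator system for quantifying team
coordination.

Modern team-sport tracking combines, per athlete, an IMU (200 Hz), GPS
(10 Hz, ±0.5 m), a local-positioning tag (40 Hz, ±0.1 m), heart rate and
pressure insoles — streams with different clocks, accuracies, latencies
and dropouts. `teamfuse` integrates them hierarchically:

* **Sensor level** — zero-lag Butterworth filtering, SNR-based quality
  (`SNR = 20 log10(A_signal/A_noise)`, recalibration flagged below
  15 dB), complementary-filter orientation
  `θ_t = α(θ_{t−1} + ω Δt) + (1−α)φ`.
* **Individual level** — adaptive-weight combination of positional
  sources, `w_t = λ w_{t−1} + (1−λ) q_t r_t` with λ = 0.65, where the
  quality–relevance product is a precision share tracked block-wise, plus
  IMU dead-reckoning increments between fixes. Phase-matched alignment
  uses movement-cycle events and an interpolating non-uniform B-spline
  `X_aligned(t) = Σ P_i N_{i,d}(t)` (d = 3); DTW is the baseline.
* **Team level** — team trajectory and centroid, wavelet-packet features
  (K = 5, top 15% by energy) with tensor fusion
  `𝒯 = 𝒳 ×₁W₁ ×₂W₂ ×₃W₃`, and fusion quality `Q_info = I(X;F)/H(X)`.

On the fused trajectory it computes windowed coordination indicators —
spatial synchronization (SSI), temporal coordination rate (TCR),
formation stability (FSQ), tactical information entropy (TIE),
perturbation response (CPR), individual–collective coupling (ICC),
decision synchronicity (DMS), load distribution harmony (LDH) — plus
team spatial entropy, relative position maintenance, multi-scale
cross-recurrence statistics (RR, DET, LAM, diagonal entropy) and the
Kuramoto order parameter `R(t) = |n⁻¹ Σ e^{iφ_j(t)}|`. A linear path
model `P_team = β₁C_spatial + β₂C_temporal + β₃Σ w_i P_ind,i + ε`, a
four-metric logistic outcome classifier (in-package IRLS,
leave-one-session-out evaluation) and mean-shift change-point detection
link coordination to performance.

Because no public dataset accompanies the method, the package ships a
coupled-oscillator session simulator with deployment-faithful sensor
corruption; its coupling strength κ is the synthetic dial for team
coordination, giving every indicator a known ground truth to recover.

## Worked example

```r
library(teamfuse)

sim <- simulate_session(sim_config(n_athletes_per_team = 4,
                                   duration_s = 120,
                                   coupling_kappa = 2, seed = 7))
res <- run_pipeline(sim$manifest, sim$streams, sim$truth$events,
                    truth = sim$truth)
head(res$indicators[c("t", "ssi", "tcr", "fsq", "tie", "icc", "ldh",
                      "r_mean")], 5)
#>       t   ssi   tcr   fsq   tie   icc   ldh r_mean
#> 1     5 0.906   0.8 0.935     0 0.964 0.976  0.991
#> 2    10 0.969  NA   0.966    NA 0.988 0.996  0.992
#> 3    15 0.968  NA   0.966    NA 0.988 0.994  0.992
#> 4    20 0.968  NA   0.965     0 0.988 0.988  0.992
#> 5    25 0.972  NA   0.967     0 0.989 0.988  0.992
```

At κ = 2 the simulated team is strongly coupled, so SSI, ICC and the
order parameter sit near 1; TIE is 0 in windows whose few passes all use
one athlete pair and NA where no pass occurred (missing, never zero); TCR
is NA in windows without acceleration events. The quality report
summarizes fusion accuracy against the simulator truth:

```r
res$quality$position_rmse_m   # 0.155  (GPS alone: ~0.68)
res$quality$snr_gain_db       # 12.9   dB gained over the raw GPS stream
res$quality$q_info            # 0.65   information preserved, [0, 1]
```

`autoplot(res$team)`, `autoplot(res$indicators)` and
`autoplot(res$records[[1]])` draw the pitch map, the indicator panel and
the adaptive-weight history; `tidy()`/`glance()` work on fitted path
models and classifiers. A command-line entry point
(`inst/cli/teamfuse`) exposes `simulate`, `fuse`, `indicators`,
`compare`, `perform` and an end-to-end `demo`:

```sh
Rscript inst/cli/teamfuse demo --seed 7 --out demo_out/
```

writes `fused_individual.csv`, `team_trajectory.csv`, `indicators.csv`,
`quality_report.json` and `comparison.csv`.

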