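# pulsefeat

Landmark detection and per-cycle feature extraction for arterial blood
pressure (ABP) and photoplethysmography (PPG) waveforms.

Every cardiac cycle of a pressure or pulse-volume waveform carries five
temporal landmarks — systolic phase onset (SPO), systolic phase peak (SPP),
dicrotic notch (DN), diastolic phase peak (DPP) and diastolic phase endpoint
(DPE, the next cycle's onset). `pulsefeat` locates them automatically and
derives 852 named morphological features per cycle, for researchers building
pulse-wave-analysis pipelines or feature-based clinical models.

The detection core is the **iterative envelope mean (IEM)**: a normalized
4-second window is repeatedly reduced by the sample-by-sample mean of its
upper and lower envelopes (monotone-cubic interpolants through the extrema
of a Savitzky–Golay-smoothed copy),

&nbsp;&nbsp;&nbsp;&nbsp; r₀ = y,&nbsp;&nbsp; r_{j+1} = r_j − (U(r_j) + L(r_j))/2,

until the envelope mean is below β·range(y) (β = 0.1). The final residual —
the non-stationary component, NSTS — exposes each cycle's landmarks as
signed extrema even when they are barely visible in the raw trace: systolic
and diastolic peaks must be positive, onset/notch/endpoint valleys negative,
with a 0.1-s separation floor between SPP and DN and between DPP and DPE
(25 samples at the nominal 256 Hz). Landmark positions are then refined to
the waveform's own local extrema. Detections are scored with the standard
tolerance rule (±8 ms = 2 samples at 256 Hz), sensitivity / PPV / F1 /
error-rate metrics and Bland–Altman agreement. A synthetic pulse-train
generator with analytic ground truth makes the whole pipeline testable
without clinical data.

## Worked example

Simulate four seconds of a 72-bpm arterial waveform, run the full pipeline,
and score the detected landmarks against the generator's ground truth:

```r
library(pulsefeat)

syn <- synth_pulse_train(synth_params(duration_s = 4, heart_rate_bpm = 72,
                                      seed = 42))
run <- featurize_record(syn$record)
run
#> pulsefeat run (recorded): 1/1 windows accepted, 3 cycles detected

run$vitals
#>   window_id cycle_id   sbp   dbp   map
#> 1         1        1  117.  77.4  88.0
#> 2         1        2  117.  77.4  88.0
#> 3         1        3  117.  77.4  88.0

run$features[1:3, c("cycle_id", "ABP_AM_SPP_wrtSPO",
                    "ABP_D_SPO_wrtDPE", "ABP_FD_fundamental_hz")]
#>   cycle_id ABP_AM_SPP_wrtSPO ABP_D_SPO_wrtDPE ABP_FD_fundamental_hz
#> 1        1             0.990            0.840                  1.19
#> 2        2             0.991            0.844                  1.18
#> 3        3             0.991            0.840                  1.19

ev <- evaluate_detection(run$landmarks, syn$truth, fs = 256)
ev$counts[, c("landmark_type", "tp", "fp", "fn", "se", "ppv", "f1", "er")]
#>   landmark_type tp fp fn se ppv f1 er
#> 1           SPO  3  0  0  1   1  1  0
#> 2           SPP  3  0  0  1   1  1  0
#> 3            DN  3  0  0  1   1  1  0
#> 4           DPP  3  0  0  1   1  1  0

ev$bland_altman
#> Bland-Altman: n = 12, bias = 0.0003255 s, LoA = [-0.005746, 0.006397] s
```

Reading the output: all three complete cycles in the window are found, every
landmark lands within the ±8 ms tolerance of its true position (SE = PPV =
F1 = 1, error rate 0), and the Bland–Altman bias of 0.3 ms with limits of
agreement inside ±7 ms shows the per-landmark timing agreement. The feature
columns shown are the systolic amplitude above the onset (normalized units),
the cycle duration in seconds, and the cycle's fundamental frequency in Hz
(≈ 72 bpm / 60). `run$features` holds all 852 features per cycle;
`write_features()` serializes them one row per cycle with `NA` sentinels as
empty cells.

Each stage is also usable on its own — `screen_window()`,
`lowpass_filter()`, `normalize_minmax()`, `iem_decompose()` (with `tidy()`,
`glance()` and `autoplot()` methods), `delineate_cycles()`,
`build_manifest()`, `extract_cycle_features()`, `match_landmarks()`,
`compute_metrics()`, `bland_altman()`. A thin command-line front end with
`featurize`, `simulate`, `evaluate` and `manifest` subcommands lives at
`inst/cli/pulsefeat.R`.

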