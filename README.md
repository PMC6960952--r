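# gaitevents

Determination of the four basic gait events — heel strike (HS), toe strike
(TS), heel off (HO) and toe off (TO) — from tri-axial accelerometers worn on
the heel and the toe during continuous walking. The package is aimed at
movement-analysis work where optical motion capture is unavailable:
rehabilitation monitoring, wearable gait assessment, activity recognition
research.

## Method

For each sensor site, sampled at $f_s$ (nominally 1000 Hz):

1. **Wavelet modulus-maxima denoising.** With $W_a(2^j,i)$ an undecimated
   wavelet transform, modulus maxima satisfying
   $\log_2|W_a(2^j,i)| \le \log_2 k + j\beta$ are tracked across dyadic
   scales; chains whose fitted exponent $\hat\beta \ge 0$ (signal) are kept,
   decaying chains ($\hat\beta < 0$, noise) are removed, and the record is
   rebuilt from the surviving maxima by alternating projections.
2. **Gravity removal.**
   $a_{Sz}(i) \leftarrow a_{Sz}(i) - \tfrac1N\sum_i a_{Sz}(i)$ over the
   whole record.
3. **Jerk-threshold segmentation.** The comprehensive change rate
   $J_{aS}(i) = \sqrt{\Delta a_{xS}^2 + \Delta a_{yS}^2 + \Delta a_{zS}^2}$
   is smoothed with a trailing 30 ms window and binarized against
   $th_S = r\cdot\max ja_S$ ($r = 0.05$): flat phases (foot on ground,
   binary 0) versus non-flat phases (binary 1).
4. **Frequency-domain double integration.** Displacement is
   $d_{sz}(n) = \mathrm{IDFT}\!\left[A_{sz}(k)/(j\omega_k)^2\right]$,
   $\omega_k = 2\pi k f_s/N$, with the DC and sub-0.1 Hz bins zeroed; the
   integration trend is removed by an 8-level sym8 wavelet decomposition
   with the deepest approximation band set to zero.
5. **Event determination.** Within each flat phase (±120 ms margin), the
   strike is the first displacement trough reached by a sharp drop
   ($\le -0.05$ m/s over 50 ms) and the off is the first later trough left
   by a sharp rise ($\ge +0.05$ m/s): $T_{HS}=t_{H\min1}$,
   $T_{TS}=t_{T\min1}$, $T_{HO}=t_{H\min2}$, $T_{TO}=t_{T\min2}$.

Detected sequences are validated against a reference with per-label error
statistics and a Bland-Altman analysis (mean difference ± 1.96 SD limits of
agreement). A synthetic treadmill-gait generator with exact ground-truth
event times provides end-to-end validation; see the methods vignette
(`vignettes/gait-event-detection.Rmd`) for the model, parameter rationale
and limitations.

## Worked example

```r
library(gaitevents)

trial <- make_trial(gait_params(n_cycles = 10, seed = 42))  # 10 s at 1000 Hz
det   <- detect_gait_events(trial$heel_rec, trial$toe_rec)
head(det$events, 8)
#>   label  time sample_index
#> 1    HS 1.191         1191
#> 2    TS 1.317         1317
#> 3    HO 1.664         1664
#> 4    TO 1.839         1839
#> 5    HS 2.192         2192
#> 6    TS 2.316         2316
#> 7    HO 2.666         2666
#> 8    TO 2.837         2837

m <- match_events(det$events, trial$truth)
summarize_errors(m$pairs)
#>   label n    mean_diff     sd_diff median_diff         mae
#> 1    HS 9 -0.005888889 0.001964971      -0.005 0.005888889
#> 2    TS 9 -0.007333333 0.002738613      -0.008 0.007333333
#> 3    HO 9  0.014555556 0.003811532       0.016 0.014555556
#> 4    TO 9  0.011333333 0.004582576       0.010 0.011333333

bland_altman(m$pairs$diff)
#> <bland_altman> n=36 mean=0.003167 s sd=0.01052 s LoA [-0.01745, 0.02378] s outside 0 (0.0%)
```

The events come out in physiological order (HS at 1.191 s, TS 126 ms later,
HO mid-stance, TO at 64 % of the cycle); against the generator's exact truth
the mean absolute timing error is about 10 ms — strikes slightly early, offs
slightly late, the systematic signature of the wavelet detrending step — and
all 36 differences fall inside the 95 % limits of agreement.

The same pipeline is available from a shell:

```sh
Rscript exec/gaitevents simulate --out /tmp/trial --seed 42
Rscript exec/gaitevents detect   --heel /tmp/trial_heel.csv \
        --toe /tmp/trial_toe.csv --out /tmp/events.csv
Rscript exec/gaitevents validate --detected /tmp/events.csv \
        --reference /tmp/trial_truth.csv --out /tmp/report.csv
```

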