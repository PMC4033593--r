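# cprsaa

Shock/no-shock ECG rhythm analysis **during ongoing chest compressions**.

Defibrillators normally force rescuers to interrupt cardiopulmonary
resuscitation (CPR) because chest compressions corrupt the ECG, and shock
advice algorithms (SAAs) cannot diagnose the rhythm reliably through the
artifact. Every interruption lowers the chance of defibrillation success.
`cprsaa` implements a complete analysis chain that avoids the interruption:

1. **Compression-artifact suppression.** The artifact is modeled as a
   quasiperiodic interference on the first five harmonics of the
   instantaneous compression frequency *f₀(n)*, derived from the compression
   marks *tₖ* (the instants of individual compressions, available from a CPR
   assist pad's compression-depth channel):

   *s*<sub>cpr</sub>(n) = Σₖ₌₁⁵ cₖ(n) · cos(k·2π·f₀(n)·n + ϕₖ(n)),  f₀(n) = 1/(tₖ − tₖ₋₁)

   An adaptive LMS filter tracks the time-varying amplitudes and phases, and
   the filtered ECG is *s*<sub>filt</sub> = ECG − *s*<sub>cpr</sub>.
2. **Two-stage shock advice on the filtered ECG**, per 3-s window:
   * a **low-electrical-activity (LEA) detector** — windows with
     *P*<sub>LEA</sub> < 0.44 or *L*<sub>min</sub> < 0.63 (energy and minimum
     0.5-s curve length of the 2.5 Hz high-passed window) are declared
     nonshockable outright, which is what makes the method specific for
     asystole under filtering residuals;
   * a **Gaussian-kernel SVM** on four standardized features — slope
     baseline *bS*, slope peak count *nP*, and the power fractions
     *P*<sub>fib</sub> (2.5–7.5 Hz) and *P*<sub>h</sub> (> 12 Hz) — with
     *f*(x) = Σ αᵢyᵢ exp(−γ‖x−xᵢ‖²) + b, shock iff *f*(x) > 0.

   Each 9-s segment is diagnosed by majority vote over its three windows.
3. **Training and evaluation tools**: LEA threshold calibration (maximize
   asystole detection, at most 5 % of shockable windows lost), class-weighted
   5-fold cross-validated grid search minimizing the balanced error rate
   BER = 1 − (TPR + TNR)/2, sensitivity/specificity/AUC/PPV metrics, and
   record-level bootstrap confidence intervals.
4. **Synthetic signal generators** (coarse VF, organized rhythms, asystole,
   compression artifacts, full corrupted corpora), so the whole chain is
   testable without clinical data.

## Worked example

```r
library(cprsaa)

# a synthetic corpus: 20 records, balanced rhythm classes, artifact mixed
# at 0 dB in-band SNR, with ground truth attached
corpus <- gen_corpus(20, c(VF = 0.4, ORG = 0.3, ASY = 0.3),
                     snr_db = 0, duration = 18, seed = 42)

# train on the first half: LEA calibration + SVM grid search
feats <- corpus_features(corpus[1:10])
model <- train_saa(feats)
model
#> <saa_model> LEA: P_LEA < 0.00112 or L_min < 0.555; <saa_svm> 37 support
#> vectors, C = 0.25, gamma = 0.03125, CV BER = 0.000

# diagnose an unseen record (an organized rhythm under the artifact)
res <- analyze_record(corpus[[12]], model)
res$segments[, c("segment", "decision", "sh_votes", "truth")]
#>   segment decision sh_votes truth
#> 1       1      NSh        0   NSh
#> 2       2      NSh        0   NSh

# evaluate the held-out half
report <- evaluate_corpus(corpus[11:20], model, ci_reps = 1000)
report
#> <saa_report> windows: Se 100.0% Sp 95.8% | segments: Se 100.0% Sp 100.0%

# how trustworthy is a shock advice at a given VF prevalence?
ppv(se = 0.910, sp = 0.966, p_vf = 0.23)   # 88.88 (%)
ppv(se = 0.910, sp = 0.966, p_vf = 0.67)   # 98.19 (%)
```

`analyze_record()` reports, for every 3-s window, the advice (`Sh`/`NSh`),
which stage decided (`LEA` or `SVM`) and the SVM discriminant value; segment
rows carry the majority decision and the vote count. `evaluate_corpus()`
returns counts, sensitivity (shockable rhythms correctly advised), specificity
(nonshockable correctly advised), BER, a per-class breakdown and record-level
bootstrap confidence bounds.

A command-line front end for the same pipeline ships in `inst/cli/cprr`
(subcommands `simulate`, `filter`, `features`, `train`, `classify`,
`evaluate`):

```sh
cprr=$(Rscript -e 'cat(system.file("cli/cprr", package = "cprsaa"))')
Rscript $cprr simulate --n 50 --mix vf=0.4,org=0.3,asy=0.3 --snr -5 --seed 42 --out corpus/
Rscript $cprr train --corpus corpus/ --out model.json
Rscript $cprr classify --input corpus/r001.csv --model model.json --out diagnoses.csv
```

## Package layout

| file | contents |
| --- | --- |
| `R/signal-core.R` | traces, marks, records, CSV/WFDB I/O, band-pass, segmentation |
| `R/filters.R`, `R/resample.R` | Butterworth design in second-order sections, polyphase resampling |
| `R/cpr-filter.R` | instantaneous compression frequency, harmonic LMS canceller |
| `R/features.R` | the six per-window discrimination features |
| `R/classifier.R` | LEA detector, SVM training/decision, majority vote |
| `R/synthetic.R` | rhythm, artifact, depth-channel and corpus generators |
| `R/evaluation.R` | Se/Sp, BER, PPV, AUC, LEA calibration, bootstrap CIs |
| `R/pipeline.R` | end-to-end analysis, training, model JSON serialization |

See the vignette (`vignettes/rhythm-analysis-during-cpr.Rmd`) for the model,
its assumptions, parameter choices and limitations.
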