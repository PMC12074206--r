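# facialEMG

Time-domain feature analysis of bilateral facial surface EMG for grading
facial-palsy severity and selecting biofeedback parameters.

## The problem

Facial palsy (FP) is conventionally graded with examiner-dependent ordinal
scales such as the House–Brackmann (HB) score (I = normal function, VI =
complete paralysis). Surface electromyography (sEMG) offers an objective
alternative: with three bipolar electrode pairs over the forehead, eye and
mouth regions of each facial side, a subject performs a fixed protocol of
instructed movements — 20 trials of 3 s MOVE followed by 4 s REST, sampled
at 2000 Hz, for six runs (smile / close eyes / raise forehead, each strong
and light). The analysis question is which of the many time-domain EMG
features both (a) track palsy severity across subjects and (b) separate
MOVE from REST robustly enough to drive EMG biofeedback.

`facialEMG` implements that analysis end to end:

1. **Conditioning** — 4th-order Butterworth band-pass (10–250 Hz) and
   band-stop (48.5–51.5 Hz, mains), applied zero-phase per channel.
2. **Segmentation** — purely protocol-clock-driven partition of each run
   into per-trial MOVE and REST intervals (6000 / 8000 samples each at the
   default protocol).
3. **Features** — twenty time-domain features per interval, channel and
   side: iEMG, MAV, MMAV1, MMAV2, SSI, VAR, RMS, STD, WL, DASDV, AAC, LOG,
   IAV, VORDER, ZC, SSC, WAMP, MYOP, KURT, SKEW.
4. **Asymmetry index** — for each feature *f*,

   `AI_f = (f_healthy − f_lesioned) / (f_healthy + f_lesioned) × 100`

   so 0 % is complete bilateral symmetry and +100 % complete absence of
   lesioned-side activity.
5. **Severity ranking** — per movement, the Fisher score of each feature's
   AI across the five ordinal HB groups (HB I controls, HB I patients,
   HB II+III, HB IV+V, HB VI),

   `FS(f) = Σ_i n_i (μ_i − μ)² / Σ_i n_i σ_i²`,

   Spearman rank correlation of the AI with the HB group, and paired
   MOVE-vs-REST contrasts with partial eta-squared effect sizes.

Because clinical recordings cannot be redistributed, the package includes a
**synthetic cohort generator**: band-limited (20–250 Hz) Gaussian EMG bursts
amplitude-modulated by the MOVE/REST envelope, attenuated on the lesioned
side according to a configurable HB-grade→attenuation map, plus baseline
noise and 50 Hz mains interference. Every pipeline stage is tested against
this generator.

## Worked example

Simulate one HB IV patient (lesioned left), run one "smile strong"
protocol, and compute the asymmetry indices:

```r
library(facialEMG)

protocol <- ProtocolSpec(movement = "smile", intensity = "strong")
patient  <- SubjectProfile("P01", hb_grade = 4, lesioned_side = "left",
                           seed = 2026)
rec <- generateRecording(patient, protocol)
rec
#> EmgRecording: 280000 samples x 6 channels @ 2000 Hz (140.0 s)
#>   channels: left_forehead, left_eye, left_mouth, right_forehead, ...

res <- analyzeRecording(rec, protocol)   # condition + segment + features
agg <- cbind(subject_id = "P01", res$aggregated)
md  <- data.frame(subject_id = "P01", hb_grade = 4, is_control = FALSE,
                  lesioned_side = "left")
ai  <- buildAsymmetryTable(agg, md, magnitude = TRUE)
subset(ai, feature %in% c("mav", "rms", "ssc") & condition == "MOVE")
#>  subject_id movement intensity condition feature healthy lesioned ai_percent
#>         P01    smile    strong      MOVE     mav    35.1     12.3       48.2
#>         P01    smile    strong      MOVE     rms    44.4     15.6       48.1
#>         P01    smile    strong      MOVE     ssc   841.5    316.8       45.3
```

HB grade IV maps to an amplitude attenuation of 0.35
(`attenuationForGrade(4)`), and the amplitude features recover the implied
asymmetry, `(1 − 0.35)/(1 + 0.35) × 100 ≈ 48.1 %`, from the simulated
signal. Note that the count feature SSC tracks severity less linearly —
at 48.2 % vs 45.3 % the discrepancy is small here, but across a cohort the
Fisher scores of amplitude features dominate those of count/shape features.

For a whole severity-graded cohort:

```r
res <- runSyntheticAnalysis(n_per_group = 10, groups = 0:4,
                            protocols = list(protocol),
                            master_seed = 20260101)
rankFeatures(res$ranking, movement = "smile", intensity = "strong")
spearmanVsHb(res$asymmetry$ai_percent[res$asymmetry$feature == "mav" &
                                      res$asymmetry$condition == "MOVE"],
             res$asymmetry$hb_group[res$asymmetry$feature == "mav" &
                                    res$asymmetry$condition == "MOVE"])
```

File-based runs use `simulateCohort()` / `analyzeCohort()` /
`reportCohort()` (or the wrapper script `inst/scripts/femg-pipeline.R`);
recordings are stored as delimited text or EDF.

## Documentation

The methods vignette (`vignettes/facial-emg-grading.Rmd`) describes the
signal model, the feature definitions and conventions, the asymmetry and
ranking statistics, every tunable parameter with its default and rationale,
and the known limitations of the synthetic validation.
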