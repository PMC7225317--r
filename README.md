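# pttsdb

Pulse transit time (PTT) indices for screening children for
sleep-disordered breathing (SDB), for sleep physiologists and
respiratory researchers working with limited multi-channel sleep studies
(oximetry, ECG, photoplethysmography, video/sound) where full
polysomnography is unavailable.

PTT is the interval from the ECG R-wave midpoint to the 50%-amplitude
point of the following plethysmograph upstroke; it varies inversely with
blood pressure. The package computes the two indices built on it:

* **PTT arousal index (PTT-AI).** A subcortical arousal appears as a drop
  in the smoothed channel PTT2 (17-point moving average, ~3.2 s at 5 Hz)
  of ≥ 15 ms over 5–45 s while PTT2 is within the valid 150–500 ms range.
  PTT-AI = arousals per artifact-free hour.
* **PTT respiratory swing.** Inspiratory effort modulates PTT with each
  breath; the swing is the mean inspiratory-trough to expiratory-peak
  rise of the 1 Hz-interpolated, 3-sample-smoothed PTT channel, in ms.

Around these it implements the full screening analysis: artifact rules
(spikes > 50 ms, out-of-range values; < 3 h artifact-free PTT or < 4 h
oximetry excludes a record), oxygen desaturation events (> 4% below
baseline for > 5 s and < 180 s) with a dip index and a four-level
oximetry risk category, five-way study classification (normal, primary
snoring, UARS, OSA, abnormal other) from oximetry plus video
annotations, and train/test ROC threshold selection (90% sensitivity,
90% specificity, and maximum sensitivity + specificity cut-offs) with
percentile-bootstrap confidence intervals. A seeded synthetic-cohort
generator produces beat series, waveforms, SpO2 traces and annotations
with known ground truth.

## Worked example

Simulate a small cohort, extract features for one child, then run the
end-to-end pipeline:

```r
library(pttsdb)

cfg <- cohort_config(n_children = 60, seed = 11, study_hours = 2)
coh <- generate_cohort(cfg)

ch <- coh$children[[1]]
ptt_features_for_record(ch$beats)
#> <ptt_feature_set> PTT-AI 9.08/h (18 arousals), swing 3.25 ms, 1.98 artifact-free h [excluded: <3 h]
oximetry_summary(ch$spo2, min_hours = 1.5)
#> <oximetry_feature_set> baseline 97.5%, mean 97.4%, min 92.1%, DI 2.00/h -> normal

rep <- run_pipeline(pipeline_config(
  cohort = cfg, seed = 11, n_boot = 200,
  min_oximetry_hours = 1.5, min_ptt_hours = 1))
rep
#> <pipeline_report> 60 children, 60 in PTT threshold set
#>   swing max-sum threshold 7.70 ms: test sens 0.50 spec 1.00
#>   PTT-AI max-sum threshold 15.95 /h: test sens 1.00 spec 1.00
```

The per-child feature set reports the arousal count and index, the
respiratory swing and the artifact-free hours (this 2 h test study is
flagged against the 3 h inclusion rule; the pipeline call lowers the
inclusion thresholds to match the short simulated studies). The pipeline
report shows, for each PTT index, the threshold that maximised
sensitivity + specificity in the training half and its performance on
the held-out half: the swing threshold of 7.7 ms falls between the two
group centres of the computed (chain-attenuated) swing distributions,
and the arousal-index threshold of ~16/h separates the planted 8/h from
25/h arousal rates cleanly at this sample size.

Reference accuracy statistics can be recomputed from the printed
contingency tables shipped with the package:

```r
contingency_accuracy(reference_oximetry_table())
#> $sensitivity 0.3846154  $specificity 0.9823009
```

— abnormal oximetry detects UARS/OSA with sensitivity 0.38 and
specificity 0.98, the motivating gap that the PTT indices address.

## Layout

* `R/` — implementation (types, synthetic cohort, signal extraction, PTT
  features, oximetry, classification, diagnostics, pipeline, IO).
* `src/` — compiled turning-point (zigzag) extraction.
* `inst/extdata/` — reference-cohort contingency counts (plain CSV).
* `vignettes/ptt-sdb-methods.Rmd` — the model, rules, numerical choices
  and generator design in detail.
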