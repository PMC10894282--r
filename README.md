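# semgrsa

Consistency and distinguishability analysis of multi-channel surface
electromyography (sEMG) for attempted hand movements.

## What this package is for

For people born with a partial forearm, a central question in myoelectric
prosthesis control is whether *attempted* movements of the missing hand
still drive the residual forearm muscles in reproducible, mutually
distinguishable ways. `semgrsa` implements the complete statistical
pipeline for that question from multi-channel sEMG sessions in which each
of 10 hand movements is repeated over cued relaxation/contraction cycles on
both the affected and the intact (control) limb:

* **Feature extraction** — per-repetition root-mean-square amplitude
  `RMS = sqrt(sum(x_i^2)/N)` and mean frequency
  `MNF = sum(f_j p_j)/sum(p_j)` over a 0–1000 Hz spectrum in 0.4 Hz bins,
  after discarding 15% of each cued phase from onset and recession and
  normalizing each channel to its maximum (percent scale).
* **Within-movement consistency** — Kendall's coefficient of concordance W
  across repetitions ranking the channels, with tie correction and the
  conventional strength bands (poor < 0.20 ≤ minimal < 0.40 ≤ weak <
  0.60 ≤ moderate < 0.80 ≤ strong).
* **Distinguishability** — split-data representational dissimilarity
  matrices (even vs odd repetitions, distance `1 − τ_b`) summarized by the
  exemplar discriminability index, `EDI = mean(off-diagonal) −
  mean(diagonal)`, tested by condition-label randomization with an
  exhaustive n! permutation null (vectorized, 10! ≈ 3.6M permutations in
  well under a second).
* **Across-limb comparisons** — exact Wilcoxon signed-rank on paired
  per-movement W values, and RDM relatedness via Kendall's τ_a under
  50,000 joint row/column label permutations.
* **Visualization support** — nonmetric multidimensional scaling under the
  squared-stress criterion, plus box-plot data tables for every channel ×
  movement × phase.

Because real clinical sessions of this kind are restricted, the package
also ships a seeded synthetic two-limb session generator with explicit
knobs for movement distinctness, repetition jitter, and affected-limb
fidelity/attenuation, used throughout the tests to verify that the
pipeline recovers known structure and stays calibrated when there is none.

## Worked example

```r
library(semgrsa)

# a reduced-rate session (500 Hz) so this runs in seconds
cfg <- protocol_config(sampling_rate = 500, band = c(20, 200), f_max = 240)
sess <- generate_cohort(cfg, distinctness = 0.9, fidelity = 0.9,
                        attenuation = 0.8, seed = 1, gain = 2.5,
                        rep_jitter_sd = 0.05)
feats <- normalize_features(rbind(compute_features(sess$unaffected, cfg, "rms"),
                                  compute_features(sess$affected, cfg, "rms")))

head(movement_consistency(feats, "rms"), 4)
#>      limb movement measure         W category
#>  affected       IF     RMS 0.9935714   strong
#>  affected       KP     RMS 0.9142857   strong
#>  affected       PP     RMS 0.9785714   strong
#>  affected       IP     RMS 0.9178571   strong

sdrdm <- build_split_rdm(summarize_channels(feats, "even"),
                         summarize_channels(feats, "odd"),
                         "RMS-median", limb = "affected")
edi_randomization_test(sdrdm, "exhaustive")
#> EDI = 0.9630, p = 2.756e-07 (exhaustive null of size 3.6288e+06)

s_all <- summarize_channels(feats, "all")
rdm_relatedness_test(build_rdm(s_all, "RMS-median", "affected"),
                     build_rdm(s_all, "RMS-median", "unaffected"), seed = 2)
#> RDM relatedness: tau_a = 0.5687, p = 2e-05 (50000 permutations)
```

Read: every attempted movement on the (synthetic) affected limb produced a
strongly consistent cross-channel pattern (W ≥ 0.80); the movement set is
discriminable (large positive EDI, p far below 0.05 against the exhaustive
permutation null); and the affected limb's movement structure is related to
the intact limb's (τ_a = 0.57, p = 2e-5).

`run_pipeline(cfg, "out/", seed = 1)` runs everything — features,
summaries, W tables, RDMs and split RDMs, EDI tests, the limb comparison,
relatedness tests, and MDS coordinates — writing each artifact as
tab-separated text plus a JSON manifest with per-file digests, so a rerun
with the same seed is digest-identical. A thin command-line wrapper lives
at `inst/scripts/semgrsa-pipeline.R`.

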