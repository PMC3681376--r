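# thermentropy

Complexity analysis of continuously monitored body temperature in systemic
inflammation, for researchers studying physiological signal variability in
critical care.

Continuously recorded skin temperature (0.1 Hz, 0.05 °C resolution) carries
slow oscillations — neurogenic (0.025–0.05 Hz), metabolic (0.00625–0.025 Hz)
and ultradian (< 0.00625 Hz) — whose irregularity reflects the state of the
thermoregulatory system. In systemic inflammatory response syndrome (SIRS)
without infection these oscillations stay broadband and complex; with sepsis
and septic shock the signal becomes organized and loses entropy.
`thermentropy` quantifies this with wavelet and information-theoretic
features and carries them through the complete statistical workflow.

## Methods at a glance

* **Preprocessing**: artifact repair by linear interpolation over annotated
  segments, mean removal (`sign_m`) and linear detrending (`sign_mdetr`).
* **Discrete Meyer wavelet features** (9 dyadic scales, scale *i* covering
  [fs/2^(i+1), fs/2^i] Hz): per-scale wavelet energy
  WE(sᵢ) = Σⱼ w²(sᵢ,j)/Lᵢ and wavelet entropy
  WEn(sᵢ) = −Σⱼ pⱼ log pⱼ with pⱼ = w²(sᵢ,j)/Σⱼ w²(sᵢ,j) normalized per
  scale. The 102-tap discrete Meyer filter is generated internally from the
  analytic frequency response; the periodized pyramid conserves energy to
  ~1e-8 relative.
* **Continuous Meyer wavelet features**: energy and entropy of the
  time–scale map, whole-map and per band (CWTen, CWTentro, CWTen1..4,
  CWTentro1..4).
* **Multiscale entropy**: sample entropy (m = 2, r = 0.15 SD, Chebyshev
  distance, self-matches excluded) over coarse-graining factors τ = 1..36;
  `sumEn` sums the defined scales, `SampEn` is the τ = 1 value.
* **Statistics**: Monte-Carlo Lilliefors, pairwise Wilcoxon rank-sum (exact
  when the combined n ≤ 20), Kruskal–Wallis with Dunn/Bonferroni follow-up,
  Spearman ρ against SOFA, one-way ANOVA.
* **Clustering**: euclidean dissimilarity over feature subsets, 2-cluster
  k-means, intraclass/interclass distances, clustering cost, agreement with
  the SIRS-versus-infected partition.
* **Classification**: random-subset wrapper (subsets of 4, scored by
  leave-one-out balanced accuracy of an LDA), per-feature significance
  index, pairwise LDA evaluation.
* **Synthetic cohorts**: a generator producing 24-h, 0.1-Hz, quantized
  temperature signals with band-structured oscillations and a per-band
  regularity knob (broadband 1/f noise ↔ slowly drifting oscillation), so
  every stage is testable without patient data.

## Worked example

```r
library(thermentropy)

co  <- generate_cohort(default_group_profiles(),
                       cohort_config(n_per_group = c(5, 10, 7), seed = 1234,
                                     artifact_rate = 1))
ft  <- extract_feature_table(co)          # 44 rows x 32 candidate features
det <- ft[ft$variant == "sign_mdetr", ]
aggregate(det[, c("WEn_s5", "sumEn")], list(group = det$group), median)
```

```
         group WEn_s5 sumEn
1       sepsis   4.19  63.1
2 septic_shock   3.75  34.0
3         SIRS   4.93  72.3
```

Mid-scale wavelet entropy (`WEn_s5`, the 5.3–10.7 min ultradian band) and
multiscale entropy (`sumEn`) fall from SIRS through sepsis to septic shock:
the loss of thermoregulatory complexity the features are built to detect.
Clustering on the ultradian CWT entropies separates SIRS from the infected
groups perfectly on this cohort, and wavelet entropies anticorrelate with
the SOFA severity score (`sumEn`: ρ = −0.73, p = 1e-4).

The numbered drivers under `analysis/` run the same workflow end to end
(simulate → preprocess → features → statistics → clustering →
classification → recovery study), print what they find, and write their
tables under `results/`; per-subject signal CSVs go to `scratch/`. Run them
in order from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
...
Rscript analysis/07_recovery_study.R
```

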