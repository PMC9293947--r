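# facekin

Video-based quantification of hypomimia (facial bradykinesia) from facial
landmark dynamics.

## The problem

Hypomimia — reduced amplitude and frequency of spontaneous and deliberate
facial movement — is a hallmark motor sign of Parkinson's disease (PD), yet
it is usually graded by eye on a coarse 0–3 perceptual scale. `facekin`
implements a fully automatic assessment: given per-frame 68-point facial
landmarks (iBUG 300-W convention) from a monologue video recording, and
optionally the grayscale frames themselves, it computes **twelve
facial-dynamics markers over eight facial regions** and runs the cohort-level
statistics and classification needed to characterise hypomimia in a
case–control study.

It is aimed at movement-disorder researchers who have landmark tracks (from
any external detector) and want objective, interpretable per-region facial
kinematics.

## The markers

Every marker is the sample standard deviation over frames of a per-frame
facial quantity — variability of movement, not its absolute level:

| Region | Marker(s) | Per-frame quantity |
|---|---|---|
| forehead | forehead lines | entropy of the edge-highlighted forehead patch (bits) |
| nose root | nose-root lines | same, glabellar patch |
| eyebrows | elevation, tilt, shape (L/R) | apex–nose-tip distance / IED; brow-line vs inter-canthal angle; apex triangle angle |
| eyes | palpebral aperture (L/R) | shoelace area of the 6-point eye contour / IED² |
| lateral canthal | canthal lines (L/R) | edge-entropy of the crow's-feet patch |
| cheeks | cheek surface (L/R) | entropy of the difference of consecutive cheek patches |
| mouth | upper lip, lower lip, mouth corner (L/R) | lip/corner–nose-tip distance / IED |
| jaw | jaw | chin–nose-tip distance / IED |

IED is the inner-eye-corner (medial canthi, landmarks 39/42) distance; all
Euclidean markers are IED-normalized, making them invariant to face scale and
rigid translation (angle markers also to rotation). Surface patches use
luminance normalized by the representable maximum into [0, 1]. Frames in
which any landmark is obscured form gaps: gaps of at most one second are
linearly interpolated, longer gaps split the recording and are excluded.
Bilateral markers are side-averaged for cohort analysis (19 sided values →
12 averaged).

The cohort pipeline follows the standard case–control design: KS-gated
ANOVA / Kruskal–Wallis group tests with Bonferroni correction over the 19
sided comparisons (adjusted threshold 0.05/19 = 0.0026), Pearson partial
correlations controlled for age, control-based 5%-tail abnormality cutoffs
with affected-area counting over the 8 regions, and leave-one-subject-out
(LOSO) ridge-logistic classification with exhaustive marker-subset search,
ROC/AUC metrics, and prevalence estimation at an operating point whose
control false-positive rate is strictly under 5%.

Because real clinical recordings are private, the package includes a
deterministic synthetic-cohort generator (`synth_config()`,
`simulate_cohort()`): animated landmark recordings plus procedurally
rendered grayscale frames with ground-truth severity, where severity
multiplies movement amplitude down.

## Worked example

```r
library(facekin)

cfg <- synth_config(n_controls = 20, n_patients = 20, duration = 10,
                    width = 160, height = 120, seed = 7)
sim <- simulate_cohort(cfg)          # landmarks + frames + markers

head(sim$markers[, c("subject_id", "avg_jaw", "avg_forehead_lines")])
#>   subject_id   avg_jaw avg_forehead_lines
#> 1       S001 0.2397616          1.1901776
#> 2       S002 0.2460579          0.7909733
#> 3       S003 0.2384867          1.0704775
#> 4       S004 0.2449049          0.9369534
#> 5       S005 0.2404884          1.0532846
#> 6       S006 0.2401555          0.6206936

res <- cmd_analyze(sim$markers, sim$cohort)
res$classification
#> <facekin_clf> LOSO ridge-logistic classification (PD vs HC)
#>   n = 40, markers: forehead_lines, nose_root_lines, eyebrow_elevation, ...
#>   AUC 1.000 | accuracy 100.0% | sensitivity 100.0% | specificity 100.0%
#>   operating point (control FPR < 5%): threshold 0.008, prevalence 100.0%, achieved FPR 0.0%
```

`avg_jaw` is the variability of the normalized chin–nose-tip distance
(dimensionless; larger = more jaw movement); `avg_forehead_lines` is the
variability of forehead wrinkle entropy in bits. Patients (severity > 0)
score lower on both, which is what the classifier exploits: the printed
report gives the pooled LOSO AUC, the confusion-table metrics at the 0.5
probability threshold, and the prevalence of hypomimia at the bounded
false-positive operating point.

For file-based workflows, `cmd_simulate()` materializes a fixture tree
(landmark CSVs, cohort table, optional PNG frames), `cmd_extract()` turns a
directory of recordings into a marker table, and
`inst/cli/facekin.R` wraps these as `simulate` / `extract` / `analyze`
subcommands.

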