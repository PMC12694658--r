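# lidarousal

Non-contact estimation of electrodermal arousal from LiDAR reflection
intensity.

Electrodermal activity (EDA, skin conductance) is a direct physiological
index of sympathetic arousal, but it normally requires electrodes on the
skin. An active near-infrared range sensor (LiDAR) aimed at the forehead
records the intensity of backscattered light, which is modulated by sweat
gland activity and skin hydration. `lidarousal` implements the full
analysis for testing whether those intensity fluctuations carry the phasic
EDA signal: a seeded multi-subject simulator of stimulus-locked skin
conductance recordings with a coupled LiDAR channel, signal cleaning and
phasic/tonic decomposition, a rank-percentile arousal statistic, and
feature- and sequence-based models evaluated under random-split and
leave-one-subject-out (LOSO) validation.

## The core statistic

For each sliding 100 s context window of the phasic EDA signal
(z-normalized per segment), the mean of the terminal 10 s is placed at its
empirical rank percentile within the context and shifted to a symmetric
scale:

    f = 100/N * |{ x_i <= m }| - 50,       f in [-50, +50]

where `m` is the terminal-window mean. `+50` marks a strongly positive
arousal change, `0` a neutral course, `-50` a strongly negative one. As a
rank statistic it is invariant to affine rescaling of the signal, which
absorbs inter-individual amplitude differences. For classification the
factor is cut into `k` equal-width classes over `[-50, +50]`; models are
scored with balanced accuracy (BA) and the chance-corrected *normalized
improvement*

    NI = (BA - c) / (1 - c),    c = 1/k,

which is 0 at chance and 1 at perfection. Regression reports MAE, RMSE and
R² on the centered scale, plus Pearson correlation and Bland–Altman
agreement (limits of agreement = bias ± 1.96·SD).

Models map a 10 s single-channel LiDAR window (200 samples at 20 Hz) to
the EDA-derived factor — classical learners (Extra Trees, Random Forest,
k-NN, Gradient Boosting, SVM, logistic regression, XGBoost) on a fixed
12-feature window summary, and sequence networks (GRU, LSTM, 1D-CNN, TCN)
on the raw window, trained with Adam (lr 0.001, cross-entropy or MSE,
75 epochs by default) on a small fully-tested neural-network engine
included in the package.

## Worked example

Simulate three subjects with a common-sign LiDAR coupling, run the whole
pipeline (clean → label → features → train → evaluate) under both
validation strategies, and print the report:

```r
library(lidarousal)

cfg <- run_config(
  simulation = sim_config(n_subjects = 3, rest_duration = 100, n_stimuli = 60,
                          coupling_gain_mean = 2, coupling_gain_sd = 0.3,
                          eda_noise_sd = 0.01, lidar_noise_sd = 0.05,
                          seed = 42),
  preprocessing = preprocess_params(detrend_window = 20, tonic_cutoff = 0.01),
  segmentation = segmentation_params(stride = 50),
  k = 3,
  model_specs = list(model_spec("extra_trees", "classification"),
                     model_spec("extra_trees", "regression")),
  strategies = c("random", "loso"),
  seed = 42
)
res <- run_pipeline(cfg)
print(res)
```

```
<pipeline_result> 2 report(s), seed 42
-- random_k3 --
<evaluation_report> strategy random, 2 model(s)
        model           task  k strategy    ba    ni ba_macro ni_macro  mae
1 extra_trees classification  3   random 0.711 0.567    0.711    0.567   NA
2 extra_trees     regression NA   random    NA    NA       NA       NA 7.78
  rmse    r2 pearson_r pearson_p
1   NA    NA        NA        NA
2   12 0.642     0.805  6.84e-22
-- loso_k3 --
<evaluation_report> strategy loso, 2 model(s)
        model           task  k strategy    ba    ni ba_macro ni_macro  mae
1 extra_trees classification  3     loso 0.664 0.496    0.674    0.511   NA
2 extra_trees     regression NA     loso    NA    NA       NA       NA 8.08
  rmse    r2 pearson_r pearson_p
1   NA    NA        NA        NA
2 12.5 0.622     0.789  1.62e-78
```

Reading the numbers: under the random split the three-class Extra Trees
classifier reaches BA 0.711, i.e. NI 0.567 — 57% of the possible
improvement over the 1/3 chance level. The regression recovers the factor
with R² 0.64 and r 0.81 on the centered −50…+50 scale (MAE 7.8 factor
units). Because every subject here shares the same coupling sign and the
noise is low, LOSO holds up almost as well (NI 0.50); with
subject-specific couplings the gap between the two strategies widens
sharply — that contrast is exercised in the test suite.

`report_ni_table(res, "random")` summarizes NI per model and class count,
and with `out_dir` set, `run_pipeline()` persists every intermediate
(per-subject recordings, labeled segments, feature matrix, per-segment
predictions, training logs, `report.json`).

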