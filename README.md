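# beatfuse

Multilabel arrhythmia classification from 12-lead ECG by **beat-level
attention fusion**, in pure R.

Most deep ECG classifiers treat a record as an undifferentiated time
series. `beatfuse` treats the **heartbeat** as the unit of analysis: a
record is segmented into beats at detected R-peaks, every beat is encoded
by one shared CNN + bidirectional-GRU encoder, and a masked attention
mechanism fuses the per-beat features into a record-level representation —
upweighting the beats that carry diagnostic evidence — before a sigmoid
multilabel head. For a record $X \in \mathbb{R}^{L\times D}$ with beats
$b_1,\dots,b_s$ and per-beat features $f_i \in \mathbb{R}^{640}$:

$$u_i = \tanh(W f_i + b),\qquad
  \alpha_i = \mathrm{softmax}_i\!\left(u_i^\top u\right) \text{ over valid beats},\qquad
  f_{\mathrm{att}} = \sum_i \alpha_i f_i ,$$

trained with multilabel binary cross-entropy plus an explicit L2 penalty,
Adam, Xavier/orthogonal initialization, and (optionally) a cross-validation
ensemble that averages the fold models' probabilities. Evaluation uses the
rank-formula (Mann-Whitney) AUC with midranks for ties, macro-averaged over
classes.

The package contains:

* `synth_*`, `synthesize_record()`, `synthesize_dataset()` — a seeded
  synthetic 12-lead ECG generator (Gaussian P-QRS-T bumps, RR jitter,
  noise, baseline wander, separable class morphologies) with exact R-peak
  ground truth, so the whole pipeline is testable without downloads;
* `detect_rpeaks()`, `pt_transform()` — a Pan-Tompkins detector re-derived
  for 100 Hz (zero-phase 5–15 Hz bandpass, five-point derivative, squaring,
  moving-window integration, adaptive thresholds with search-back);
* `segment_record()` — masked fixed-slot beat stacks (25 samples before /
  55 after the R-peak, 20 slots);
* `build_model()` / `fit()` / `predict_probs()` — the full model plus two
  ablation variants (`backbone`: same encoder on the unsegmented record;
  `temporal_attention`: attention over encoder time steps), with
  hand-implemented forward/backward passes verified against finite
  differences;
* `auc_rank()`, `macro_auc()`, `cross_validate_ensemble()`,
  `run_beat_length_sweep()`, `export_attention()`;
* `load_ptbxl_metadata()` and friends — an optional loader for a local
  PTB-XL v1.0.1 directory (WFDB format-16 signals, six annotation levels,
  recommended folds). Nothing is downloaded.

The reference configuration (`model_config()`) instantiates the full-width
model — 569,373 trainable parameters, with the attention dimension (55) and
classifier width (25) fixed against that budget by
`scripts/resolve_budget.R`.

## Worked example

```r
library(beatfuse)

# a 3-class synthetic task at 20 dB SNR
mix <- c(NORM = 0.34, `ST-shift` = 0.33, `wide-QRS` = 0.33)
train_rec <- synthesize_dataset(600, mix, synth_spec(snr_db = 20), seed = 101)
test_rec  <- synthesize_dataset(200, mix, synth_spec(snr_db = 20), seed = 202)

# full pipeline: R-peak detection -> segmentation -> masked beat stacks
tr <- model_data(train_rec, "beatfusion")
te <- model_data(test_rec,  "beatfusion")
cls <- c("NORM", "ST-shift", "wide-QRS")
tr$y <- tr$y[, cls]; te$y <- te$y[, cls]

model <- build_model("beatfusion", small_model_config(n_classes = 3), seed = 1)
model <- fit(model, tr,
             train_config(batch_size = 64, learning_rate = 1e-3,
                          epochs = 5, seed = 1),
             val_data = te, verbose = TRUE)
#> epoch   1  loss 1.9450  val macro-AUC 0.8291
#> epoch   2  loss 1.5477  val macro-AUC 0.9839
#> epoch   3  loss 1.0507  val macro-AUC 1.0000
#> epoch   4  loss 0.5508  val macro-AUC 1.0000
#> epoch   5  loss 0.1979  val macro-AUC 1.0000
```

The per-epoch line shows the training loss (BCE + L2) falling while the
held-out macro-AUC — the mean over the three one-vs-rest rank AUCs —
reaches 1.0: the three synthetic morphologies are separable by
construction, so a correctly wired pipeline should solve the task within a
few epochs. Attention weights for a single record align with its detected
beats:

```r
ea <- export_attention(model, test_rec[[1]])
head(ea, 3)
#>   beat_index peak_sample start_sample     weight
#> 1          1          43           18 0.07904693
#> 2          2         130          105 0.06282727
#> 3          3         212          187 0.10415177
```

On records where only a minority of beats carry the abnormal morphology,
trained models concentrate weight on those beats (about 0.2 vs 0.03 in the
packaged experiments) — the interpretability property the beat-level design
exists for.

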