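# spectrogan

Adversarial synthesis of EEG spectrograms for epileptic seizure
prediction, as a tested R framework.

Good pre-ictal EEG is scarce: seizures are rare events, long-term
recordings are costly, and datasets are dominated by interictal time. One
line of work addresses this by *generating* pre-ictal data — train a deep
convolutional generative adversarial network (DCGAN) on spectrogram images
of real EEG, screen the synthesized samples with a one-class SVM, and ask
whether a classifier trained on synthetic data predicts real seizures.
`spectrogan` implements that entire experimental loop for researchers who
want to study the protocol itself: every stage is a tested, configurable
function, and a built-in signal simulator makes the whole pipeline
runnable end to end on one CPU with no data downloads.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic EEG (segments + seizure timelines) | `sim_config()`, `sim_preset()`, `simulate_segment()`, `simulate_dataset()`, `simulate_timeline()` |
| Spectrogram images (notch filter, STFT, resize) | `preprocess_config()`, `remove_line_noise()`, `stft_channel()`, `assemble_image()`, `preprocess_dataset()` |
| DCGAN synthesis | `build_gan()`, `train_gan()`, `sample_gan()`, `d_loss()`, `g_loss()`, `early_stop_index()` |
| One-class SVM screening | `selector_config()`, `featurize()`, `fit_ocsvm()`, `filter_samples()` |
| CESP classifier | `cesp_config()`, `build_cesp()`, `train_cesp()`, `predict_cesp()` |
| Evaluation protocol | `run_regime_matrix()`, `segment_metrics()`, `alarm_evaluate()`, `chance_probability()`, `chance_pvalue()`, `chance_test()`, `hanley_mcneil_compare()`, `roc_report()` |

The models follow the published architecture: the generator maps a
100-dimensional Gaussian latent vector through a 4096-unit dense layer
(reshaped to 4×4×256) and six stride-2 5×5 transposed convolutions to a
256×256×3 tanh image; the discriminator stacks four stride-2 5×5
convolutions (256/128/64/32 filters) into a sigmoid score; the CESP
("convolutional epileptic seizure predictor") uses three conv–ReLU–maxpool
blocks (126/64/64 filters) and 32/2-unit sigmoid heads. Training uses Adam
(GAN: lr 1e-3, beta1 0.5, batch 32; CESP: lr 1e-4, 10-fold stratified CV)
with the k = 15 consecutive-violation early-stopping rule on the GAN loss
monitors. Quarter-scale "desk" configurations (64×64 images) make CPU
experimentation practical. Since no deep-learning framework is assumed,
the package carries its own small conv-net engine (R orchestration,
single-precision im2col/GEMM convolutions in C++), validated against
finite differences in the test suite.

Evaluation covers both levels reported in this literature:
segment-level (sensitivity/specificity/accuracy/AUC under the
TRTR/TSTR/TRTS/TSTS train-test regime matrix with time-disjoint splits)
and event-level (alarms under a 10-min seizure prediction horizon and
30-min occurrence period, false predictions per interictal hour, and the
binomial chance-predictor test `P = 1 - exp(-FPR·SOP)`,
`p = Σ_{k≥n} C(N,k) P^k (1-P)^{N-k}`).

## Worked example

```r
library(spectrogan)

cfg  <- sim_preset("desk", seed = 1)                      # 8 ch, 256 Hz, 8 s
segs <- simulate_dataset(cfg, n_per_class = 200)
pc   <- preprocess_config(window_s = 1, out_size = 64, line_freq = 60)
imgs <- preprocess_dataset(segs, pc)

# train the quarter-scale DCGAN on the pre-ictal training portion
pre  <- Filter(function(im) im$label == "preictal", imgs[1:300])
gan  <- build_gan(generator_config_desk(), discriminator_config_desk(),
                  out_size = 64, class_label = "preictal", seed = 1)
gan  <- train_gan(gan, pre, max_epochs = 40, seed = 1)

# screen synthetic samples and run the regime matrix
fake <- sample_gan(gan, 200, seed = 2)
keep <- filter_samples(fit_ocsvm(pre, selector_config()), fake)
keep$acceptance_rate
#> [1] 0.485
tab  <- run_regime_matrix(imgs, keep$accepted,
                          cesp_config(lr = 1e-3, epochs = 5, seed = 1))
tab[, c("regime", "n_train", "n_test", "accuracy", "auc")]
#>   regime n_train n_test accuracy auc
#> 1   TRTR     300    100     1.00   1
#> 2   TSTR     300    100     0.79   1
#> 3   TRTS     300     74     1.00   1
#> 4   TSTS     300     74     1.00   1
```

Training on real data (TRTR) separates the simulated classes perfectly,
and a model trained only on screened GAN output plus real interictal data
(TSTR) ranks the held-out real test set just as well (AUC 1.0) — the
train-on-synthetic/test-on-real logic the framework exists to probe. The
lower TSTR accuracy at the fixed 0.5 cutoff shows the usual calibration
shift of models trained on synthetic data, which is why
`predict_cesp()` also returns a pairwise-normalized score for alarm
thresholds. Event-level scoring then works off a simulated timeline:

```r
tl <- simulate_timeline(cfg, duration_h = 10, n_seizures = 4)
pr <- predict_cesp(attr(tab, "models")$synthetic,
                   preprocess_dataset(tl$segments, pc))
ev <- alarm_evaluate(tl, data.frame(t_start = tl$segment_index$t_start,
                                    score = pr$p_normalized), alarm_config())
chance_test(ev, sop_min = 30)   # binomial tail vs a random alarm process
```

A thin command-line front end over the same functions is installed at
`inst/cli/spectrogan.R` (subcommands `simulate`, `preprocess`,
`train-gan`, `generate`, `select`, `train-cesp`, `evaluate`,
`chance-test`, `compare-auc`).

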