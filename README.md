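# visreason

Same–different (SD) versus spatial-relation (SR) visual reasoning, from
pixels to EEG statistics, in one tested R package.

Two judgments on the same stimulus — *are these two shapes aligned more
horizontally or vertically?* (SR) versus *are they the same shape?* (SD)
— sit on opposite sides of a well-known dichotomy for feedforward
networks: convolutional networks learn SR rules that transfer to novel
shapes but fail to generalize SD beyond the training items, unless the
items are segmented into separate channels (a Siamese "segmentation
oracle"). In humans the two tasks, equated for difficulty by an adaptive
staircase, differ in their electrophysiology: larger late evoked
potentials over centro-parietal sensors and stronger induced low-beta
(16–24 Hz) oscillations over occipito-parietal sensors in SD. This
package implements the full computational chain behind those claims:

* **`hexominoes`** — exhaustive enumeration of the 35 free hexominoes
  (6-cell polyominoes up to rotation/reflection), canonical forms, and
  the 30/5 train/test dictionary split.
* **`stimulus_geometry`** — pair placement at distance 2ρ along a
  ±45° diagonal rotated by a signed offset θ, shared jitter, SD/SR
  ground-truth labels, and binary 50×80 rendering.
* **`network_experiments`** — the six-conv-layer CNN (four 2×2 channels,
  stride-1 conv and pooling, two 128-unit dense layers, dropout 0.3,
  binary cross-entropy, Adam, batch 50, early stop at 90% validation)
  and its Siamese variant, implemented from scratch in C++/Armadillo,
  plus the repeated-split generalization experiment.
* **`quest_behavior`** — a QUEST-style Bayesian staircase with Weibull
  observers reproducing the alternating 16×70-trial session that holds
  accuracy at 80% by adjusting ρ (SD blocks) or θ (SR blocks).
* **`eeg_synth`** — synthetic multichannel EEG epochs (1/f background,
  alpha, shared evoked response) with injectable SD-specific ERP and
  16–24 Hz induced-power effects, plus a lossless binary epoch
  container.
* **`erp_pipeline`** — baseline-subtracted ERPs, pointwise t tests of
  the SD−SR difference on the seven midline electrodes, and
  Benjamini–Hochberg FDR correction.
* **`tf_pipeline`** — complex Morlet wavelet power (1–50 Hz log-spaced,
  1–20 cycles), dB baseline against the pre-fixation window,
  all-electrode condition-difference maps, cluster-based permutation
  statistics (|t| > 3.5 threshold, cluster mass, 500 sign-flip
  permutations) and within-cluster effect sizes (d = t/√n).
* **`run_pipeline()`** and `inst/cli/visreason.R` — staged orchestration
  with config-hashed manifests and a report assembling all panels.

The core statistic at the end of the chain is the cluster-mass
permutation test: pointwise one-sample t values of the per-subject
SD−SR dB maps are thresholded at |t| > 3.5, 4-connected clusters are
scored by their mass Σt, and each observed mass is referred to the null
distribution of the maximum |mass| under random per-subject sign flips
— exact label exchange for a paired design; the minimum attainable
p-value with 500 permutations is 1/501 ≈ 0.002.

## A worked example

```r
library(visreason)

dict <- enumerate_free_hexominoes()
dict
#> <hexomino_set> 35 free shapes of 6 cells

split <- split_dictionary(dict, n_test = 5, seed = 1)
cfg <- network_config(learning_rate = 1e-3, epochs = 15)

## the spatial-relation task: learned and generalized almost immediately
sr <- visreason:::make_task_datasets("SR", dict, split, 1000, 1000, 1000, 7)
m_sr <- train_model(build_cnn(cfg, seed = 7), sr$train, sr$val)
tail(m_sr$history, 1)
#>   epoch      loss train_acc val_acc
#> 1     1 0.2086392     0.927   0.988
evaluate_model(m_sr, sr$test)$accuracy
#> [1] 0.984

## the same network on same-different: held-out shapes stay at chance
sd <- visreason:::make_task_datasets("SD", dict, split, 1000, 1000, 1000, 7)
m_sd <- train_model(build_cnn(network_config(learning_rate = 1e-3,
                                             epochs = 15, stop_at_val = 1.1),
                    seed = 7), sd$train, sd$val)
evaluate_model(m_sd, sd$test)$accuracy
#> [1] 0.491
```

One epoch takes the CNN to 98% on spatial relations, including shapes it
never saw in training; fifteen epochs on same-different leave held-out
shapes at 49% — chance for a balanced binary task. The Siamese variant
(`build_siamese()`: items fed separately, feature difference classified)
closes that gap, and `run_dichotomy_experiment()` runs all three
conditions over repeated random dictionary splits.

On the EEG side:

```r
post <- subset(eeg_montage(), label %in% c("P3", "P1", "Pz", "P2", "P4",
                                           "PO3", "POz", "PO4", "O1",
                                           "Oz", "O2", "CPz"))
ep   <- synthesize_epochs(n_subjects = 14, trials_per_condition = 100,
                          montage = post, seed = 1)
spec <- wavelet_spec(n_freqs = 12, f_range = c(4, 40), sfreq = 256)
maps <- condition_diff_maps(ep, spec, decim = 8)
res  <- cluster_permutation_test(maps, cluster_config(seed = 1))
res
#> <tf_stat_result> 12 x 76 t-map, 4 cluster(s), min p 0.002
#>   id sign n_cells       mass           p     f_lo     f_hi   t_lo    t_hi
#> 3  3    1      67 802.172356 0.001996008 14.04477 26.31733  0.525  1.4000
#> 4  4    1      11  61.796092 0.001996008  4.00000  4.00000  0.650  0.9625
#> ...
round(unlist(cluster_effect_size(maps, res$sig_mask)[c("t", "p", "d")]), 4)
#>       t       p       d
#> 16.5809  0.0000  4.4314
```

The dominant cluster sits in the injected low-beta band during the
post-stimulus window (times are epoch time; the stimulus appears at
0.35 s, so 0.525-1.4 s spans the injected 250-950 ms effect with wavelet
smearing); the small 4 Hz cluster is the low-frequency power of the
SD-only evoked deflection, which the generator also injects.
`cluster_effect_size()` reports the one-sample t, p and Cohen's d of the
subject means inside the significant region.

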