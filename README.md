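# PatchAL

Pool-based deep active learning for binary histopathology patch
classification, built for the setting where unlabeled patches are
plentiful and every label costs expert time. PatchAL trains a conditional
VAE-GAN backbone — encoder *E*, class-conditioned generator *G*,
discriminator *D* and dropout classifier *M* — jointly under the
composite objective

    L = L_C + L_D + λ1·L_KL + λ2·L_G + λ3·L_GD + λ4·L_GC

and then iterates the active-learning loop: draw a candidate batch from
the unlabeled pool D_U, score each candidate by

* **BALD** mutual information via Monte Carlo dropout,
  `unc = H(mean_t p_t) − (1/T) Σ_t H(p_t)`,
* **diversity**, the entropy of softmaxed z-scored distances from the
  candidate's latent code to the labeled pool's class centroids
  (largest in the disagreement region between classes), and
* their min–max-scaled combination
  `score = θ·S(unc) + (1−θ)·S(div)`,

select the top *n*, query a (simulated) oracle, reconstruct the selected
samples through `G(E(x*), y*)`, fold originals **and** reconstructions
into the labeled pool D_L, and retrain. Reconstructions cost no labels,
so every learning curve is keyed by the fraction of oracle-labeled
originals. Baseline arms (random, predictive entropy, least confidence,
BALD with and without reconstruction) share the same loop for
comparisons.

Everything runs at desk scale on one CPU: a bundled synthetic generator
produces two-class histology-like patches (pink eosin-style background,
dark nucleus-like blobs whose density encodes the class), with
invalid-image screening, exact 8-fold dihedral (D4) augmentation,
count-preserving Gaussian noise, and stratified splitting. Evaluation
tools cover confusion-table metrics, rank-based AUC, learning curves,
convergence fractions, strategy comparison tables and classical MDS
embeddings of classifier features.

## Worked example

```r
library(PatchAL)

cfg <- syntheticConfig(nPositive = 570, nNegative = 430, patchSize = 32, seed = 1)
ds  <- generateDataset(cfg)
ds  <- screenInvalid(ds)$valid
ds  <- stratifiedSplit(ds, trainRatio = 0.7, seed = 2)
train <- ds[sampleSplits(ds) == "train"]
test  <- ds[sampleSplits(ds) == "test"]
train
#> ImageSet with 700 samples ( 32x32 pixels )
#>   labels:     negative=301 positive=399
#>   splits:     train=700
#>   provenance: real=700

run <- runActiveLearning(
  loopConfig(strategy = "combined",
             acquisition = acquisitionConfig(poolSize = 200, nSelect = 15,
                                             T = 10, theta = 0.5),
             maxIterations = 5, seed = 7),
  train, test)
run
#> ActiveRun: 5 iterations, strategy combined
#>   oracle queries: 75
#>   final: |D_L| = 220, accuracy = 0.8133, recall = 0.7076, AUC = 0.9206

round(runHistory(run)[, c("iteration", "n_labeled", "n_labeled_originals",
                          "labeled_fraction", "accuracy", "recall", "auc")], 4)
#>   iteration n_labeled n_labeled_originals labeled_fraction accuracy recall    auc
#> 1         1       100                  85           0.1214   0.5200 0.1579 0.9154
#> 2         2       130                 100           0.1429   0.4300 0.0000 0.9240
#> 3         3       160                 115           0.1643   0.6767 0.4327 0.9149
#> 4         4       190                 130           0.1857   0.7767 0.6257 0.9136
#> 5         5       220                 145           0.2071   0.8133 0.7076 0.9206
```

Reading the trace: the loop starts from a 10% stratified pool (70
originals; |D_L| = 100 after the first iteration because the generative
arm adds 15 originals *and* 15 reconstructions per round while
`n_labeled_originals` counts only the 15 oracle queries). Accuracy climbs
as labels accumulate — from near-chance thresholding at a 12% labeled
fraction to 0.81 at 21% — while the ranking quality (AUC ≈ 0.92) is
already high early, a typical signature of a small dense classifier
whose decision threshold calibrates later than its ordering. With a
full-training reference accuracy, `buildLearningCurve()` plus
`convergenceFraction()` report the smallest labeled fraction that matches
full-data training within a tolerance.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/patchal.R synth --n-positive 570 --n-negative 430 \
    --patch-size 32 --seed 1 --out data/synth
Rscript inst/cli/patchal.R run --config config.yaml --strategy combined \
    --theta 0.5 --n-select 100 --max-iter 100 --seed 7 --out runs/combined
Rscript inst/cli/patchal.R report --runs runs/combined,runs/random --out report
```

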