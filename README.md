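# ecmlse

Sequence-based prediction of extracellular matrix (ECM) proteins by latent
space encoding of k-spaced amino acid pair compositions.

ECM proteins form the cross-linked macromolecular network that fills the
extracellular space of metazoan tissues; telling them apart from other
secreted proteins matters for studying tissue architecture and diseases
such as fibrosis, arthritis and cancer. Experimental annotation is slow,
and the available positive class is small (hundreds of sequences against
thousands of non-ECM secretory proteins), so the problem is a heavily
imbalanced binary classification from sequence alone. This package is for
computational biologists who want a self-contained, reproducible
implementation of the CKSAAP + latent-space-encoding approach, including
its full evaluation protocol.

## Method

**Encoding.** A protein sequence over the 20 canonical residues is encoded
by the composition of k-spaced amino acid pairs (CKSAAP): for each gap
j = 0, 1, ..., k the 400 ordered residue pairs (AA, AC, ..., YY) separated
by exactly j intervening residues are tallied and the block is normalized
by its number of valid pairs, giving a feature vector of length
(k + 1) × 400. The j = 0 block is the classical dipeptide composition
(DPC); larger gaps capture longer-range pairwise sequence structure.

**Model (DeepLSE).** The feature vector x ∈ R^((k+1)·400) is compressed by
an encoder (hidden widths 50 and 10, each with batch normalization, ReLU
and 30 % dropout) into a sigmoid latent vector z ∈ (0,1)^LV with no
normalization or dropout. Two heads share z:

* a mirror-symmetric decoder reconstructing x̂ (reconstruction loss
  ‖x − x̂‖² / dim), and
* a classifier (three ReLU layers of 10 units and a 2-unit softmax) giving
  class scores p(ECM | x).

Training jointly minimizes
`w_cls · CE(y, p) + w_rec · MSE(x, x̂)` with Adam, early-stopping on
validation balanced accuracy. Forcing the same bottleneck to serve
reconstruction and discrimination yields a latent space in which the two
classes form separable clusters — directly plottable when LV = 2 via
`embed()`.

**Protocol.** Trials draw a balanced training set (270 + 270 on the
benchmark-sized pool of 445 ECM / 3,327 non-ECM), a 30 + 810 validation
set, and test on the 145 + 2,247 remainder. Each configuration is trained
over repeated randomized trials (20 by default); only models reaching 75 %
validation balanced accuracy are aggregated. The (k, LV) ablation grid
over k = 0..10 and LV = 2..9 (88 configurations, 1,760 trials) selects the
operating point by mean test balanced accuracy. Reported statistics are
the imbalance-robust set: sensitivity, specificity, balanced accuracy,
Youden's index, MCC and F1.

## Worked example

Every stage runs without downloads via the synthetic generator, which
plants a chosen residue pair at a chosen gap in the positive class (and
marginal-matched decoy residues in the negatives, so only the k-spaced
co-occurrence separates the classes):

```r
library(ecmlse)

fx <- benchmark_fixture()        # 100 ECM / 600 non-ECM, pair C-K at gap 3
summary <- run_trials(
  fx$records, cksaap_config(k_max = 3),
  model_options = list(latent_dim = 3L),
  splits = split_spec(train_pos = 70, train_neg = 70,
                      val_pos = 15, val_neg = 60),
  n_trials = 3, filter_threshold = 0.75, base_seed = 11)

summary$n_selected
#> [1] 3
round(summary$mean[c("sensitivity", "specificity", "balanced_accuracy", "mcc")], 3)
#>       sensitivity       specificity balanced_accuracy               mcc
#>             0.956             0.999             0.977             0.954
round(summary$sd[c("sensitivity", "specificity", "balanced_accuracy", "mcc")], 3)
#>       sensitivity       specificity balanced_accuracy               mcc
#>             0.038             0.001             0.019             0.020
```

All three trials pass the validation filter; the mean test balanced
accuracy of 0.977 (over the 15 ECM / 470 non-ECM test remainders) shows
the encoder + latent-space classifier recovering the planted gap-3 signal
almost perfectly, with chance-level performance expected (and tested) when
no signal is planted.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ecmlse.R simulate --out-prefix data/sim --n-pos 100 --n-neg 600 --gap 3 --seed 1
Rscript inst/cli/ecmlse.R train --fasta data/sim.fasta --labels data/sim.labels.tsv \
    --out-dir runs/demo --k 3 --lv 3 --trials 3 --seed 11
Rscript inst/cli/ecmlse.R predict --model runs/demo/model.rds --fasta data/sim.fasta \
    --out runs/demo/pred.tsv
```

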