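# protpath

Missense-variant pathogenicity prediction from protein sequence, for
researchers who have labeled mutant sequences (e.g. from functional
assays or clinical databases) and a corpus of related domain sequences,
but no structural data and no annotation-based priors.

## The model

A mutant protein sequence is represented two complementary ways and the
representations are fused:

1. a **masked-language-model transformer encoder**, pre-trained from
   scratch on a protein domain family corpus (each amino acid is a
   token over a 20-word dictionary plus terminator), pools the sequence
   into a fixed-dimension contextual embedding
   `emb_x ∈ R^d` (default d = 768);
2. a **Kyte–Doolittle hydropathy encoding** maps each residue to its
   hydropathy value (Ile = 4.5 … Arg = −4.5), zero-padded to the
   encoder's maximum length: `hy_x ∈ R^{d_Hy}`.

The concatenation feeds a one-hidden-layer perceptron

```
h  = ReLU(W¹ [emb_x, hy_x] + b¹)
ŷ  = sigmoid(w² · h + b²)
```

trained with binary cross-entropy against benign (0) / pathogenic (1)
labels. Attention is `softmax(QKᵀ/√d_k)V` with multi-head projections;
pre-training is the canonical 15% / 80-10-10 masking recipe. Evaluation
ships ROC/PR curves with oracle-verifiable AUROC (trapezoid =
Mann–Whitney concordance) and AUPR (average precision).

The package also contains the surrounding tooling: FASTA ingestion and
cleaning, corpus/vocabulary files, class-imbalance augmentation
(terminator-noise copies, truncated wild-type negatives), stratified
5/4/1 fine-tune/train/test splitting that keeps augmented records out
of the test set, a synthetic-data simulator with a plantable
pathogenicity signal, and a command-line pipeline
(`inst/cli/protpath.R`).

## Worked example

Desk scale, one CPU, ~3 minutes (the `tiny` profile: 2 layers, 64
hidden units, 4 heads, 64-token window):

```r
library(protpath)

# a synthetic conserved domain family: 500 training members + 100 held out
fam <- generate_family(family_spec(n_sequences = 600, seed = 11))
vocab <- build_vocabulary()
cfg <- encoder_profile("tiny", vocab_size = vocab$size)
corpus <- tokenize_corpus(fam[1:500, ], vocab, max_len = cfg$max_len)

# pre-train the language model and score held-out masked prediction
lm <- protein_lm(corpus, cfg, steps = 2000, batch_size = 16, seed = 22)
heldout <- tokenize_corpus(fam[501:600, ], vocab, max_len = cfg$max_len)
evaluate_mlm(lm, heldout, seed = 33)
#> [1] 0.9744444

# labeled mutants: pathogenic = hydropathy flips at conserved positions
muts <- generate_mutation_set(fam, mutation_set_spec(seed = 101))
fit <- fusion_classifier(muts, encoder = lm, variant = "full",
                         config = classifier_config(seed = 1))
fit
#> Fusion pathogenicity classifier (variant: full )
#>   features: 128, hidden: 512, epochs: 300, mode: feature_based
#>   held-out test: accuracy 0.875, AUROC 1.000, AUPR 1.000, F1 0.615

predict(fit, muts[1:3, ])
#>            id       score label
#> 1 mut0001_ben 0.008568038     0
#> 2 mut0002_ben 0.006606748     0
#> 3 mut0003_ben 0.012352075     0
```

The masked accuracy of 0.974 sits just under the generator's
predictability ceiling (~0.98, set by the family's conservation
structure). The ranking metrics saturate (AUROC/AUPR 1.0) because the
planted signal is strong by design, while the thresholded metrics are
lower: with a 1:3.65 class imbalance the scores of a well-ranking but
uncalibrated classifier sit below the default 0.5 cut for part of the
pathogenic class. `summary(fit)` prints the full held-out metric row
(accuracy, AUROC, AUPR, recall, precision, F1); `plot(fit)` draws the
held-out ROC curve.

## Command-line pipeline

```sh
Rscript inst/cli/protpath.R simulate     --config run.yaml --out-dir out
Rscript inst/cli/protpath.R build-corpus --config run.yaml --out-dir out \
        --fasta out/family.fasta
Rscript inst/cli/protpath.R pretrain     --config run.yaml --out-dir out
Rscript inst/cli/protpath.R train        --config run.yaml --out-dir out \
        --fasta out/mutations.fasta --labels out/labels.tsv \
        --encoder out/encoder.rds
```

Every stage writes a manifest (config snapshot, input checksums,
derived seed) from which it can be replayed exactly. See
`vignettes/methods.Rmd` for the model, its assumptions, the synthetic
data design and known limitations.
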