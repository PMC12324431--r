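# minscfg

Minimal stochastic context-free grammars (SCFGs) for RNA secondary
structure, trainable from **sequences alone**.

## The problem

RNA secondary structure — helices of nested Watson–Crick–Franklin
(A:U, G:C) and wobble (G:U) base pairs — is usually learned either
from curated structures, from alignments that expose covariation, or
by very large sequence models. This package implements the opposite
extreme: the two smallest probabilistic grammars that can describe
nested base pairing, and asks how much of the chemistry they can
rediscover from a few dozen plain RNA sequences.

It is aimed at computational RNA biologists and method developers who
want a transparent, fully inspectable baseline: every parameter has a
name and a meaning, training is exact gradient descent on the
marginal likelihood, and every dynamic program is validated against a
brute-force enumeration oracle in the test suite.

## The models and the method

**G6** (21 free parameters) has nonterminals S, L, F:

    S -> LS | L          with probability tS / 1-tS
    L -> aFb | a         with tL*pbp(a,b) / (1-tL)*ps(a)
    F -> aFb | LS        with tF*pbp(a,b) / 1-tF

`ps` is a 4-simplex over nucleotides, `pbp` a 16-cell simplex over
ordered pairs. `tL` prices *starting* a helix, `tF` *extending* one —
with `tL < tF` stacked helices are favoured over isolated pairs.
**G5** (20 parameters: `S -> aS | aSbS | eps`) has a single pairing
probability and therefore cannot express that preference; comparing
the two isolates helix aggregation as the decisive ingredient.

The marginal probability of a sequence, summed over all structures,
is computed by a log-space Inside algorithm (O(n³), the SCFG analogue
of McCaskill's partition function). Its exact gradient — the expected
rule-usage counts — comes from the companion Outside pass, so the
negative log-likelihood of a training set can be minimized by plain
SGD (defaults: learning rate 0.1, batches of 10, 100 epochs, uniform
initialization) **without structures or alignments**. Also included:
maximum-likelihood training from labelled structures, base-pair
posteriors, maximum-expected-accuracy (MEA) and CYK decoding,
sensitivity/PPV/global-F1 evaluation, composition-preserving
shuffling controls, and a generative sampler that draws
(sequence, structure) pairs from any parameterization.

## A worked example

```r
library(minscfg)

# ground truth: a structured-RNA-like G6 parameterization whose pbp
# holds 0.95 mass on the six canonical pairs, tL = 0.119, tF = 0.788
truth <- wcf_reference_params()

# 150 training sequences at natural structured-RNA lengths; only the
# *sequences* are used for training
train <- sample_from_grammar(truth, 150, seed = 421,
                             min_length = 100, max_length = 400)

fit <- sgd_train(train, grammar = "G6", epochs = 150, seed = 422)
fit$params
#> <scfg_params> grammar G6 (21 free parameters)
#>   tS = 0.7849  tL = 0.1651  tF = 0.8060
#>   ps : A 0.2393  C 0.2669  G 0.2481  U 0.2457
#>   pbp: 0.9062 of mass on the 6 canonical pairs
```

Starting from a uniform distribution over all 16 ordered pairs
(canonical mass 6/16 = 0.375), sequence-only SGD concentrates 0.91 of
the pair-emission mass on the six canonical pairs and recovers helix
aggregation: `tL` (helix start, 0.17) lands far below `tF` (helix
extension, 0.81), close to the generating values 0.119/0.788 — the
base-pairing rules emerge with no structure labels at all.

Downstream, the trained parameters predict structures for held-out
sequences, scored at base-pair level against the generative truth:

```r
test <- sample_from_grammar(truth, 100, seed = 425,
                            min_length = 100, max_length = 400)
pred <- predict_structures(test, fit$params, method = "mea")
evaluate_structures(pred, test)
#> # A tibble: 1 x 6
#>      tp    fp    fn sensitivity   ppv    f1
#>   <int> <int> <int>       <dbl> <dbl> <dbl>
#> 1  2544  1452  2998       0.459 0.637 0.533
```

F1 = 0.533 here is essentially the ceiling for this task: the
generative structure is a *sample* from the grammar, not its posterior
mode, and decoding the same test set with the true parameters scores
F1 = 0.536. (The shuffled-sequence control behaves differently from
the original large-step experiments under this package's conservative
optimizer — see the methods vignette for the full analysis.)

Fitted objects are broom-friendly (`tidy()`, `glance()`) and plot
themselves (`autoplot()` for loss curves, parameter bars, posterior
heat maps). A command-line interface wraps the same functions:

```sh
minscfg train  --mode sgd --fasta train.fa --epochs 100 --lr 0.1 \
               --batch 10 --seed 1 --out params.yaml
minscfg predict --fasta test.fa --params params.yaml --out pred.db
minscfg eval    --pred pred.db --true test.db
minscfg sample  --params params.yaml --n 200 --seed 7 --out sample.fa
minscfg shuffle --fasta train.fa --seed 3 --out shuffled.fa
```

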