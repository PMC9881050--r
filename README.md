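# targetlr

Genome-wide prediction of therapeutic targets for protein and peptide
drugs.

Protein and peptide drugs (antibodies, recombinant proteins, therapeutic
peptides) bind a characteristically different slice of the proteome than
small molecules: their known targets are enriched for signal peptides,
transmembrane regions, signaling molecules and high centrality in the
signal-transduction network, and depleted for housekeeping genes.
`targetlr` turns such class-conditional differences into a genome-wide
ranking: it computes sequence, expression, polymorphism, annotation and
network features for every protein, ranks features by minimum-redundancy
maximum-relevance (mRMR) mutual information, and fits a likelihood-ratio
naive Bayes classifier. It is aimed at computational biologists
prioritizing candidate targets from disease-related protein lists, and at
methodologists who want a fully synthetic, reproducible benchmark of the
approach.

## The model

Per feature `f`, the evidence weight is the likelihood ratio

    LR(f) = P(f | target) / P(f | non-target) = (TP_f / T) / (FP_f / F)

estimated per bin from a gold standard of `T` positives and `F` negatives
(optionally smoothed by a pseudocount α). Under naive Bayes the combined
score of a protein is the product of its per-feature LRs,

    LR(f1...fn) = Π LR(fi),

which is proportional to the posterior odds of being a target because the
prior odds are constant across the genome; the combined LR is used
directly as the prediction score. Negatives are re-sampled 100 times and
every reported statistic is a mean ± SD over replicates. See the vignette
(`vignettes/target-prediction.Rmd`) for the full model, feature
definitions and design decisions.

## Worked example

Simulate a genome with planted target structure, build the feature
matrix, rank features, cross-validate and score:

```r
library(targetlr)

genome <- simulate_genome(genome_config(n_proteins = 1000,
                                        n_positives = 60, seed = 19))
feats <- assemble_feature_matrix(genome$sequences, genome$expression,
                                 genome$annotations, genome$networks)
gold <- gold_standard(genome$positives, rownames(feats),
                      size = 60, n_replicates = 20, seed = 23)
ranking <- mrmr_rank(feats, gold)
head(as.data.frame(ranking), 6)
#>   rank            feature  relevance redundancy
#> 1    1 signaling_molecule 0.39152795         NA
#> 2    2      degree_signal 0.03409839 0.00000000
#> 3    3     reaction_count 0.19854775 0.03924486
#> 4    4      pathway_count 0.12595011 0.03022219
#> 5    5     signal_peptide 0.36460418 0.07497642
#> 6    6            charged 0.17875792 0.04498523

cross_validate(feats, gold, ranking = ranking, k_features = 6, seed = 29)
#> 10-fold CV, 6-feature model: AUC = 0.9894 +/- 0.0051 (20 replicates)

fit <- target_lr(feats, gold$positives, gold$negatives[[1]],
                 ranking = ranking, n_features = 6)
head(predict(fit, feats), 5)
#>   protein_id combined_lr rank grade known
#> 1     P00004    27172.51    1  high  TRUE
#> 2     P00031    27172.51    2  high  TRUE
#> 3     P00032    27172.51    3  high  TRUE
#> 4     P00042    14601.49    4  high  TRUE
#> 5     P00026    12438.30    5  high  TRUE
```

`relevance` is the mean mutual information (bits) between a feature and
the class label over the negative replicates; `redundancy` the mean MI
with already-selected features. The cross-validated AUC of 0.989 ± 0.005
says that on this synthetic genome the six selected features nearly
separate planted targets from background. In the prediction table,
`combined_lr` is the product of per-feature likelihood ratios (a score of
27 172 means the feature evidence multiplies the prior odds by ~2.7e4),
`rank` is the genome-wide position and `grade` buckets scores by the
configurable cutoffs (`high` ≥ 100, `median` ≥ 1).

A thin command-line wrapper around the same functions ships in
`inst/cli/targetlr.R` (subcommands `simulate`, `train`, `predict`,
`evaluate`).

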