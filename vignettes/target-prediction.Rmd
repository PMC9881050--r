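---
title: "Predicting protein and peptide drug targets with likelihood-ratio naive Bayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein and peptide drug targets with likelihood-ratio naive Bayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetlr)
```

## The problem

Most approved drugs are small molecules, but protein and peptide drugs
(antibodies, recombinant proteins, therapeutic peptides) bind a
systematically different part of the human proteome. Given a set of known
therapeutic targets of approved protein or peptide drugs, the task is to
score every other protein in the genome for its likelihood of being a
viable target of that drug class. `targetlr` implements the full pipeline:
feature computation, feature selection, classification, and evaluation,
plus a synthetic genome generator so the whole pipeline can be exercised
and benchmarked without access to curated drug/annotation databases.

## The model

For a protein with feature values $f_1 \dots f_n$, Bayes' rule gives
posterior odds of being a target

$$O_{post} = O_{prior} \times LR(f_1 \dots f_n),$$

where the likelihood ratio of a single feature is

$$LR(f) = \frac{P(f \mid \mathrm{target})}{P(f \mid \mathrm{non\text{-}target})}
        = \frac{TP_f / T}{FP_f / F},$$

with $T$ and $F$ the numbers of gold-standard positives and negatives and
$TP_f$, $FP_f$ those of them exhibiting feature value $f$. Under the naive
Bayes independence assumption the combined evidence is the product

$$LR(f_1 \dots f_n) = \prod_{i=1}^{n} LR(f_i).$$

Because $O_{prior}$ is the same constant for every protein, the combined
LR is used directly as the prediction score; proteins are ranked by
decreasing score and assigned high / median / low confidence grades by
configurable cutoffs (defaults: combined LR $\ge 100$ high, $\ge 1$
median). These cutoffs are presentation thresholds only; they do not
affect ranking or AUC.

`fit_lr_table()` estimates per-bin LRs with an optional pseudocount
$\alpha$:

$$LR_b = \frac{(TP_b + \alpha)/(T + k\alpha)}{(FP_b + \alpha)/(F + k\alpha)},$$

where $k$ is the number of bins. $\alpha = 0$ reproduces the unsmoothed
ratio literally; the default $\alpha = 0.5$ (Jeffreys-style) keeps every
LR finite when a bin is empty in one class, which is essential when the
product of many features is taken. Continuous features are cut into five
equal-frequency bins computed on the pooled labeled training values; the
bin count is configurable. Binning is refitted inside every
cross-validation fold and for every negative replicate, so no information
leaks from held-out proteins.

Scores are accumulated in log space and returned in linear space; the test
suite verifies agreement of the two formulations to $10^{-9}$ relative
error, and that with $\alpha = 0$ and binary features the combined LR
equals the directly computed ratio of naive-Bayes class posteriors.

A missing feature value contributes $LR = 1$ (neutral evidence) at
prediction time, and proteins missing a feature are excluded from that
feature's LR fit. This keeps genome-wide scoring well defined when, for
example, a protein is absent from the signal-transduction network.

## The features

One row per protein, twelve binary annotation flags (signal peptide,
transmembrane region, signaling molecule, transcription factor,
housekeeping, self-interacting, enzyme, GPCR, ion channel, nuclear hormone
receptor, kinase, transporter) and twenty-seven continuous features:

* **Amino-acid class composition** — percentages of nine overlapping
  classes: tiny (A,C,G,S,T), small (A,B,C,D,G,N,P,S,T,V), aliphatic
  (A,I,L,V), aromatic (F,H,W,Y), nonpolar (A,C,F,G,I,L,M,P,V,W,Y), polar
  (D,E,H,K,N,Q,R,S,T,Z), charged (B,D,E,H,K,R,Z), basic (H,K,R), acidic
  (B,D,E,Z). The ambiguity codes B (Asp/Asn) and Z (Glu/Gln) belong
  exactly to the classes listed.
* **GRAVY** — mean Kyte–Doolittle hydropathy.
* **Charge** — summed residue charges in the pepstats convention
  (K,R = +1; H = +0.5; D,E = −1; B,Z = −0.5; termini ignored).
* **Theoretical pI** — the pH at which the Henderson–Hasselbalch net
  charge (Bjellqvist pKa set, both termini, N-terminal pKa
  residue-specific) is zero, found by bisection on [0, 14] to a charge
  tolerance of $10^{-3}$. For ionization B maps to D, Z to E; X and U are
  treated as non-ionizable.
* **PEST motif count** — candidate regions are maximal stretches strictly
  between positively charged residues (K/R/H) or the termini, at least 10
  residues long, containing at least one P, one of D/E and one of S/T.
  Each candidate is scored
  $0.55 \cdot \mathrm{DEPST} - 0.5 \cdot \mathrm{HI}$, where DEPST is the
  mass percentage of D/E/P/S/T residues and HI the mass-weighted mean of
  the Kyte–Doolittle scale mapped onto $10 \cdot KD + 45$; candidates
  scoring $\ge 5$ are counted as "potential" motifs. Published variants of
  PEST scoring differ in details; the constants are isolated in one table
  (`PEST_CONSTANTS`) so the rule can be recalibrated, and the tests pin
  the chosen rule with independently hand-computed scores.
* **Disorder score** — per-position fold index
  $2.785\langle H\rangle - |\langle R\rangle| - 1.151$ over a centered
  51-residue window truncated at the termini, with $\langle H\rangle$ the
  mean hydropathy rescaled to [0, 1] and $\langle R\rangle$ the mean
  residue charge (K,R = +1, D,E = −1). Maximal runs of negative index of
  length $\ge 30$ count as disordered; the score is their summed length
  divided by the protein length. The ≥ 30 cutoff suppresses short spurious
  segments.
* **TSPS** (tissue specificity) —
  $\sum_i f_i \log_2(f_i/p)$ over tissues, with $f_i$ the gene's
  expression fraction in tissue $i$ and $p = 1/n$; 0 for uniform
  expression and $\log_2 n$ for single-tissue expression. Zero tissues
  contribute 0.
* **Housekeeping** — detected (value strictly above a configurable
  threshold, default 0) in all tissues. The detection cutoff of the
  original RNA-seq processing is not published, hence configurable.
* **C_ratio** — $(N_{ns} + \varepsilon)/(N_s + \varepsilon)$ with
  nonsynonymous/synonymous SNP counts and $\varepsilon = 0.01$ guarding
  small counts.
* **Network centralities** — degree (distinct partners; a self-loop marks
  self-interaction instead of contributing to degree) and normalized
  betweenness
  $B(n) = 2 \sum_{s \ne n \ne t} [\sigma_{st}(n)/\sigma_{st}] / ((N-1)(N-2))$
  in the undirected PPI and signal-transduction networks, plus in/out-degree
  in the directed TF→target network. Shortest paths are unweighted (BFS);
  disconnected pairs contribute 0. The betweenness implementation is
  cross-checked against exhaustive shortest-path enumeration on random
  graphs in the test suite.
* **Consumed as inputs** — domain count, protein age class (1–16),
  evolutionary rate, reaction and pathway counts come from the annotation
  table; the package does not re-derive them from primary databases, and
  likewise reads signal peptide/transmembrane flags rather than predicting
  them from sequence.

## Gold standards and feature selection

The positive set is the non-redundant known-target set: a greedy pass in
lexicographic id order drops any protein with global Needleman–Wunsch
identity (BLOSUM62, gap open/extend 10/0.5; identity = matches / alignment
columns) above 40% to an already-kept protein. The alignment order is not
part of the published protocol; lexicographic order makes the result
deterministic and idempotent.

Negatives are drawn uniformly without replacement from the genome minus
every known or possible target, 100 proteins per replicate, 100 replicates
with per-replicate seeds derived from one master seed. Uniform sampling is
assumed (the weighting of the original construction is unstated). All
downstream quantities (MI terms, CV AUCs) are computed per replicate and
averaged, reported as mean ± SD.

mRMR ranks features greedily: the first feature maximizes the mean mutual
information $I(f, c)$ with the class label; each later step maximizes the
quotient

$$\max_{f_j \in T} \frac{I(f_j, c)}{\frac{1}{|S|}\sum_{f_i \in S} I(f_j, f_i)},$$

with all MI terms averaged over the negative replicates. MI is the plug-in
discrete estimator in bits; continuous features are discretized into three
states at mean ± SD of the labeled values (the convention of the classic
mRMR implementation; the original discretization is unpublished, so the
scheme is configurable). Decisions the quotient form leaves open are fixed
as follows: the first step uses pure relevance (the denominator is
undefined at $|S| = 0$); a zero denominator at later steps is treated as
$+\infty$ (its limit), with relevance and then feature name breaking ties;
all other ties break lexicographically. The ranking is verified against an
independent exhaustive implementation on random fixtures.

## Evaluation

AUC is computed as the Mann–Whitney rank statistic (ties credited 0.5),
verified against brute-force pair counting. Cross-validation is stratified
10-fold per negative replicate with LR tables refitted per fold; the
replicate's AUC pools the held-out scores rather than averaging per-fold
AUCs, because with 100 positives a 10-positive fold gives an unstable ROC.
Independent tests fit one model per training replicate and evaluate it on
every test-negative replicate (a full grid), after verifying that training
and test positives are disjoint. Group comparisons use one-sided
Wilcoxon rank-sum tests (continuous) or one-sided Fisher's exact tests
(binary) in the direction observed in the data, with Benjamini–Hochberg
adjustment across features; one-sided P values are cross-checked against a
permutation oracle in the tests.

## The synthetic genome

`simulate_genome()` draws a genome-scale bundle in the same file formats
the analysis functions read, so tests exercise the parsers too. Defaults
are 5000 proteins with 100 positives, 32 tissues, and these
class-conditional mechanisms:

* binary flags are Bernoulli with the published target / non-target
  prevalences (e.g., signal peptide 84.85% vs 15.24%);
* tissue expression fractions are symmetric Dirichlet draws with
  concentration 0.35 (positives) vs 0.50 (negatives), calibrated to give
  group mean TSPS near the reported values (≈ 1.34 vs 0.95 at 32 tissues);
  non-housekeeping proteins get at least one zeroed tissue so the
  housekeeping flag is exactly recomputable from the expression matrix;
* the signal-transduction network is a preferential-attachment graph over
  the signaling-molecule proteins with positives assigned to node slots
  with probability proportional to (degree + 1)^2, elevating their degree
  and betweenness; the PPI network uses a milder exponent of 0.5;
  self-interacting proteins carry self-loops;
* TF indegree is Poisson with mean 7.48 (positives) vs 2.96 (negatives);
* sequences are residue-wise draws from a human-like composition, with
  the positive class tilted toward tiny/aromatic residues and away from
  basic ones, so sequence features separate weakly, as they do in real
  data;
* counts (domains, pathways, reactions, SNPs) use Poisson or
  negative-binomial families matching the reported group means in
  location and direction.

Where only group means and directions are reported, distribution families
were chosen once for positivity and realistic dispersion (log-normal,
Dirichlet, negative binomial); all parameters sit in `genome_config()`.
`genome_config(null = TRUE)` equalizes every class-conditional parameter,
giving the no-signal control.

What the generator does **not** emulate: homology structure beyond
optionally injected duplicates (sequences are compositionally random, so
the 40% identity filter is exercised on dedicated fixtures rather than on
the genome), realistic domain architecture or motif grammar, correlated
annotation errors, and the curatorial biases of real drug/target
databases. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted effects, not the published
performance numbers, which depend on curated database extracts that are
not redistributable here.

On the default configuration the full pipeline (features → mRMR →
6-feature model → repeated 10-fold CV) attains a mean AUC above 0.9, and
the null configuration stays within sampling error of 0.5; both are
recomputed by the test suite and by `scripts/acceptance.R`. Recovery of
per-feature LR tables is accurate for prevalent flags but binomially
limited for rare ones: a flag carried by ~3% of the 100 positives is
estimated from ~3 proteins, so its fitted odds ratio has ≈ 50% relative
sampling error no matter how large the genome is. This is a property of
the study size, and it is the main known limitation of desk-scale
benchmarking with this generator.

## Problem sizes and runtime choices

The test suite runs the full-scale default genome (5000 × 100) once for
the end-to-end checks and uses a shared 600-protein genome for module
tests; mRMR averaging uses all 100 negative replicates at full scale and
3–10 replicates in module tests. These sizes were chosen to keep the whole
suite in the low minutes on a single core while leaving every statistical
check adequately powered, with the exception noted above.

## Coordinates and conventions

Intervals (PEST motifs, disorder segments) are 0-based half-open
internally and in returned data frames; FASTA ids are the first
whitespace-delimited header token; TSV feature tables carry a `#kind:`
header line typing each column as binary or continuous so that
write/read round-trips are exact.
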