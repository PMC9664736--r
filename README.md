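# spliceoe

Regional constraint against aberrant splicing from population variation,
and a random-forest ensemble for prioritizing pathogenic splice-altering
variants.

## The problem

Most clinically interpretable splice variants sit at the canonical
donor/acceptor dinucleotides; cryptic splice-altering variants deeper in
introns and exons are routinely ignored, and per-variant splice
predictors alone underperform there. Purifying selection offers an
orthogonal signal: genomic regions where splice-disrupting variation is
deleterious show a *depletion* of such variants in large cohorts of
healthy individuals. `spliceoe` measures that depletion regionally and
combines it with per-variant splice predictions into a single
pathogenicity score.

## The model

**Substitution probabilities.** Population SNVs passing a strict filter
(PASS, AC ≥ 1, ≥ 10X coverage in ≥ 50% of samples, reference-matching,
inside merged protein-coding transcripts, scored, unmasked, absent from
the truth set) are tallied over every scored protein-coding site. Each
site carries a summed splice delta score, s = AG + AL + DG + DL ∈ [0, 4]
(the variant's own ref→alt score at variant sites, the max over the
three possible alternates elsewhere), discretized into 8 bins. Counts by
reference allele × score bin give 32 per-site substitution
probabilities p(ref, bin) and genome-wide cell proportions, separately
for autosomes and X (PARs excluded, Y dropped).

**Regional O/E.** Genes are tiled into windows (default 50 bp). For a
window, with per-cell observed variant counts O[i] and expected counts
E[i] (the sum of p over the window's nucleotides in cell i), after
adding a pseudocount of 1.0 to both sides:

    O/E = Σ_{i=1}^{32} X[i] · (O[i] − E[i]) / E[i]

where X[i] is a likelihood weight, by default 1/Proportion[i], which
up-weights the rare, splice-relevant cells. The statistic is 0 when
observed equals expected everywhere and goes negative under depletion.
Windows with fewer than 6.5415 informative sites (summed score > 0) or
under 80% score coverage are dropped; single-exon genes are shifted
toward tolerance. Raw O/E values are rank-normalized to a constraint
score in [0, 1], where 1 is the most constrained (most depleted) region.

**Ensemble.** A 1000-tree probability forest on the feature vector
\[constraint score, max splice delta score, max spliceosome-classifier
score\] yields a per-variant pathogenicity probability in [0, 1]
(suggested preliminary cutoff: 0.5). Training uses a region-grouped
60/40 split (no constraint region straddles train and test) with
stratified, group-aware 5-fold cross-validation, and is evaluated with
precision–recall curves, step-sum average precision and per-decile
odds-ratio enrichment with 95% CIs.

A synthetic-data generator (`simulate_bundle()`) emulates all inputs —
genes on both strands, junction-peaked score tracks, population variants
with a tunable depletion factor at splice-relevant sites of constrained
genes, coverage, masks, and labeled truth sets — so the whole pipeline is
testable without population-scale downloads.

## Worked example

```r
library(spliceoe)

bundle <- simulate_bundle(simulation_config(seed = 42))
fit <- fit_splice_constraint(bundle)   # autosome + X models
glance(fit)
#>   n_regions n_autosome   n_x window_size scheme             median_oe n_variants_retained
#> 1      1031        902   129          50 inverse_proportion     -4.70                9110

head(tidy(fit)[, c("region_id", "oe", "constraint_score", "n_informative")], 4)
#>   region_id       oe constraint_score n_informative
#> 1 chr1:400-450 -23.8            0.565            43
#> 2 chr1:450-500 102.             0.170            42
#> 3 chr1:500-550  63.6            0.264            40
#> 4 chr1:550-600  81.5            0.218            40

# did the model recover the planted constraint?
regs <- ground_truth_labels(bundle, fit$models$autosome$regions)
median(regs$constraint_score[regs$constrained])   # 0.863
median(regs$constraint_score[!regs$constrained])  # 0.401

# train and evaluate the ensemble on the synthetic truth set
examples <- assemble_examples(bundle$truth, fit, genome = bundle$genome) |>
  group_split_examples(seed = 42)
train <- dplyr::filter(examples, split == "train")
test  <- dplyr::filter(examples, split == "test")
model <- train_ensemble(train, n_trees = 1000, seed = 42)
test$ml_score <- predict(model, test)
curve <- pr_curve(test$ml_score, test$label)
average_precision(curve)                                  # 1 (planted signal is easy)
pr_baseline(attr(curve, "n_pos"), attr(curve, "n_neg"))   # 0.227
autoplot(curve)
```

The glance line says 1031 windows survived the filters (902 autosomal,
129 on X, normalized separately). The region table shows the signed
weighted O/E and its rank-normalized constraint score: `chr1:400-450`
is depleted (O/E −23.8 → score 0.565 under this run's distribution),
its neighbors variant-rich and tolerant. On the planted truth set the
constrained-gene windows' median score (0.86) clearly exceeds the
tolerant ones (0.40), and the ensemble separates pathogenic from benign
far above the 0.227 chance baseline.

A command-line driver with `simulate`, `build-matrix`, `score-regions`,
`train`, `predict` and `evaluate` subcommands is installed at
`system.file("cli", "spliceoe", package = "spliceoe")`.

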