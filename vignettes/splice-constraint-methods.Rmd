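---
title: "Regional splicing constraint: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional splicing constraint: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceoe)
```

## The model and its assumptions

The package estimates regional genetic constraint against aberrant
splicing: the degree to which splice-relevant variation observed in a
healthy population falls short of a mutational expectation. The premise
is that purifying selection removes deleterious splice-disrupting
alleles, so regions harboring them appear depleted. Three assumptions
matter:

1. **The splice predictor stratifies mutational consequence.** Each
   possible substitution carries four delta scores (acceptor gain/loss,
   donor gain/loss), each in [0, 1]. We use their sum, s ∈ [0, 4], so a
   nucleotide contributing to several splicing scenarios is not
   understated. At sites without a qualifying population variant the
   max over the three alternates stands in; at variant sites the
   variant's own ref→alt sum is used.
2. **A per-site expectation suffices.** The substitution probability is
   conditioned only on the reference allele and the score bin (no
   trinucleotide context): the predictor already sees the flanking
   sequence, which injects local context indirectly.
3. **Depletion is regional.** Selection against splice disruption acts
   on windows (splice sites, regulatory neighborhoods), so observed and
   expected counts are aggregated over windows before comparison.

### The substitution table

Counts are tallied over every scored, unmasked position of merged
protein-coding transcripts (strand-separated union of transcripts per
gene; tallies are then summed over strands, with reference alleles read
as written in the reference — score records are keyed the same way, so
no reverse-complementing is applied). Each site increments exactly one
of 4 × 8 = 32 (reference allele × score bin) cells, as a variant site or
a no-variant site. Then

* p(ref, bin) = n_var / (n_var + n_novar), the per-site substitution
  probability in that cell, and
* Proportion(ref, bin) = cell sites / all sites,

with autosomes and X tallied into separate tables (hemizygosity changes
both the callset and the selective regime), pseudoautosomal regions
excluded from X, and Y excluded outright. Empty cells get p = 0 with a
logged flag rather than smoothing — the pseudocounts below absorb the
degeneracy, and smoothing would quietly fabricate expectation where
there is no data.

### The weighted O/E statistic

For a window, with per-cell raw observed counts o[i] and expected sums
e[i], both sides get a pseudocount of 1.0 (O = 1 + o, E = 1 + e) and

$$\mathrm{O/E} = \sum_{i=1}^{32} X[i]\,\frac{O[i] - E[i]}{E[i]}.$$

The pseudocounts are applied once per cell; under this reading the
statistic is exactly 0 when observed equals expected everywhere, and it
has a continuous negative range — more negative means more depleted.
(Both orientation conventions appear in the constraint literature; here
the normalization direction fixes it — scores are sorted from largest
to smallest O/E and the smallest O/E gets the top constraint score — so
*negative* O/E is the constrained end.)

Weight schemes for X[i] (`weight_vector()`):

| scheme | X[i] |
|---|---|
| `unweighted` | 1 |
| `linear` | bin representative score (midpoint) |
| `log` | −10·log10 Proportion[i] |
| `one_minus_proportion` | 1 − Proportion[i] |
| `inverse_proportion` | 1 / Proportion[i] (default) |
| `inverse_substitution_rate` | 1 / p(ref, bin) |

`inverse_proportion` is the default because the rare high-score cells —
the splice-relevant ones — carry nearly all the constraint signal, and
this weight makes the statistic scale-free with respect to how many
low-score sites a window happens to contain. Inverse schemes with a
zero denominator set that cell's weight to 0 and flag it (the cell
contributes nothing); the bin *representative* for the linear scheme is
the midpoint (the weight's definition leaves the representative open). The splicing-unaware
variant of the model is recovered by a single bin covering [0, 4] with
the unweighted scheme.

### Window filtering

* **Informative sites.** A window is only usable if it contains enough
  sites with any splicing signal (summed score > 0). The count per
  window is modeled as Poisson with rate λ = the genome-wide fraction
  of such sites; the critical value 6.5415 (α = 0.025) is adopted as a
  named constant, `INFORMATIVE_SITE_CUTOFF`. Its quoted derivation — an
  F distribution "with 7 degrees of freedom" representing the 8
  proportion bins — cannot be reproduced unambiguously, because an F
  distribution needs two degree-of-freedom parameters; the constant is
  therefore carried verbatim rather than re-derived. In practice it means a
  window needs ≥ 7 informative sites. `filter_windows()` also warns if
  λ·window is below the cutoff for the configured window size — with
  the default 50 bp windows and λ near 0.75 on synthetic data the
  expected count is ~37, comfortably above it.
* **Score coverage.** Windows with fewer than 80% of bases carrying a
  score record are dropped (`min_coverage_frac = 0.8`): an expectation
  built on a minority of a window's bases is not comparable to its
  observed count.

### Single-exon genes and normalization

Single-exon genes undergo no splicing, so depletion there cannot mean
splicing constraint. Their regions' O/E values are shifted positively
(toward tolerance). "Arbitrarily increased" is made concrete as: shift
so the single-exon mean lands at the 80th percentile of the multi-exon
O/E distribution, never downward; a fixed `delta` can be supplied
instead. Only regions lying wholly within single-exon genes are
touched.

Retained O/E values are rank-normalized: sorted largest → smallest,
scores (n − rank)/(n − 1) ∈ [0, 1], ties averaged. Score 1 is the most
constrained region. The map is anti-monotone by construction, needs at
least two regions, and autosome and X are normalized separately (their
O/E scales are not comparable). A position covered by overlapping
windows (step < window) takes the maximum covering score — the most
conservative call for prioritization. For display,
`log_display_score()` applies −10·log10(1 − s) with a configurable cap
at s = 1.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `window_size` | 50 | bp | smallest size supported by the informative-site cutoff; captures focal constraint at junctions |
| `step` | = window | bp | non-overlapping tiling is deterministic and non-redundant; smaller steps are allowed and resolved by the max rule |
| bin edges | 0, .1, .2, .4, .6, .8, 1, 2, 4 | summed score | finer resolution at low scores where most sites lie; any increasing 8-edge partition of [0, 4] is accepted (the method fixes eight bins but not their edges; these defaults are this package's choice) |
| `min_informative` | 6.5415 | sites | adopted critical value (above) |
| `min_coverage_frac` | 0.8 | fraction | expectation comparability |
| pseudocount | 1.0 | counts | centers the null at 0; fixed, not exposed |
| ensemble trees | 1000 | trees | the method's fixed ensemble size; other forest hyperparameters are standard defaults (unlimited depth, √p features, bootstrap), with the training seed recorded in the model object |

## The ensemble classifier

`assemble_examples()` builds the three-feature vector — constraint
score, max splice delta score, max spliceosome-classifier score — and
excludes non-autosomal variants and any variant missing a feature
(e.g. falling in a filtered-out window). The max of the four delta
scores is used as the splice-prediction feature — the natural reading
of a "max" splice feature — with the summed score available as a
switch. A
pass-through deleteriousness score (e.g. CADD) may ride along for
comparison reports but is never a feature.

Leakage control is grouped by constraint region: `group_split_examples()`
assigns whole regions to train/test (Bernoulli 0.6 per region, so the
expected training share of variants is 60%), and
`stratified_group_folds()` assigns regions to cross-validation folds
greedily, largest first, each into the fold where it least increases
squared class load — on single-variant regions this yields exactly
equal per-fold class counts, and a region never appears in two folds'
validation sets. Forest training (`ranger`, probability mode, one
thread) is bitwise-reproducible from the recorded seed.

## Evaluation statistics

* PR curves at every distinct score threshold (descending, no
  interpolation), average precision as the step sum Σ(R_i − R_{i−1})P_i
  — which is 1 exactly when the classes separate strictly — plus the
  trapezoidal PR area as a clearly labeled secondary summary (PR areas
  are often quoted without a stated integration rule; the step sum is
  the primary metric here).
* Baseline = P/(P + B), chance-level precision.
* Decile bins on [0, 1], lower-edge inclusive, last bin closed (so 1.0
  lands in the tenth bin).
* Per-decile odds ratios (A/B)/(C/D) with log-scale 95% CIs. Zero cells
  get the Haldane–Anscombe 0.5 correction on all four cells of that
  decile and a `corrected` flag — the textbook odds-ratio CI is undefined at zero
  cells, and the correction keeps it finite without discarding the
  decile.
* Variant strata: drop canonical sites (A-1/A-2/D+1/D+2), drop the
  splice region (≤ 8 intronic, ≤ 3 exonic bases), keep max splice score
  < 0.2; composable via `subset_filter()`. Position labels are computed
  strand-aware against merged exons; the acceptor side of the first
  exon and the donor side of the last exon are never canonical (they do
  not participate in splicing). An intronic base equidistant from both
  junctions is assigned to the acceptor side — a fixed, documented
  tie-break for odd-length introns.

## The synthetic-data generator

`simulate_bundle()` produces a mutually consistent bundle: reference
FASTA, gene models on both strands (including ~10% single-exon genes
and an X chromosome with a gene inside PAR1, so the PAR exclusion is
exercised), a per-substitution score track, population variants,
coverage, an exclusion mask, and a labeled truth set excluded from the
population callset.

What it emulates, and why these defaults:

* **Score track.** Junction-adjacent sites get high summed scores
  (canonical positions 1.5–3.5, splice region 0.4–2.0); background
  sites draw from a mixture with a point mass at 0, a bulk of weak
  scores and a cryptic-site tail reaching every bin, so all 32 cells of
  the substitution table are populated.
* **Depletion.** Each site carries a variant with probability
  μ(ref)·(d if the site's max summed score ≥ `motif_threshold` and the
  gene is constrained, else 1). The threshold defaults to 0.4:
  selection plausibly acts on any site predicted splice-relevant, not
  only the strongest ones. Constrained genes are drawn from multi-exon
  autosomal genes only — splicing constraint is undefined for
  single-exon genes, which the model deliberately shifts tolerant.
* **Rates.** μ = (0.18, 0.25, 0.27, 0.12) for A/C/G/T. These are
  deliberately hotter than human per-site polymorphism rates (realistic
  mutation-rate calibration is out of scope): at desk scale — 40 genes,
  ~60 kb of genic sequence, 50 bp windows — each window must carry a
  statistically detectable dose of the planted depletion, which these
  rates deliver while preserving the rank ordering of per-allele rates
  (transversion-poor A/T below G/C).

What it does **not** emulate: real mutation-rate heterogeneity
(trinucleotide context, CpG), linkage, coverage structure, mapping
artifacts beyond a toy mask, allele-frequency spectra, or realistic
score distributions (true high splice scores are far rarer). Passing
recovery tests therefore demonstrates that the estimator recovers a
planted regional depletion of the assumed form — not that it would
achieve any particular performance on real population data.

Problem sizes used by the test-suite recovery studies — 40 genes, 20%
constrained, d = 0.1, 20 seeds, plus a depletion sweep over
d ∈ {0.1, 0.4, 0.7, 1} — were chosen as the smallest study giving
stable medians across seeds.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; VCF/GTF
  (1-based) are converted at the I/O boundary only.
* Multi-allelic VCF records are decomposed to biallelic SNVs before
  filtering; a site with several retained variants counts once, under
  its max-sum variant, so shared sequence is never double-weighted —
  likewise a variant inside overlapping genes is one row annotated with
  all of them.
* A variant whose REF mismatches the reference is excluded and tallied
  in the per-criterion discard report, never fatal; a malformed GTF or
  a BED without an identity column is fatal with a pointed message.
* Ties in rank normalization take the mean rank; ties in the position
  lookup take the max score; the equidistant-intron tie-break is
  acceptor-side.
* `weighted_oe` needs no guard against division by zero: E ≥ 1 by
  construction.
* Model files are versioned serialized objects; loading verifies format
  and version and a reloaded ensemble predicts bit-identically.

## Known limitations

* The informative-site constant is adopted, not derived (see above).
* The rank-normalized score is relative to the fitted region set: two
  models are comparable only through their own [0, 1] scales.
* Empty substitution cells contribute zero weight under inverse
  schemes; with very small inputs many cells are empty and the
  statistic leans on few cells (the warning surfaces this).
* The generator's simplifications above mean synthetic benchmarks
  bound implementation correctness, not real-world accuracy.
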