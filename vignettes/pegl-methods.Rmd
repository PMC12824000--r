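---
title: "Measuring phylogenetically effective gene length with pegl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetically effective gene length with pegl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegl)
```

## The model

A gene alignment of $n$ columns is scored against an ensemble of $T$
random unrooted trees. For tree $t$ with topology and branch lengths
$\tau_t$, the likelihood of column $i$ under a reversible substitution
model factorizes over columns, so the total log-likelihood is the sum of
site terms, $L_t = \sum_{i=1}^n \ell_{t,i}$. Treating the $\ell_{t,i}$
as features and $L_t$ as the response, the Lasso

$$\hat\beta(\lambda) = \arg\min_\beta \tfrac{1}{2T}\lVert L - \beta_0 -
X\beta\rVert^2 + \lambda \lVert\beta\rVert_1$$

asks which sites are *needed* to predict the tree likelihood. Because
$L = X\mathbf{1}$ exactly, the unpenalized solution is trivial; the
penalty makes the question non-trivial: columns whose likelihood varies
little, or redundantly, across random trees are driven to exactly zero.
The number of sites with $\hat\beta_i(\lambda^*) \neq 0$ at the
cross-validated penalty $\lambda^*$ is the phylogenetically effective
gene length (PEGL); PEGL$/n$ is the proportion of informative sites.
The measure requires no reference topology and no ad hoc filtering
threshold.

Two properties of this construction are worth keeping in mind when
reading results:

* **Duplicate columns.** Columns with identical site patterns produce
  identical feature vectors. The L1 solution over an exact-duplicate
  block is not unique; with deterministic cyclic coordinate descent
  (glmnet) membership within a block is arbitrary but stable. Invariant
  columns, which collapse into at most four patterns, are therefore
  counted essentially once per pattern — which is exactly why they do
  not inflate PEGL.
* **Collinearity.** All site likelihoods co-vary strongly with the total
  tree length of each random tree, so the regression tends to represent
  the response with a sparse subset of the variable columns rather than
  all of them. PEGL is thus a *lower* envelope of "sites with any
  signal": a deliberately parsimonious census.

## Likelihood engine

Site likelihoods come from Felsenstein pruning with per-node rescaling
(log-scalers accumulated per site), which keeps $n$ up to a few thousand
sites stable at short branch lengths. Gaps, `?`, `N` and IUPAC ambiguity
codes contribute partial likelihood 1 for each compatible state — they
are soft missing data, never a fifth state; a fully ambiguous column has
likelihood exactly 1. Models are JC69, HKY85 and GTR, scaled to one
expected substitution per site at stationarity, optionally with
discrete-gamma rate heterogeneity (k = 4 equal-weight categories,
category rates by the mean-of-quantiles rule) and a proportion of
invariant sites. Base frequencies for HKY85/GTR default to
ambiguity-weighted empirical counts.

Branch lengths are optimized one at a time by bracketed Brent search on
$[10^{-8}, 10]$, cycling until a full pass improves the total
log-likelihood by less than $10^{-6}$ (at most 20 cycles). The clamps
matter: identical sequences drive lengths to the lower bound instead of
zero (where conflicting columns would have zero likelihood), and
saturated pairs stop at 10 substitutions/site instead of diverging.

In place of a full model-finder, `select_model()` sweeps
{JC69, HKY85, GTR} × {+Γ4, none} and minimizes
BIC $= -2\ln L + k\ln n$, with ties resolved toward fewer parameters;
the model can also be fixed directly, which is what the synthetic
pipeline does (data are generated and scored under JC69). Whether site
likelihoods should use each gene's selected model or a fixed one is left
configurable; the default is the model the caller passes.

## Random-tree ensemble

The published workflow generates random trees with an external tool
whose sampling law is undocumented. Here the ensemble is fully
specified: topologies grow by a Yule random-split process (a uniformly
chosen current tip is bifurcated until $m$ tips exist, labels assigned
in random order, tree unrooted), and each of the $2m-3$ branches draws
an i.i.d. Exponential length with mean `bl_mean` = 0.1
substitutions/site. Both choices are exposed as parameters. A master
seed yields per-tree child seeds through a single up-front
`sample.int()` draw, so ensembles are reproducible and order-stable.
The reference ensemble size is $T = 10{,}000$ trees; the test-suite and
the bundled synthetic reproduction use 200–1,000 trees, which leaves the
qualitative behavior of every statistic intact at a fraction of the
cost.

## Penalty path and cross-validation

Features are standardized inside glmnet (zero-variance columns are
always excluded exactly); the intercept is unpenalized. The penalty path
is geometric with 100 values from $\lambda_{\max}$ (smallest all-zero
penalty, nudged up by $10^{-6}$ relative so the all-zero endpoint is
exact in floating point) down to $\lambda_{\max}\cdot 10^{-4}$. The path
is passed to `cv.glmnet` explicitly because glmnet's internal path stops
early once deviance saturates, which would truncate the low-penalty end.
$\lambda^*$ is chosen by seeded 10-fold cross-validation at the error
minimum by default; the one-standard-error rule is available
(`lambda_rule = "1se"`) and gives sparser masks. Coefficients are
reported on the original feature scale, and multiplying all
log-likelihoods by a positive constant leaves the informative mask
unchanged (standardization contract), up to the documented
arbitrariness inside exact-duplicate blocks.

## Branch support

The ML tree is found by neighbor joining on closed-form JC distances
(negative NJ lengths clamped to zero) followed by best-improving NNI
hill-climbing with full branch-length re-optimization, stopping when no
rearrangement gains more than $10^{-4}$ log-units. For each internal
branch the aLRT statistic is $2(\ell_1 - \ell_2)$, where $\ell_1$
re-optimizes the focal branch on the current arrangement and $\ell_2$ is
the better of the two NNI alternatives, each with the focal branch
re-optimized. Parametric support is $1 - p$ with
$p = \tfrac12\Pr(\chi^2_1 \ge \text{stat})$ for a positive statistic and
$p = 1$ at zero (the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture), so
a statistic of 2.706 maps to support 0.95. Two deliberate
simplifications: only the focal branch is re-optimized during the NNI
comparison (an optional `"full"` mode also re-optimizes the four
adjacent branches), and negative statistics — possible when the input
tree is not locally optimal, common on star-like shallow data — are
clamped to zero with a warning rather than treated as errors. Supports
are reported raw, one per internal branch, with no multiplicity
correction; the average over the $m-3$ internal branches is the
per-gene support metric. All internal branches are counted in the
average, including effectively zero-length ones, which is why
within-species (star-like) genes show low averages by construction.

## Synthetic data: what it emulates, and what it does not

Two divergence regimes are generated. *Among-species* genes evolve on
Yule trees rescaled so the mean root-to-tip depth is 0.05
substitutions/site (congeneric mitochondrial scale). *Within-species*
genes evolve on star-like trees with short internal branches (mean
$\theta/10$) and longer terminals (mean $\theta = 0.005$), so most
variable sites are autapomorphies — variation that contributes to tree
likelihood but not to internal-branch support, reproducing the
characteristic combination of ordinary PEGL with low average aLRT at
shallow depth. Sites are invariant with probability `p_invariant`
(default 0.45, the mid-range of protein-coding mitochondrial
alignments); the rest carry codon-position rate multipliers, default
(1, 0.6, 4) — conserved second positions, fast synonymous third
positions. Panels draw gene lengths uniformly on 700–2,000 bp (rounded
to whole codons) with 5–8 taxa per gene, one tree per gene by default.
`inject_indels()` gaps a contiguous region for a taxon subset to
reproduce the indel-rich low-informativeness artifact that
combined-then-split alignments exhibit.

Ground truth is operational: invariant-class sites are
expected-uninformative, everything else expected-informative. That
label is leaky in both directions — a "variable-class" site can
realize zero substitutions at shallow depth, and distinct variable
sites can share one site pattern — so recovery tests compare selected
fractions between classes (enrichment) rather than expecting the mask
to equal the labels. The generator does not attempt realistic indel
evolution, selection, recombination, or gene-tree discordance;
conclusions from passing tests are about the estimator's mechanics, not
about any real mitochondrial or nuclear dataset.

## Problem sizes and numerical choices

The bundled end-to-end reproduction (`run_reproduce_synthetic()`, also
driven by `scripts/acceptance.R`) uses 8 genes per level, 700–2,000 bp,
400-tree ensembles, JC69 scoring, 10-fold CV and 10,000 bootstrap
replicates — a few minutes on one CPU; the statistics it reports
(informative-site percentages near a third of sites, a strong positive
length–PEGL regression, fast third positions, high among-species aLRT)
are stable in sign and magnitude across seeds at these sizes. Other
fixed choices: percentile (not BCa) bootstrap intervals at 2.5/97.5%,
significance declared when the interval excludes zero; "gapless length"
is the count of completely gap-free columns; proportions always use all
$n$ columns as the denominator; alignment columns are 1-based
everywhere; a column is flagged indel-rich within a group when more
than half of that group's sequences are gaps (configurable).

## Known limitations

* PEGL is duplicate-parsimonious (see above): on short alignments of
  few taxa, where many columns share patterns, it undercounts "sites
  with signal" relative to a per-column census, and the membership of
  the mask inside a duplicate block is arbitrary-but-stable.
* The aLRT implementation re-optimizes only the focal branch by
  default; supports on data with strong rate heterogeneity and
  near-zero internal branches are approximate.
* The tree search is plain NNI hill-climbing from an NJ start — fine
  up to ~25 taxa, not a replacement for a production ML search.
* Model selection sweeps six candidates; it is a stand-in for a full
  model-finder, kept deliberately small and overrideable.
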