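# pegl — phylogenetically effective gene length via sparse learning

`pegl` quantifies how much of a gene alignment actually carries
phylogenetic information. Given a nucleotide alignment, it generates an
ensemble of random phylogenetic trees (random topology *and* branch
lengths), computes the log-likelihood of every alignment column on every
tree under a standard substitution model, and fits an L1-penalized
(Lasso) regression of each tree's total log-likelihood
`L_t = Σ_i ℓ_{t,i}` on its site log-likelihoods `ℓ_{t,i}`. Because the
penalty produces exact zeros, sites whose likelihood contribution barely
varies across trees are dropped; the sites keeping non-zero coefficients
`β̂_i(λ*)` at the cross-validated penalty `λ*` are the phylogenetically
informative ones. Their count is the **phylogenetically effective gene
length**:

```
PEGL(g) = Σ_{i=1..n} 1{ β̂_i(λ*) ≠ 0 }
```

and `PEGL(g)/n` is the proportion of informative sites — a
topology-agnostic, threshold-free measure for comparing markers (e.g.
mitochondrial vs nuclear genes, shallow vs deep divergence). It is aimed
at systematists choosing loci for population-level and congeneric-species
studies.

Around that core the package provides:

* a Felsenstein-pruning likelihood engine (JC69 / HKY85 / GTR, discrete
  gamma, invariant sites, per-node rescaling) with BIC model choice;
* ML tree search (NJ start + NNI hill-climbing) and **parametric aLRT**
  branch support — `2(ℓ1 − ℓ2)` against the better NNI alternative,
  support from the ½χ²₀ + ½χ²₁ mixture — as a topology-only companion
  metric;
* panel statistics: length–informativeness regression, codon-position
  breakdown, positional profiles, percentile-bootstrap comparison of two
  gene groups;
* simulators of within-species (shallow, autapomorphy-dominated) and
  among-species (Yule) alignments with planted per-site ground truth.

## Worked example

Simulate one among-species gene and measure its effective length:

```r
library(pegl)

tree <- simulate_yule_tree(6, depth_scale = 0.05, seed = 1)
gene <- simulate_alignment(tree, subst_model("JC69"), n = 600,
                           p_invariant = 0.45, codon_rates = c(1, 0.6, 4),
                           seed = 1)
fit <- informativeness_run(gene$alignment, n_trees = 500, seed = 7,
                           model = "JC69")
fit
#> Lasso informativeness fit: 500 trees x 600 sites
#>   lambda* = 0.0104592 (min rule, 10-fold CV)
#>   PEGL = 312 informative sites (52.0% of alignment)

codon_position_counts(fit$mask, frame = 1L)
#>  c1  c2  c3
#> 106  96 110
```

312 of 600 sites (52%) carry tree-likelihood signal at the
cross-validated penalty; the counts by codon position show the
fast-evolving third positions contributing the largest share (110 vs
106 and 96). Branch support on the same gene:

```r
bst <- alrt_annotate(ml_search(gene$alignment, subst_model("JC69")),
                     gene$alignment, subst_model("JC69"))
average_alrt(bst)
#> [1] 1
```

(the simulated internal branches are long relative to the 600 bp of
data, so every internal branch is maximally supported).

Full-pipeline synthetic panels (two divergence levels × several genes,
records, regression, codon breakdown, bootstrap comparison) are produced
by `run_reproduce_synthetic()`; per-file outputs by `run_simulate()`,
`run_informativeness()`, `run_support()` and `run_compare()`, each of
which serializes its resolved configuration and seed next to its
results. A thin command-line wrapper over these functions is shipped in
`inst/scripts/pegl-cli.R`.

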