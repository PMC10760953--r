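# dimerclass

Classify activating variants of a homodimeric receptor ligand-binding domain
(LBD) into mechanistic classes from conformational ensembles, and identify
the inter-residue distances that drive the classification.

## The problem

Activating mutations in the estrogen receptor alpha LBD come in two flavors:
**class I** mutations (Y537S, D538G) reposition helix 12 directly, while
**class II** mutations (V422del, G442R, F461V, S463P, L469V) cluster near the
homodimer interface and act by enforcing dimerization. Given per-variant
conformational ensembles (multi-model PDB files, coordinate tables, or the
built-in synthetic generator), `dimerclass` featurizes each snapshot into
symmetry-averaged pairwise Cα (or Cβ) distances at three structural sites —
2,403 ligand-binding-pocket distances in 21 groups, 36 antagonist-state
H12–H3/H5 distances in 1 group, and 181 cross-chain dimer-interface
distances in 4 groups — and trains a sparse classifier that separates the two
classes while selecting the few distances that matter.

## The model

Snapshots are labeled y = 0 (class I) or 1 (class II) and modeled by
weighted logistic regression, logit P(y=1 | x) = β₀ + xᵀβ, fit by minimizing

    (1/n) Σᵢ wᵧᵢ · CE(yᵢ, σ(β₀ + xᵢᵀβ))
      + λ [ (1−α) Σₗ √pₗ ‖β⁽ˡ⁾‖₂ + α ‖β‖₁ ]

a class-weighted cross entropy plus the **sparse group lasso**: β⁽ˡ⁾ is the
coefficient block of feature group l (pₗ features), λ sets the overall
regularization strength and α ∈ [0,1] balances feature sparsity (α = 1,
lasso) against group sparsity (α = 0, group lasso). The intercept is never
penalized. The solver is a deterministic monotone FISTA (accelerated
proximal gradient with backtracking and restart) written in plain R.
Hyperparameters are tuned on a fixed validation split over λ ∈ 10^(−4..3)
and α ∈ {0, 0.1, …, 1}; features with |β| > 10^−1.6 are selected (capped at
the top 15 by |β|) and the model is refit unpenalized on the selection.
Features are standardized against each variant's initial structure, so a
negative coefficient on a selected distance reads directly as "this residue
pair sits closer together in class II".

## Worked example

The package ships a generator that emulates the 7-variant study design with
a known planted signal: class II ensembles carry six cross-interface
contractions (3–6.4 Å) among H8 residues 427/430/434 and the H9–H10 loop
residues 462/464/465, on top of 1 Å AR(1) positional noise. A scaled-down
cohort (200 snapshots per variant) runs in under half a minute:

```r
library(dimerclass)

cohort <- generate_cohort(synthetic_spec(n_snapshots = 200, seed = 1))
result <- run_classification_pipeline(cohort$ensembles, cohort$labels,
                                      split = proportional_split_spec(200))
result
#> <dimer_pipeline> CA features: 2620 in pool, 6 selected (threshold 0.0251, cap 15)
#>   best lambda = 0.1, alpha = 0.5
#>   median per-variant accuracy: validation 1, test 1

tidy(result)
#> # A tibble: 6 × 9
#>   feature site      residue_a residue_b scope       refit_coefficient sign     interpretation
#>   <chr>   <chr>         <int>     <int> <chr>                   <dbl> <chr>    <chr>
#> 1 f2612   interface       430       462 inter_chain             -6.62 negative closer in class II than in class I
#> 2 f2613   interface       430       464 inter_chain             -4.89 negative closer in class II than in class I
#> 3 f2606   interface       427       462 inter_chain             -5.90 negative closer in class II than in class I
#> 4 f2619   interface       434       464 inter_chain             -4.26 negative closer in class II than in class I
#> 5 f2620   interface       434       465 inter_chain             -1.60 negative closer in class II than in class I
#> 6 f2608   interface       427       465 inter_chain             -1.04 negative closer in class II than in class I
```

The pipeline recovers exactly the six planted features — all at the dimer
interface, all with negative coefficients (closer in class II) — and
classifies every variant's validation and test snapshots correctly
(median per-variant accuracy 1.0 on both splits). `glance(result)` returns
the one-row run summary, `autoplot(result)` the per-site attribution chart,
and `write_report_bundle(result, dir)` the full set of delimited-text
report tables.

Ensembles from files work the same way: `read_multimodel_pdb()` /
`read_coordinate_table()` produce the same `snapshot_ensemble` objects the
generator emits.

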