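# oascreen

Edge-weighted optimal-assignment molecular similarity for ligand-based
virtual screening, with evolutionary optimization of the query's
assignment-edge weights.

## What it does, and for whom

In ligand-based virtual screening (VS) a chemical library is ranked by
similarity to one known active query molecule.  The optimal-assignment (OA)
similarity compares two molecular graphs by the maximum-weight bipartite
matching of their atoms,

    S(A,B) = max_π Σ_i S_{iπ(i)},      S_OA(A,B) = S(A,B) / sqrt(S(A,A)·S(B,B)),

where `S_ij` is a radial-basis similarity of per-atom physico-chemical
descriptor vectors enriched by a decay-damped, recursive comparison of the
depth-2 atom neighborhoods, and the matching is solved exactly with the
Hungarian method.  Because not all parts of a query matter equally for
activity, each assignment edge leaving query atom `i` can carry a weight
`w_i ≥ 0` with `Σ w_i = m`:

    S_w(Q,B) = max_π Σ_i w_i · S_{iπ(i)}.

`oascreen` optimizes these weights against VS metrics (AUC or BEDROC) on a
labeled active/decoy dataset, using constriction particle swarm optimization
(φ1 = φ2 = 2.05, χ ≈ 0.73, 2D-grid torus neighborhood) or one of three
differential evolution variants (`DE/rand/1`, `DE/best/2`,
`DE/current-to-best/1`; binomial recombination, F = 0.8, CR = 0.6,
λ = 0.6), searching the bounded raw space `[-0.5, 0.5]^m`.  It also provides
the standard VS evaluation stack (ROC/AUC, BEDROC with α = 53.6, ROC
enrichment, chemotype-aware awROCE, discovery curves), a split/multirun
evaluation harness, a weight-redistribution transform for per-atom Ball &
Stick visualization, and a synthetic planted-pharmacophore dataset generator
so everything is testable without external data.  It is aimed at
cheminformaticians prototyping query-weighted similarity searching.

## Worked example

```r
library(oascreen)

# a synthetic screening deck with a planted indole-carbonyl pharmacophore:
# 40 actives in 5 chemotype clusters, 200 confusable decoys
fx <- generate_planted_dataset(fixture_spec(seed = 1))
fx$dataset
#> <oa_dataset> 240 molecules (active: 40, decoy: 200), 5 chemotype clusters

# unweighted OA screening
r0 <- oa_screen(fx$query, fx$dataset)
metric_report(r0)
#> Virtual-screening metrics
#>   AUC:    0.8005
#>   BEDROC: 0.0410 (alpha = 53.6)
#>   ROCE:   1% = 0.00, 2% = 0.00, 5% = 0.00
#>   awROCE: 1% = 0.00, 2% = 0.00, 5% = 0.00

# optimize the query's edge weights on half the data, test on the other half
plan <- make_splits(fx$dataset, n_splits = 1, seed = 11)
keep <- plan[, 1]
opt <- oa_dataset(fx$dataset$mols[keep],  fx$dataset$info$label[keep],
                  fx$dataset$info$cluster[keep])
ext <- oa_dataset(fx$dataset$mols[!keep], fx$dataset$info$label[!keep],
                  fx$dataset$info$cluster[!keep])
fit <- oa_fit(fx$query, opt, metric = "auc", method = "pso",
              budget = 1500, seed = 42)
fit
#> Edge-weight optimization (pso, AUC)
#>   query: query (13 atoms)
#>   evaluations: 1500   best training AUC: 0.8815

auc(oa_screen(fx$query, ext))   # uniform weights, external half
#> [1] 0.807
auc(predict(fit, ext))          # optimized weights, external half
#> [1] 0.8715

# which atoms carry the weight?  redistribute over local environments
awm <- redistribute_weights(fx$query, coef(fit))
round(awm$norm, 2)
#>  [1] 0.00 0.35 0.46 0.50 0.67 0.88 1.00 0.94 0.36 0.12 0.07 0.23 0.65
export_ballstick(fx$query, awm, "query_weights")   # .sdf + radius table
```

The numbers above are what the code prints at those seeds: optimizing the
edge weights lifts the external-half AUC from 0.81 to 0.87, and the largest
redistributed weights sit on planted-fragment atoms (atoms 3-13, the
carbonyl/indole region of the 13-atom query, versus atom 1 of the ethyl
linker at 0), which is how the method communicates *why* a
query matches.

A thin command-line front end with `screen`, `optimize`, `evaluate`,
`experiment`, `visualize` and `fixtures` subcommands is installed at
`inst/cli/oascreen.R`.

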