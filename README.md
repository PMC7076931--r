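# sadmine

Niche-vs-neutral inference for microbial communities: maximum-likelihood
species abundance distribution (SAD) fitting with Akaike-weight model
selection, MIC-based co-occurrence networks, Chao1 richness and
rarefaction, and stepwise-AIC environmental richness models — with a
synthetic-data generator that provides known ground truth for every stage.

## Who this is for

Microbial ecologists with OTU count tables (QIIME-classic TSV), per-sample
metadata (site, region, domain) and environmental covariates who want to
ask: are these communities structured by niche processes or assembling
neutrally, which taxa co-occur more than chance allows, and which soil
parameters drive richness?

## The statistics at the core

**SAD model selection.** Pooled per-species counts `n_i >= 1` are fitted by
maximum likelihood under two zero-truncated families:

- Poisson-lognormal (niche signature):
  `P(n) = ∫ Pois(n; λ) dLogNormal(λ; μ, σ)`, evaluated by mode-centred
  adaptive Gauss–Hermite quadrature;
- negative binomial (neutral comparator), mean `m`, dispersion `k`.

Support is summarized by Akaike weights
`w_i = exp(-Δ_i/2) / Σ_j exp(-Δ_j/2)`, `Δ_i = AIC_i - min AIC`; `w_PLN`
near 1 reads as niche structure, `w_NB` near 1 as neutrality. Octave
histograms (`floor(log2 n)`) and a prominence-based mode counter
operationalize SAD multimodality, a signature of emergent neutrality.

**Co-occurrence.** The maximal information coefficient (MIC) is the max
over grids `(nx, ny)` with `nx·ny ≤ n^0.6` of grid mutual information
normalized by `log2(min(nx, ny))` — exhaustively searched at small n,
by the published equipartition + dynamic-programming heuristic otherwise.
Edges require MIC > 0.8 and a Benjamini–Hochberg-adjusted permutation
p ≤ 0.001; topology is summarized with NetworkAnalyzer conventions.

**Richness.** Chao1 (bias-corrected by default:
`S_obs + F1(F1-1) / (2(F2+1))`), exact hypergeometric rarefaction, Pearson
correlations between domain richness, and Gaussian / negative-binomial
models of Chao1 against pruned covariates (|R| > 0.6 rule) selected by a
stepwise-AIC loop with region forced into the model.

## Worked example

```r
library(sadmine)

# a community whose truth we know: lognormal rates, Poisson counts
av <- simulate_sad(community_spec(1500, "pln", mu = 0.5, sigma = 2), seed = 1)
w  <- akaike_weights(fit_sad(av, "pln"), fit_sad(av, "nb"))
round(c(wPLN = w$wPLN, wNB = w$wNB), 4)
#> wPLN  wNB
#>    1    0

# the full pipeline on the bundled two-region, nine-site synthetic world
out <- run_pipeline(pipeline_config(seed = 1), "pipe_out", quiet = TRUE)
out$sad$comparisons[, c("domain", "group", "wPLN", "wNB")]
#>     domain            group       wPLN           wNB
#> 1 bacteria   vestfold_hills 1.00000000 4.235805e-136
#> 2 bacteria windmill_islands 1.00000000  6.918713e-53
#> 3  eukarya   vestfold_hills 0.08088518  9.191148e-01
#> 4  eukarya windmill_islands 0.99999999  7.903759e-09
#> 5  archaea   vestfold_hills 0.99999939  6.073492e-07
#> 6  archaea windmill_islands 0.76265216  2.373478e-01
```

The generator plants PLN communities everywhere except the Vestfold-Hills
eukaryotes, which are drawn NB — and that is exactly the group the weights
flag as neutral (`wNB = 0.92`), while bacteria show the overwhelming PLN
support typical of niche-structured communities.

```r
out$network$network
#> cooccurrence_network: 6 nodes, 3 edges, 3 components
#>   clustering coefficient = 0 | avg neighbours = 1 | char path length = 1 | diameter = 1
out$models$summary[, c("response", "distribution", "deviance_explained_pct")]
#>         response      distribution deviance_explained_pct
#> 1 bacteria Chao1 Negative binomial               95.77789
#> 2  eukarya Chao1          Gaussian               93.50529
#> 3  archaea Chao1          Gaussian               99.96564
```

The network stage recovers 3 of the 7 planted co-occurring pairs at the
strict MIC > 0.8 / adjusted p <= 0.001 filter with zero false edges —
realistic attrition at this noise level (the dedicated
`make_network_fixture()` world, with weaker sample wobble, yields 6–7/7) —
and the permutation null test correctly flags that the planted table
co-occurs more than chance (p = 0.005 at 199 permutations). The model
stage reports the Table-style summary of stepwise-selected environmental
predictors per domain; the very high archaeal deviance explained is
stepwise-AIC overfitting at desk-scale n = 36, discussed in the vignette.

Every stage writes plain TSV/JSON under the output directory
(`sad_weights.tsv`, `sad_octaves.tsv`, `chao1.tsv`,
`richness_correlations.tsv`, `network_edges.tsv`, `network_topology.json`,
`model_summary.tsv`, `manifest.json`), and reruns with the same seed are
byte-identical.

A command-line interface wraps the same operations:

```sh
Rscript inst/cli/sadmine.R simulate --out fixture --seed 1
Rscript inst/cli/sadmine.R sadfit   --in fixture --out results --scale regional
Rscript inst/cli/sadmine.R all      --out full_run --seed 1
```

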