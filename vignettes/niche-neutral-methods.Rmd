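---
title: "Niche or neutral? SAD model selection, MIC networks and richness models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche or neutral? SAD model selection, MIC networks and richness models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question this package answers

Soil microbial communities can be structured by *niche* processes
(deterministic sorting along environmental gradients) or assemble largely
*neutrally* (demographic stochasticity among ecologically equivalent taxa).
A practical way to ask which regime dominates is to fit competing species
abundance distributions (SADs) to pooled OTU counts: a Poisson-lognormal
(PLN) arises when many independent environmental factors multiply a taxon's
fitness (a niche signature), while a negative binomial (NB) arises from
gamma-distributed rates and serves as the neutral-style comparator. The
relative support for the two fits, summarized as Akaike weights
($w_{PLN}$, $w_{NB}$), is the core inference. Around it sit the standard
companions of a microbiome survey: Chao1 richness and rarefaction,
co-occurrence networks built from maximal information coefficients (MIC),
and environmental models of richness selected by stepwise AIC.

# The SAD models

For a species with latent mean abundance $\lambda$, observed counts are
Poisson. The PLN takes $\lambda \sim \mathrm{LogNormal}(\mu, \sigma)$:

$$P(n) = \int_0^\infty \frac{e^{-\lambda}\lambda^n}{n!}\,
  \mathrm{dLogNormal}(\lambda; \mu, \sigma).$$

The NB is the gamma-Poisson mixture with mean $m$ and dispersion $k$.
Because an abundance vector contains only *observed* species, both
likelihoods are zero-truncated by default: each term is
$P(n)/(1 - P(0))$. Untruncated fitting remains available through the
`truncated = FALSE` flag, since source descriptions of this procedure do
not always state the convention; truncation is standard SAD practice and is
what the generator emulates (zero draws are discarded).

## Numerical evaluation of the PLN

The integral has no closed form. After substituting
$\lambda = \exp(\mu + \sqrt{2}\sigma t)$ it becomes a Gauss-Hermite
integral, but a *fixed* Hermite rule centred at $\mu$ fails for large $n$:
the Poisson factor concentrates in a window of width
$\approx 1/(\sigma\sqrt{2n})$ around $\log n$, which falls between nodes
once $n$ is in the hundreds. `pln_pmf()` therefore recentres: for each $n$
a Newton iteration (the log-integrand is strictly concave, $h'' \le -2$)
finds the mode and curvature, and the Hermite rule is shifted and scaled
there — adaptive Gauss-Hermite quadrature. Node counts escalate
40 → 80 → 160 until successive values agree to a relative $10^{-8}$, with a
direct adaptive-quadrature fallback if they never do. Tests pin the
implementation to an independent `integrate()`-based oracle over a grid of
$(\mu, \sigma, n)$ including $n = 5 \times 10^4$; observed relative error
is about $10^{-11}$.

## Fitting and convergence policy

`fit_sad()` maximizes the truncated log-likelihood with Nelder-Mead from
three deterministic moment-based starts ($\sigma$, $m$, $k$ on the log
scale). A fit is declared *unconverged* when the optimizer fails, when
fewer than 5 species are available (small-data rule: weights are then
reported `NA`, mirroring how small local datasets behave in practice), or
when the numerical Hessian at the optimum shows *negative* curvature. The
curvature check deliberately tolerates near-zero eigenvalues: on strongly
heavy-tailed data the truncated NB likelihood rises toward its
log-series limit as $k \to 0$ and plateaus along a boundary ridge. That
supremum is statistically meaningful for model comparison (its AIC is what
the data support), so a flat ridge is treated as converged while a saddle
is not.

## Akaike weights, octaves, multimodality

With both fits converged, $\Delta_i = AIC_i - \min AIC$ and
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; weights sum to 1 and are
invariant to shifting both AICs. Abundances are displayed in octaves
$r = \lfloor \log_2 n \rfloor$ (singletons in octave 0); the
boundary-splitting Preston variant is *not* used — the plain floor rule is
deterministic and testable. Expected octave proportions under a fitted
model sum the truncated pmf over each octave; for the PLN this sum is
evaluated as a quadrature of Poisson CDF differences over the lognormal
rate, so deep-tail octaves cost no more than early ones. Multimodality is
operationalized by `count_modes()`: strict local maxima of the
proportion-normalized histogram with prominence (height above the higher
flanking minimum) exceeding 0.05, plateaus counting once. This is our
operationalization of a visual judgement, not a published algorithm. One
interaction to know about: a mixture component centred near $\mu = 0$
spreads its species almost evenly over octaves 0–1, and the resulting flat
hump can fall below the prominence threshold even when the mixture is
clearly bimodal by eye — modes are detected most reliably when both humps
sit in interior octaves.

# The synthetic world

`make_fixture()` emulates the study layout at desk scale: 2 regions
(5 + 4 sites), three domains with very different richness (2500 / 300 /
120 species), per-domain depths 10000 / 2000 / 5000 reads, and per-site
replicate sample counts of 8 (bacteria) and 4 (eukarya, archaea) —
reduced from 93 and 18 to keep a full pipeline run around a minute.
Communities are drawn *as latent rates* ($\lambda_i$ lognormal for PLN,
gamma for NB); samples are multinomial draws over those rates with
optional lognormal overdispersion (0.3 by default, a typical
sample-to-sample wobble for replicate soil cores). Sampling from rates
rather than from realized counts is essential: pooling multinomial
resamples of a *fixed integer community* does not stay in the generating
family, whereas Poisson sampling effort applied to lognormal rates is
exactly PLN with $\mu$ shifted by the log effort. This was verified
empirically during development — the wrong construction drives all pooled
fits toward NB.

Planted co-occurrence multiplies both members of a pair by a shared
per-sample lognormal factor (reciprocal for negative pairs), then restores
each sample's depth by largest-remainder rounding. In the network fixture
the planted OTUs are deliberately *minor* (about 1% of reads each):
abundant planted pairs would propagate through the compositional
normalization and correlate everything with everything.

What a green test does **not** establish: the generator has no taxonomy,
no sequence-level error, no primer bias, no spatial autocorrelation along
transects, and its overdispersion is symmetric lognormal — conclusions
about real amplicon data rest on the method, not on these simulations.

# MIC co-occurrence networks

`mic()` computes the maximal information coefficient: the maximum over
grid shapes $(n_x, n_y)$ with $n_x n_y \le B(n) = n^{0.6}$ of grid mutual
information normalized by $\log_2 \min(n_x, n_y)$. For $n \le 16$ the
search is *exhaustive* (every admissible row partition — cuts can only
fall between distinct values — combined with an exact column dynamic
program), so the small-$n$ oracle-equality invariant holds to machine
precision. For larger $n$ the published heuristic is used: equipartition
one axis, optimize the other by dynamic programming over at most
$c \cdot n_x$ clump boundaries ($c = 15$), applied in both orientations.
Since MIC is *defined* as a maximum over grids, running the complete
search where it is affordable is a better optimizer of the same objective,
not a different statistic.

Significance is by permutation: each OTU's sample order is shuffled
independently, $p = (b + 1)/(n_{perm} + 1)$. With $n_{perm} = 999$ the
attainable minimum is 0.001 — exactly the edge threshold. Consequently the
pipeline tests permutation p-values only on *candidate* pairs that already
pass the MIC $> 0.8$ screen and applies Benjamini-Hochberg within that
candidate set: correcting across all $\binom{k}{2}$ pairs would push the
smallest attainable adjusted p to $p_{\min} \cdot m / t$ and make the
stated thresholds jointly unattainable for any pair. The null
co-occurrence test uses the number of pairs with MIC above the threshold
as its statistic; the p-value filter cannot be recomputed inside each null
replicate without nested permutations.

Topology follows the undirected NetworkAnalyzer conventions: mean local
clustering with degree-$<2$ nodes contributing 0, characteristic path
length over connected pairs only, diameter as the longest finite shortest
path, average neighbours $2E/N$.

# Diversity

Chao1 defaults to the bias-corrected form
$S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$ (the vegan convention); the classic
form $S_{obs} + F_1^2/(2F_2)$ is the flagged alternative and falls back to
the corrected form when $F_2 = 0$. Rarefaction ($q = 0$) uses the exact
hypergeometric expectation with log-gamma arithmetic. Cross-domain
richness correlations pair samples by site and within-site rank — the
pairing in the motivating analyses is implicit, so this convention is ours
and unpaired samples are dropped with a reported count.

# Environmental richness models

Covariates are pruned before modelling: columns are visited in
lexicographic order and a later column correlated $|R| > 0.6$ with an
already-kept one is removed. Models are Gaussian (identity link) or
negative binomial (log link, dispersion by profile ML via the standard
IRLS alternation; AIC counts the dispersion parameter). Chao1 responses
are real-valued and are rounded to integers under the NB family, with a
message. Penalized-spline smoothness selection is deliberately out of
scope: "GAM-like" curvature is offered as unpenalized natural cubic
splines with fixed df = 3, compared against the linear term by AIC. The
stepwise search starts from the saturated model, evaluates all single-term
drops and adds each round, accepts the best strict AIC improvement, breaks
ties toward fewer terms then lexicographically, and never drops forced
terms. "Region as a random effect" inside a stepwise AIC loop is
statistically ambiguous; region is implemented as a forced fixed
categorical term (a flag makes it selectable instead), which is what a
fixed-effects AIC comparison can actually support.

A caveat at desk scale: with only a few dozen samples per domain and
~15 candidate covariates (each also available as a spline), stepwise AIC
can overfit dramatically — the bundled archaeal fit reports near-total
deviance explained from what is mostly noise. This is faithful stepwise
behaviour at small n, not a defect of the implementation; the recovery
guarantees tested by the acceptance suite use 90 samples against 10
candidates.

# Determinism and numerical conventions

Every stochastic operation takes an explicit seed; the pipeline splits one
master seed deterministically per stage, and a rerun with the same config
is byte-identical. Optimizer convergence uses relative log-likelihood
change $10^{-10}$; quadrature escalates until $10^{-8}$ relative
agreement; MIC ties between grids resolve to the first-found partition in
a fixed iteration order. Degenerate inputs (empty tables, all-zero
vectors, constant covariates, zero-variance correlations) raise
descriptive errors or warnings rather than propagating NaN.

# Known limitations

* Only PLN and NB are fitted; log-series, zero-sum multinomial and gambin
  are out of scope, as is any mechanistic neutral simulation.
* The NB boundary ridge means $\hat k$ is not interpretable when the fit
  sits near the log-series limit, although the model comparison remains
  valid.
* MIC beyond $n^{0.6}$ grid budgets, TIC/MAS statistics, and compositional
  methods (SparCC-style) are not implemented.
* True mixed-effects richness models and penalized smoothers are not
  implemented; the spline df is fixed.
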