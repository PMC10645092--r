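---
title: "Linking pairwise co-occurrence to trait dissimilarity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking pairwise co-occurrence to trait dissimilarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooctraits)
```

## The question

Do functional traits predict which species are found together? For lake fish,
three traits carry distinct ecological hypotheses. Thermal preference is a
proxy for environmental filtering: two cold-water species should co-occur in
the same stratified lakes, while a cold-water and a warm-water species should
rarely share a lake. Trophic level carries the biotic hypotheses: species at
similar trophic positions may compete, while a large trophic gap marks a
potential predator–prey pair whose interaction can extirpate the prey locally.
Body size is entangled with both — similar-sized species may compete, very
different sizes may interact as predator and prey.

`cooctraits` implements the full chain from presence/absence surveys to a
trait-level answer: a pairwise co-occurrence effect size under a
marginal-preserving null model, pooled across watersheds, regressed on
per-trait distances with permutation inference.

## The co-occurrence response

Each watershed is an incidence matrix: species as rows, lakes as columns, 0/1
cells. For a species pair with occupancies $r_a$, $r_b$ and $s$ shared lakes,
the C-score counts checkerboard units,

$$C_{ab} = (r_a - s)(r_b - s),$$

so identical distributions score 0 and disjoint ones $r_a r_b$. Raw C-scores
are not comparable across pairs or watersheds — they scale with occupancy —
so each is standardized against the *fixed–fixed* null model: the uniform
distribution over all binary matrices with the observed row totals (species
occupancies) and column totals (lake richnesses). With $C_\mathrm{exp}$ and
$\mathrm{SD}_\mathrm{exp}$ the mean and standard deviation of the pair's
C-score over that ensemble,

$$\mathrm{SES}_{ab} = \frac{C_\mathrm{obs} - C_\mathrm{exp}}{\mathrm{SD}_\mathrm{exp}}.$$

Positive SES means the pair co-occurs less than expected (segregation),
negative more (aggregation). The pair's overall response is the arithmetic
mean of its SES over the watersheds where both species occur.

Fixing both margins is deliberately conservative: it attributes nothing to
differences in species commonness or site richness, only to the *pattern* of
joint placement.

### Sampling the null: the curveball chain

The ensemble is sampled by the curveball Markov chain. One trade picks two
rows uniformly at random, pools the columns held by exactly one of them, and
re-partitions that pool uniformly, each row keeping its count of exclusive
columns. Trades preserve both margins, and the chain's stationary
distribution is uniform over the fixed-marginal set. The implementation runs
in compiled code on R's own RNG stream, so `set.seed()` makes every ensemble
bit-reproducible.

Mixing parameters are not dictated by the statistic, so the package fixes a
conservative default protocol — 1000 burn-in trades, one sample every 100
trades — and validates it empirically: on small matrices whose fixed-marginal
sets can be enumerated by brute force, thinned samples pass chi-square
goodness-of-fit tests against the uniform distribution (the test suite runs
this on twenty random matrices). Both knobs are exposed (`burn_in`, `thin`).
Note that goodness-of-fit checks assume approximately independent draws;
aggressive thinning (say below ~20 trades on tiny matrices) leaves visible
autocorrelation even though each marginal draw is uniform.

Three further conventions, each exposed or documented because reasonable
implementations differ:

* `n_samples` defaults to 999 null matrices; $\mathrm{SD}_\mathrm{exp}$ uses
  the sample (n − 1) standard deviation.
* The observed matrix is *not* counted as a null draw; `include_observed`
  adds it for users who prefer the inclusive convention.
* Pairs whose null C-score distribution has zero spread are flagged
  *degenerate* and excluded from pooling — their null carries no information,
  and mapping them to SES 0 would fabricate evidence of randomness. The
  per-watershed record keeps them visible.

## Watershed filtering and traits

Watersheds with fewer than 20 lakes or fewer than 20 occurring species are
removed before analysis, so every randomized matrix has at least a 20 × 20
block; the bounds are inclusive (exactly 20 × 20 is kept) and configurable.
Species present in a watershed's table but occurring in none of its lakes are
dropped *before* the species count, so the filter reflects the realized
community. That ordering is a package choice: the alternative (counting
listed-but-absent species) would retain slightly smaller realized matrices.

The trait table carries adult body size (total length, cm), temperature
preference (°C) and trophic level (dimensionless, ≥ 1). Temperature
preference may be missing; a missing value is imputed as the unweighted mean
of congeners with known values (genus taken from the table's own genus
column), and a species with no informative congener is a hard error rather
than a silent drop. Body size and trophic level must be complete on input.

Traits are z-scored — sample (n − 1) SD — over exactly the species entering
the pooled pair table, so distances are scaled to the analysed community
rather than to whatever superset the CSV happens to contain (`zscore_traits`
takes an explicit species set for users who want the other convention). The
per-trait dissimilarity of a pair is then the one-dimensional Euclidean
distance $|z_a - z_b|$; traits are never merged into a combined distance.
Quadratic terms are plain squares of those distances, not centered or
re-standardized: the fitted coefficient then reads directly as curvature of
the SES–distance relationship, at the cost of collinearity with the linear
term, which the permutation test handles without distributional assumptions.

## The regression and its permutation test

Four OLS models with intercept are fitted to the pooled table
(`cooc_models`):

| model | terms |
|---|---|
| `H1_full` | body + body², temperature, trophic + trophic² |
| `H2_body` | body + body² |
| `H3_temp` | temperature |
| `H4_trophic` | trophic + trophic² |

Parametric t-based p-values are reported for completeness, but pairwise
distances are not independent observations — every species sits in many
pairs — so the headline inference is a randomization test: the design
(the per-pair combination of trait distances) is held fixed while the SES
response is shuffled, the model refitted, and each term's slope recorded.
The two-sided permutation p-value is

$$p = \frac{1 + \#\{|\beta^\ast| \ge |\beta_\mathrm{obs}|\}}{n_\mathrm{perm} + 1},$$

with 9999 permutations by default; the +1 correction includes the observed
arrangement and keeps p off zero. Refits reuse the observed design's QR
decomposition across blocks of permuted responses, so the default 9999
permutations cost well under a second at a few thousand pairs.

Two shuffling schemes are provided because they answer subtly different
questions and neither is canonical:

* `pair_shuffle` (default) permutes the pooled SES vector freely over pairs.
  It is the literal "randomize the response" null: any assignment of
  co-occurrence values to trait-distance combinations is equally likely.
* `species_identity` permutes species labels and carries pair responses
  along, as in a Mantel test. It preserves the dependence structure among
  pairs sharing a species and is the stricter null when that dependence is
  strong. When the pair set is incomplete, a relabelling maps some pairs onto
  pairs with no observed SES; those rows are dropped from that replicate's
  refit, which slightly varies the per-replicate n. With complete pair
  coverage the scheme is the exact Mantel permutation.

Observed estimates are identical under either mode; only p-values differ.
Type-I error of the default mode is validated by simulation (below).

## The synthetic metacommunity generator

Real survey data of this kind are typically not redistributable, so the
package ships a generator whose planted effects make every pipeline stage
testable. It is a construction of this package — the simplest generative
analogue of each trait hypothesis — not a fitted model of any real system.

1. **Environmental filtering.** Each lake draws a temperature (watershed
   mean ~ Normal(18, 3) °C, lakes ~ Normal(mean, 2.5) within it); a species'
   presence log-odds drop from the baseline by
   $\beta_\mathrm{env} \cdot ((T_\mathrm{pref} - T_\mathrm{lake})/s)^2$ with
   scale $s = 5$ °C. Similar thermal preferences thus mean correlated
   occupancy: aggregation at small temperature distance, segregation at
   large — a positive `d_temp` slope.
2. **Predation.** Within a lake, each co-occurring species more than
   `pred_gap` trophic levels above a species is an independent removal
   hazard of rate $\beta_\mathrm{pred}$: removal probability
   $1 - e^{-\beta_\mathrm{pred} k}$ with $k$ present predators. Hazards are
   tied to *which* predators share the lake — that conditional dependence is
   what a marginal-preserving null can detect. A cull that fires whenever
   *any* predator is present does not work as a planted effect: in a
   realistic pool some predator is present almost everywhere, the cull
   becomes an unconditional thinning of prey occupancy, and the fixed
   margins absorb it entirely.
3. **Competition.** For present pairs closer than `comp_width` body-size
   z-units, one member (at random) is removed with probability
   $1 - e^{-\beta_\mathrm{comp}}$; off by default.

Stages run once, in that order, with no iteration to equilibrium — the
generator stays analyzable and never uses the pipeline's own statistics, so
validation is not circular. Traits are drawn on realistic scales
(body size log-normal around 25 cm; temperature Normal(18, 5.5) °C spanning
cold- to warm-water guilds; trophic level uniform on 2–4.5), with genera in
blocks so congeneric imputation can be exercised.

Default effect settings mirror the regime the pipeline is designed to
detect: filtering on (`beta_env = 1.5`, i.e. a species ~10 °C off a lake's
temperature is effectively excluded), predation on (`beta_pred = 0.8`, one
present predator removes a prey species with probability 0.55), competition
off. `pred_gap = 2` trophic levels restricts predation to true top-predator /
low-trophic pairs. That bend location matters statistically, not just
biologically: the predation signal is a hockey stick — flat until the gap,
rising after — and when the bend sits mid-range the *linear* trophic term
absorbs most of it, leaving the quadratic term without power. A power study
run while designing the recovery simulations (30 replicates per setting)
showed quadratic-term recovery rates of only 0.4–0.6 for bends near 1.5
z-units regardless of strength, versus ~0.9 once the bend moves late in the
observed distance range. Binning pooled SES by trophic distance displays the
planted hockey stick directly and is a useful diagnostic on any dataset.

What the generator deliberately does not emulate: spatial structure and
dispersal limitation (lakes are exchangeable within a watershed), species
abundance (occupancy only), correlated traits (body size and trophic level
are drawn independently, unlike real fish), richness gradients, and
imperfect detection. Passing recovery tests therefore show the *pipeline*
recovers planted effects under its own assumptions — they do not show those
assumptions hold for any particular survey.

## Reproducibility and seeds

A single master seed fans out deterministically: each watershed's null chain
is seeded by a polynomial hash of the watershed id added to the master seed
(`watershed_seed()`), so results are independent of processing order and a
single watershed can be recomputed in isolation; the permutation streams of
the four hypothesis models derive from the master seed analogously. Two runs
with the same configuration and seed produce byte-identical artifacts, and
every stage writes a CSV checkpoint from which downstream stages can be
re-run exactly (`regress_from_design()`).

## Validation built into the test suite

The suite validates the statistical machinery against independent oracles,
at simulation sizes chosen to keep the default run in minutes:

* *Conservation*: every sample of the curveball chain preserves all row and
  column totals (checked over 10⁵ samples of random 20 × 20 matrices).
* *Uniformity*: chain samples match brute-force enumerations of small
  fixed-marginal sets by chi-square goodness of fit.
* *Exactness*: pair C-scores against a naive shared-lake counter; sampled
  null mean/SD/SES against exhaustive enumeration, within Monte-Carlo error
  computed from the enumerated moments; sampled permutation p against the
  exhaustive 24-permutation p on four pairs.
* *Type-I error*: 200 neutral surveys (all effects off; 25 species, 3
  watersheds of 30 lakes; 199 null matrices, 499 permutations) — per-term
  rejection at the 5% level stays near nominal and p-values pass a KS test
  of uniformity.
* *Recovery*: 10 structured surveys per scenario (40 species, 5 watersheds
  of 40 lakes; 499 null matrices, 999 permutations) — filtering-only surveys
  recover a positive significant temperature slope, predation-only surveys a
  positive significant trophic quadratic term, and neutral surveys leave
  body-size terms non-significant, in at least 8 of 10 replicates each.

## Known limitations

* The SES response treats the 999-draw null mean and SD as known; their
  Monte-Carlo error propagates into the response noise (visible in the
  type-I simulations as slight extra dispersion, not as bias).
* Pairs sharing a species are dependent; `pair_shuffle` ignores that
  dependence, which is the usual practice but can be anticonservative when
  a few species dominate many pairs. `species_identity` is the guarded
  alternative.
* Collinearity of a distance with its square is accepted by design;
  interpret linear and quadratic coefficients jointly, not term by term.
* Mean-SES pooling weights every watershed equally regardless of lake count;
  an inverse-variance pooling would require the per-watershed null SD to be
  comparable across very different matrix sizes, which it is not.
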