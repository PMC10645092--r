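# cooctraits

Trait-based analysis of pairwise species co-occurrence for community
ecologists working with presence/absence surveys — built around lake fish
metacommunities, applicable to any system organized as sites-within-regions
incidence matrices plus a species trait table.

## What it computes

For every species pair in each watershed (region) the package computes the
checkerboard C-score, `C = (r_a − s)(r_b − s)`, where `r_a`, `r_b` are the
two species' lake counts and `s` the number of lakes shared. The score is
standardized against the fixed–fixed null model — the uniform distribution
over all binary matrices with the observed row and column totals — sampled
with the curveball Markov chain (999 null matrices by default):

    SES = (C_obs − C_exp) / SD_exp

Positive SES = segregation (the pair co-occurs less than chance), negative =
aggregation. Pair SES values are averaged across the watersheds where both
species occur, and the pooled values are regressed on per-trait Euclidean
distances (z-scored body size, temperature preference, trophic level, with
quadratic terms for body size and trophic level) under four hypothesis
models. Slopes are tested with a Mantel-style randomization: the trait
distances stay fixed while the SES response is shuffled (9999 times by
default), giving distribution-free p-values that do not assume pairs are
independent.

A synthetic metacommunity generator with tunable environmental filtering,
predation and competition effects makes the whole pipeline testable without
access to restricted survey data; see the methods vignette
(`vignettes/trait-cooccurrence.Rmd`) for the model, the generator's
mechanisms and every numerical convention.

## Worked example

Simulate a 40-species, 5-watershed survey with environmental filtering and
predation switched on, run the full pipeline, and inspect the temperature
hypothesis:

```r
library(cooctraits)

cfg <- run_config(
  sim = sim_config(n_species = 40, n_watersheds = 5, lakes_per_watershed = 40),
  out_dir = "example_run", n_null = 499, n_perm = 1999, seed = 11
)
res <- run_pipeline(cfg)

head(res$pooled, 3)
#>   species_a species_b     mean_ses n_watersheds
#> 1     sp001     sp002 -0.006848229            3
#> 2     sp001     sp003 -0.274467497            3
#> 3     sp001     sp004 -0.589730031            3

summary(res$reports$H3_temp)
#> Model 'H3_temp': 666 species pairs, R^2 = 0.251 (adj. 0.250), residual SD 0.511
#>
#>                    term estimate slope standard error t-value
#>             (intercept)         -0.377         0.0337   -11.2
#>  temperature preference          0.356         0.0238    14.9
#>  p-value regression p-value randomization
#>            1.05e-26                    NA
#>            1.30e-43                 5e-04
```

Reading the output: each pooled row is one species pair's mean SES over the
watersheds holding both species (negative = aggregated). The H3 fit shows
the planted filtering effect — pairs one z-unit further apart in temperature
preference are on average 0.36 SES units more segregated, and no arrangement
as extreme arose in 1999 response shuffles (randomization p = 1/2000). The
run directory also holds the per-watershed SES table, the design table, all
four model reports (CSV/JSON/text) and a run manifest with per-watershed
seeds — re-running with the same config and seed reproduces every file byte
for byte.

A command-line front end over the same functions ships in
`inst/cli/cooc.R` (subcommands `run`, `ses`, `regress`, `simulate`).

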