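# reefconnect

Does a single marine protected area matter to a whole region? For a
remote coral atoll such as Dongsha (northern South China Sea), the
answer hinges on whether each reef species' gene pool is effectively
panmictic across the region, or whether the atoll acts as an
intergenerational **stepping-stone** through which short-dispersing
larvae connect otherwise isolated reefs. `reefconnect` implements the
analysis chain needed to ask that question from single-locus mtDNA
samples, for population geneticists and MPA planners:

* **Haplotype-level statistics** — haplotype diversity
  *h* = (n/(n−1))(1 − Σp²), nucleotide diversity π with pairwise
  deletion, private-haplotype fractions, Fu's *F*ₛ = ln(S′/(1−S′)) with
  S′ = P(K ≥ k_obs | θ̂, n) under the Ewens sampling distribution and a
  1,000-simulation coalescent null, and pairwise Φ_ST (two-level AMOVA
  on raw difference counts) with 1,000-permutation tests.
* **Metapopulation model choice** — a structured-coalescent simulator
  over panmixia, n-island and stepping-stone topologies (backwards
  migration rates m/μ, windowed exponential priors on Θ and m/μ,
  HKY+Γ₄ or infinite-sites mutation), rejection-ABC marginal-likelihood
  proxies, and the standard Bayes-factor arithmetic: relative
  probabilities, 2 ln BF, odds, Kass–Raftery labels, and the exhaustive
  3-vs-3 replicate permutation t-test.
* **Reef-graph connectivity** — habitat patches (≥ 25 ha, 8-connected)
  from plain-matrix rasters, least-cost linksets over a cost raster
  (sea 1, land 10,000), binary dispersal graphs thresholded at
  D_max = PLD × 18.7 km/day, betweenness centrality, diameter and
  focal-patch rank, plus a synthetic seascape generator.
* **The PLD regression** — logistic regression of stepping-stone
  outcome on maximum pelagic larval duration with backward BIC
  selection and per-day odds-change reporting.

The package ships the published traits and model-selection outcomes of
the nine Dongsha reef species (`dongsha_species()`), which drive the
regression and group summaries.

## Worked example

Simulate a five-site stepping-stone species, test it, and ask which
metapopulation model its data support:

```r
library(reefconnect)

demes <- c("Dongsha", "Taiwan", "Luzon", "Xisha", "Nansha")
truth <- build_model("stepping_stone", demes, Theta = 0.01, M = 10,
                     neighbor_pairs = line_neighbors(demes))
mm  <- mutation_model(kappa = 4, alpha = 0.5)
sim <- simulate_dataset(truth, setNames(rep(20, 5), demes),
                        L = 600, mm, seed = 1)

diversity_table(sim$aln, sim$pm, nsim_fs = 200, seed = 1)[, 1:7]
#>   population  N n_haplotypes private pct_private         h          pi
#> 1    Dongsha 20            9       9         100 0.9052632 0.010280702
#> 2      Luzon 20            9       9         100 0.8473684 0.005885965
#> 3     Nansha 20           13      13         100 0.9105263 0.005947368
#> 4     Taiwan 20            7       7         100 0.7684211 0.014728070
#> 5      Xisha 20           10      10         100 0.9000000 0.008061404

post <- abc_model_choice(summarize_dataset(sim$aln, sim$pm),
                         model_templates(demes), prior_spec(),
                         nsim_per_model = 200, accept_fraction = 0.05,
                         seed = 42)
post
#> <model_posterior>
#>       panmixia         island stepping_stone
#>          0.167          0.267          0.567
#> best: stepping_stone  2lnBF: 1.508  odds: 2.12:1  support: weak
```

Every haplotype is private to its site here — at Θ = 0.01 per site over
600 bp with M = 10, demes share recent ancestry but not identical
haplotypes, the same pattern that makes Φ_ST informative.

The stepping-stone topology wins, and with a production reference table
(`nsim_per_model = 10000`, `accept_fraction = 0.01`) the support
sharpens. On the nine published species the PLD regression gives:

```r
fit <- dongsha_pld_regression()
unname(fit$odds_change_percent["pld_days"])
#> [1] 9.258134
pld_group_summary()
#>            model n mean_pld   sd_pld
#> 1       panmixia 5    77.80 57.88955
#> 2 stepping_stone 4    37.25 14.97498
```

— each added day of larval duration cuts the odds of a stepping-stone
outcome by 9.3%; stepping-stone species average 37 days of PLD against
78 for the panmictic group.

## Analysis workflow

Numbered drivers under `analysis/` replay the full study shape on
synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_datasets.R 1   # three synthetic species
Rscript analysis/02_popgen_stats.R 1        # diversity + PhiST tables
Rscript analysis/03_model_selection.R 1     # ABC + Bayes factors
Rscript analysis/04_reef_graph.R 1          # seascape, linkset, ranks
Rscript analysis/05_pld_regression.R 1      # PLD regression + curve
```

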