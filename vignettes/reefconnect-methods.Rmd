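---
title: "Methods: metapopulation model choice and reef-graph connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metapopulation model choice and reef-graph connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefconnect)
```

## The question

A singleton marine protected area — here Dongsha Atoll in the northern
South China Sea — can matter regionally in two distinct ways: its
populations can be demographically and genetically continuous with the
rest of the region (effective panmixia), or it can act as an
intergenerational *stepping-stone*, a waypoint through which larvae of
short-dispersing species connect otherwise isolated reefs. `reefconnect`
implements the full chain of analyses needed to ask that question from
single-locus mtDNA samples: haplotype-level diversity statistics,
coalescent-based selection among three metapopulation topologies, a
raster reef-graph centrality analysis driven by pelagic larval duration
(PLD), and a logistic regression of metapopulation outcome on PLD.

## Diversity and differentiation statistics

Haplotype diversity is the unbiased expected heterozygosity
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ over haplotype
frequencies. Nucleotide diversity $\pi$ is the mean per-pair proportion
of differing sites, computed with *pairwise deletion*: a site enters a
pair's comparison only when both sequences carry an unambiguous base.
The package treats `N` and `-` as missing; other IUPAC ambiguity codes
are mapped to `N` with a warning. Two sequences share a haplotype iff
they agree at every jointly non-missing site; a sequence compatible with
several established haplotypes joins the first-encountered one in input
order, a deterministic tie-break. Distances are raw mismatch counts with
no substitution-model correction, matching the default behaviour of the
standard mtDNA toolchain.

Fu's $F_s$ compares the observed number of distinct haplotypes $k$ with
its neutral expectation under the Ewens sampling distribution given the
scaled diversity $\hat\theta$ (estimated as the mean number of pairwise
differences per locus, $\theta_\pi$):

$$ S' = \Pr(K \ge k_\mathrm{obs} \mid \hat\theta, n), \qquad
   F_s = \ln \frac{S'}{1 - S'} . $$

$\Pr(K = k) = |s(n,k)|\,\theta^k / \theta^{(n)}$ uses unsigned Stirling
numbers of the first kind, computed by the triangular recurrence in log
space so that sample sizes typical of mtDNA surveys do not overflow, and
$F_s$ itself is evaluated in log space to survive $S'$ near 0 or 1.
Significance follows the field convention: 1,000 neutral coalescent
simulations at $\hat\theta$ with the same $n$ (infinite-sites mutation),
a lower-tail p-value, and the $\alpha = 0.02$ threshold reported
alongside. Simulated monomorphic datasets take the limiting value
$F_s = +\infty$, so they can never count as "more extreme" than a finite
observed value. P-values throughout the package use the add-one
(permutation-inclusive) estimator $p = (1 + m)/(B + 1)$, which cannot be
zero; it differs from the raw proportion by at most $1/(B+1)$.

Pairwise $\Phi_{ST}$ is the two-level AMOVA estimator with the raw
difference counts $d_{ij}$ as squared distances. Negative estimates are
retained internally — they are legitimate draws of a near-zero
parameter — and zeroed only in the display matrix, which is how such
matrices are conventionally published. The permutation test shuffles
individual labels holding sample sizes fixed. The focal-site comparison
is a two-sided one-sample t-test of the regional values against the
focal value as null mean.

## The synthetic-data engine

The generator is a structured-coalescent simulator over the three
candidate topologies:

* **panmixia** — a single deme;
* **n-island** — $d$ demes with equal $\Theta$ and one migration rate
  between every ordered pair;
* **stepping-stone** — migration only between declared neighbour demes
  (a connected graph is required).

Time is scaled in expected mutations per site, the convention of
coalescent samplers for single loci, so $\Theta$ absorbs the
inheritance scalar (haploid-maternal for mtDNA; the scalar is carried as
metadata only). With $k_i$ lineages in deme $i$, coalescence occurs at
rate $k_i(k_i-1)/\Theta_i$; each lineage in $i$ migrates backwards in
time to deme $j$ at rate $M_{ij} = (m/\mu)_{ij}$. Migration rates are
*backwards* immigration rates, stated explicitly because the direction
convention is a classic source of confusion.

Parameter draws come from windowed exponential priors —
$\Theta \in [10^{-5}, 10^{-1}]$ with pre-truncation mean $0.01$, and
$m/\mu \in [10^{-4}, 10^{6}]$ with mean $10^{5}$ — sampled by inverse
CDF on the truncated distribution. The rate is fixed from the stated
mean *before* truncation; the alternative (post-truncation mean) is not
distinguishable from the published description, and the choice is
exposed in `prior_spec()`.

**Strong-migration limit.** Near the top of the migration prior the
expected number of backwards migration events per genealogy runs into
the millions while the resulting data are indistinguishable from
panmixia. When the expected migration-event count exceeds a threshold
(default 5,000, computed deterministically from the parameters), the
simulator switches to the analytic strong-migration limit: an
unstructured coalescent with $\Theta_\mathrm{eff} = d \bar\Theta$, which
is the exact limiting process for symmetric migration with equal deme
sizes (lineages equilibrate across demes between coalescences, meeting
in any one deme with probability $1/d$). The switch is a property of the
parameter draw, not of the random path, so seeded runs stay
reproducible.

Two mutation engines sit on top of the genealogies. The HKY+G engine
draws a root sequence from the equilibrium base frequencies, assigns
each site to one of four equal-probability discrete-gamma categories
(category means, the standard discretization), and evolves each category
block along the tree at its rate. The infinite-sites engine drops
Poisson mutations on branches, each hitting a fresh site, so haplotype
identity and difference counts come straight from the genealogy; it is
exact, fast, and is what the $F_s$ null and the ABC reference tables
use. The analytic first-step oracle
(`expected_pairwise_coalescence_time`) solves the two-lineage
location-state linear system exactly and anchors the simulator's
Monte-Carlo tests; the marginal ancestral process of a tagged pair does
not depend on the other sampled lineages, so pairwise expectations need
only the two-lineage system.

## Model choice

Marginal likelihoods of the three topologies are approximated by
rejection ABC rather than by MCMC path sampling: parameters are drawn
from the priors above, datasets simulated and reduced to a fixed-order
summary vector (per-population $h$, $\pi$, $k$; all pairwise
$\Phi_{ST}$, undefined entries imputed as 0 and flagged; global $k$),
all statistics scaled by their median absolute deviation across the
pooled reference table, and the closest fraction (default 1% of the
pooled table, with 10,000 simulations per model) accepted by Euclidean
distance. Per-model acceptance rates at the common distance threshold
serve as marginal-likelihood proxies. Everything downstream — relative
probabilities, the antisymmetric $2\ln BF$ matrix, best-vs-second odds,
the Kass–Raftery labels (substantial above 3, strong above 6, the
latter corresponding to odds better than 20:1) and the exhaustive
3-vs-3 replicate permutation t-test with its $p = 0.05$ floor — is the
same arithmetic that a path-sampling analysis would feed. A model with
zero acceptances receives the probability floor
$1/(\text{total accepted} + \text{number of models})$ with a flag,
avoiding $-\infty$ proxies.

Replicated runs use independent seeds per replicate; the permutation
test enumerates all $\binom{6}{3} = 20$ relabelings, counts the observed
one, and therefore bottoms out at exactly $p = 0.05$ when one model
dominates all three replicates.

The panmixia template is simulated as a single deme and the observed
population labels are retained as strata, so its summary vectors have
the same dimension as the structured models'. The published gloss that
panmixia means a migrant proportion above 0.1 is treated as
interpretation, not as a simulated constraint.

## Reef graphs

Seascapes are plain rasters: a habitat mask and a cost layer (open water
1 per cell, land 10,000 per cell — land is expensively traversable, not
a hard barrier, which matters for narrow isthmuses). Habitat patches are
8-connected components of at least 25 ha (one 1-km cell is 100 ha).
Least-cost distances are exact Dijkstra expansions over the 8-neighbour
grid, with step cost equal to step length (resolution, or
$\sqrt2 \times$ resolution diagonally) times the mean of the two cells'
costs; patch-to-patch distance is the minimum over boundary-cell pairs
(edge-to-edge, not centroid-to-centroid, because large atolls make
centroids misleading). On open water the grid metric exceeds the
Euclidean distance by at most the octile overhead of about 8%.

A species' dispersal graph joins patches whose least-cost distance is at
most $D_\mathrm{max} = \mathrm{PLD} \times 18.7$ km/day (the mean summer
surface current speed in the region). The candidate linkset is complete
(all pairs), thresholded by $D_\mathrm{max}$; the graph is binary,
simple and undirected. Betweenness centrality uses unweighted shortest
paths with equal splitting among ties, endpoints excluded, normalized by
$(n-1)(n-2)/2$; graph diameter is the maximum shortest-path step count,
reported per component with a flag when the graph is disconnected. The
synthetic seascape generator places square patches and rectangular land
barriers at known coordinates and records the geometry as ground truth,
which is what the octile-bound and bridge-patch tests check.

## The PLD regression

Species whose data select the stepping-stone topology are coded 1,
panmixia 0 (the island model is never selected in the nine-species
dataset, so a binary coding suffices; a multinomial extension is out of
scope). The logistic fit is standard IRLS maximum likelihood; backward
BIC selection over {PLD, closest distance, furthest distance} drops the
term whose removal most decreases BIC until none helps. The headline
quantity is the per-day percent change in odds,
$100\,(1 - e^{\beta_\mathrm{PLD}})$, with Wald 95% intervals
($\beta \pm 1.96\,\mathrm{SE}$) transformed the same way — Wald rather
than profile intervals, matching how such intervals are conventionally
drawn on the fitted curve. With $n = 9$ the fit is fragile by
construction; complete separation is detected and flagged rather than
silently returned, and no penalization is added because the original
analysis used none. Great-circle distances use the haversine formula on
a 6,371-km sphere.

On the nine published species (PLDs 26–180 days; four stepping-stone
outcomes) the fit gives a slope of $-0.0972$, i.e. a 9.3% per-day
decrease in the odds of a stepping-stone outcome, and backward BIC
retains PLD alone. The PLD group means are 77.8 days (panmictic
species) and 37.25 days (stepping-stone), with a stepping-stone sd of
14.97. Recomputing the panmictic group's sd from the published PLDs
gives 57.9, not the published 60; the package reports the recomputed
value and does not force the discrepancy.

## Problem sizes and test design

The test-suite and acceptance problem sizes are chosen to exercise every
claim at desk scale: Ewens/Fs oracle grids cover all $n \le 8$,
$k \le n$, $\theta \in \{0.1, 1, 10\}$; simulator means are checked
against the first-step oracles at 1,500–5,000 replicates inside 3–4
standard-error Monte-Carlo envelopes; the ABC recovery experiment uses
the strongly structured stepping-stone condition ($\Theta = 0.01$,
$M = 10$, five demes in a line, 20 samples per deme, 500 bp) with 25
repetitions at 200 simulations per model and 5% acceptance, and a
panmictic control that must never yield strong stepping-stone support.
Analysis drivers default to 1,000 permutations and 1,000 null
simulations (the conventional counts) and a 200-per-model reference
table; `nsim_per_model = 10000` with 1% acceptance is the recommended
production setting and is the package default in `abc_model_choice()`.

## What the synthetic data do and do not show

The generator reproduces the *generative models* of the analysis — the
three topologies, the priors, HKY+G sequence evolution — but not the
field realities of the original data: heterogeneous and opportunistic
sampling across sites, uneven sample sizes, sequencing error,
demographic non-equilibrium (growth, bottlenecks), selection on mtDNA,
or the real geography of the South China Sea reef mosaic (the seascapes
here are constructed archipelagos, not digitized maps). Passing tests
therefore demonstrate the correctness and internal calibration of the
statistics and the self-consistency of the model-choice machinery; they
do not re-establish the empirical findings for the real species, which
would require the archived sequence data and the digitized reef raster.

Known limitations: the ABC proxy ranks models by acceptance rate, which
converges to posterior model probability only as the summary statistics
approach sufficiency; single-locus mtDNA gives one realization of the
coalescent, so model probabilities are sharp relative to the underlying
evolutionary uncertainty; and the dispersal graph is a heuristic
reachability model, explicitly not a biophysical larval transport
simulation.
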