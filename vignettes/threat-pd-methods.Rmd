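---
title: "Methods: projected PD loss under phylogenetically clustered extinction threats"
author: "pdthreat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projected PD loss under clustered extinction threats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdthreat)
```

## The problem

Extinction always removes branch length from the tree of life, but how much
depends on *which* species die. Faith's phylogenetic diversity (PD) — the sum
of branch lengths spanning a set of taxa — falls surprisingly little under
random extinction, because on most trees a modest random survivor set still
touches nearly every deep edge. Phylogenetically *clustered* extinction, in
which close relatives die together, can prune whole clades and their stems,
and so has long been expected to destroy disproportionate amounts of
evolutionary history; but tree shape modulates, and can even offset, this
effect. `pdthreat` implements the full analysis chain for asking this
question about a clade facing several distinct anthropogenic threats — the
motivating system is the ~838 living species of reef-building corals
(Scleractinia), whose IUCN assessment scores each species for eight binary
attributes (Red-List status thresholds, rarity, restricted range, and
susceptibility to bleaching, disease and crown-of-thorns predation).

The chain has four stages, each exposed as ordinary functions and wrapped by
the fitting-style entry point `threat_pd()`:

1. **Tree shape** — is the clade's time tree Yule-like, or tippy and
   imbalanced? (`gamma_statistic()`, `colless_yule_test()`)
2. **Threat clustering** — how phylogenetically clumped is each binary
   threat? (`phylo_d()`)
3. **Projected PD loss** — if every carrier of a threat goes extinct, how
   does surviving PD compare with random extinction of equally many species?
   (`percent_delta_epd()`)
4. **The cross-category relationship** — does clustering (low D) predict
   excess PD loss across threats? (`regress()`)

## Statistics and conventions

### Faith's PD, rooted

`faith_pd(tree, survivors)` sums the edges of the minimal subtree connecting
the survivors **to the original root**. The rooted convention matters for
clades like corals whose two root-daughter lineages ("complex" and "robust")
diverged in the Paleozoic: the two stem edges below the root carry a large
share of total PD, and they survive as long as any descendant does. The
clade-restricted reruns (`threat_pd(..., clade = "first")`) exist precisely
to check whether those two edges dominate the signal; pruned subtrees are
re-rooted at the most recent common ancestor of the kept tips, with no stem
edge above it.

### Percent difference in projected PD

For a doomed set of size $k$,

$$\%\Delta E(PD) = 100 \times \frac{\overline{PD}_{\text{random}} - PD_{\text{observed}}}{\overline{PD}_{\text{random}}},$$

where $\overline{PD}_{\text{random}}$ is the mean survivor PD over removals
of $k$ tips uniformly at random (default 1000 replicates). Positive values
mean the scenario destroys *more* PD than random extinction of equally many
species. The literature offers several normalizations (by total PD, by
expected loss, by expected survivor PD); we normalize by the expected
survivor PD, which reproduces the sign structure of the published coral
results (bleaching and disease strongly positive, range restriction
negative). Absolute magnitudes under other normalizations differ by a scale
factor, so cross-study comparisons should compare signs and ranks, not raw
values. When $\binom{n}{k} \le$ `reps` the null is enumerated exhaustively,
making small worked examples exact (the balanced four-tip tree with a doomed
cherry gives exactly $100(11/3 - 3)/(11/3) = 18.18\%$).

### The D statistic

`phylo_d()` measures phylogenetic signal in a binary trait as the sum of
sister-clade disparities: internal-node values are estimated bottom-up as
the mean of the two daughter values, and $d$ is the summed absolute
difference between daughters over all internal nodes. The raw $d$ is scaled
between two prevalence-preserving nulls,

$$D = \frac{d_{\text{obs}} - \bar d_{\text{Brownian}}}{\bar d_{\text{random}} - \bar d_{\text{Brownian}}},$$

so that $D = 1$ matches random label shuffles and $D = 0$ matches a
Brownian threshold trait (a latent liability evolving by Brownian motion,
with the top-$k$ tips scored 1 — rank thresholding keeps prevalence exact).
$D$ is not clamped: observed traits can be more dispersed than random
($D > 1$) or more clumped than Brownian ($D < 0$), and published coral
values include both. The daughter-mean nodal estimator is a declared design
choice; it reproduces both anchors by construction of the scaling, which is
what the downstream analysis consumes. Two one-tailed Monte-Carlo p-values
use the $(1+b)/(\text{reps}+1)$ convention: `p_random` counts shuffle
replicates at or below $d_{\text{obs}}$ (departure from random toward
clumping), `p_brownian` counts Brownian replicates at or above it (departure
from clumped toward random). A trait flagged `ns_vs_clumped`
(`p_brownian > 0.01`) is statistically indistinguishable from Brownian
clumping, matching the flag semantics of the published coral table.

Note that $d$ itself is topology-only; branch lengths enter solely through
the Brownian null, so $D$ is invariant to rescaling time but not to
arbitrary branch-length deformations.

### Gamma and Colless

`gamma_statistic()` is computed from the lineage-through-time intervals
$g_k$ (the time with exactly $k$ lineages, $k = 2..n$):

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\left(\sum_{k=2}^{i} k\,g_k\right) - T/2}{T\,\sqrt{1/(12(n-2))}},
\qquad T = \sum_{k=2}^{n} k\,g_k .$$

Under the Yule model $\gamma$ is asymptotically standard normal; positive
values mean divergences concentrate near the present. Ties in node ages
(zero-length intervals) are legal. `colless_index()` sums the daughter-clade
size disparities over internal nodes; `colless_yule_test()` compares it with
Yule topologies of the same size, drawn directly by the recursive
uniform-split construction (under Yule, the left-clade size of an $n$-clade
node is uniform on $1..n-1$) — ages never enter, so null trees need no
rescaling. The Monte-Carlo p-value again uses $(1+b)/(\text{reps}+1)$.

`simulate_yule()` conditions on $n$ by drawing the full internode vector
$g_2, \dots, g_n$ as independent exponentials with rates $2, \dots, n$,
including the final interval between the last split and the present; without
that final interval the gamma null calibration would be biased.

## The synthetic generator

`synth_spec()` defines coral-like study conditions; the defaults are the
conditions the real system presents: 838 extant species, a root at 365.3 My
splitting 55.1/44.9% into two clades, strongly positive gamma, above-Yule
imbalance, and eight threat categories whose prevalences (3.92–57.99%) are
the published coral values with clustering weights graded from 1 (fully
clumped) to 0 (fully random). `coral_preset()` is the scaled-down working
size used throughout the tests (400 tips, 10 trees) — chosen so a full
pipeline run completes in seconds while keeping every qualitative feature.

**Topology.** Each clade grows as a biased pure-birth tree: at every split
the speciating tip is chosen with weight $\kappa^{r_i/m}$, where $r_i$ is
the rank of the tip's depth among the $m$ active tips. The exponent is
bounded in $(0,1]$, so $\kappa$ is a mild, interpretable dial: the deepest
tip is at most $\kappa$ times as likely to speciate as the shallowest, and
$\kappa = 1$ is exactly Yule. We deliberately avoided unbounded exponents
(weights like $\kappa^{\text{depth}}$): their weights explode with depth
(already $\sim 10^7$ at 400 tips for $\kappa = 1.5$), collapsing the
topology toward a caterpillar — and on such degenerate trees the
clustering–PD-loss relationship the generator exists to exhibit inverts
outright. At the default $\kappa = 1.5$, mean Colless at $n = 400$ rises
from the Yule ~1980 to ~2510, comfortably above the Yule expectation while
preserving that relationship.

**Node ages.** Within each clade, Yule waiting times are rescaled so the
clade root sits at `root_age` × U(0.6, 0.9) (explicit deep stems join the
clades at the root), then every internal age is mapped
$a \mapsto A\,(a/A)^{\beta}$ with $A$ the clade root age. The transform is
monotone, fixes the root and the present, and for $\beta > 1$ pushes
divergences toward the present, raising gamma directly without rejection
sampling; $\beta = 2.5$ yields tree-wide gamma around 20, the coral-like
regime.

**Tree samples.** `generate_tree_sample()` draws the topology once and
redraws node ages per tree. A posterior sample over a fixed tip set may vary
in topology as well; age-only variation is the conservative choice that
keeps the per-category trait tables meaningful across the whole sample
(a trait clumped on tree 1 stays clumped on the others, as in real posterior
samples, where topological variation is concentrated at poorly supported
nodes).

**Threat tables.** Each category with prevalence $p$ and weight $w$ places
$k = \mathrm{round}(pn)$ carriers: $k_{bm} \sim \mathrm{Binomial}(k, w)$
from the top of a Brownian liability ranking, the rest uniformly from the
remainder, so realized prevalence is exact and mean D decreases
monotonically in $w$ (calibrations: $w=0$ gives mean D ≈ 1, $w=1$ gives
mean D ≈ 0).

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: real threat categories overlap (the same
*Acropora* species are susceptible to both bleaching and predation), whereas
generated categories are independent; real posterior samples carry
correlated node-age uncertainty; and real threats are not Brownian-threshold
draws — their placement reflects ecology, so quantities like the
cross-category slope transfer only qualitatively (sign and rank structure,
not magnitudes).

## Orchestration, seeding, degenerate inputs

`threat_pd()` runs every category over every tree and aggregates a
per-category table (mean ± SD over trees), mirroring the published
coral-table layout. All randomness derives from one master seed:
per-category streams are keyed by a hash of the category *name* and
per-tree streams by the tree index, so permuting table columns permutes
output rows and nothing else, and reruns are bit-identical. Categories
monomorphic on the analysed tip set (e.g. a threat confined to the other
clade in a clade-restricted rerun) produce flagged `NA` rows rather than
silent drops; species present in the threat table but absent from the trees
are excluded with a logged count (the coral assessment covers 827 of 838
species). Ultrametricity is validated to an absolute tolerance of 1e-6 My —
posterior tree files carry limited decimal precision — and violations name
the worst tip. Polytomies are resolved by uniform random sequential pairing,
with each new node's age uniform between the polytomy's age and its older
child, which preserves ultrametricity and avoids the zero-length edges that
degenerate gamma.

`regress()` fits ordinary least squares of %ΔE(PD) on D, or on prevalence
*as a fraction* (required for slope magnitudes to be comparable across
clade-restricted blocks), with the classical two-sided t-test on $n-2$
degrees of freedom. The default `on_means` mode fits the eight category
means; `per_tree` fits within each tree and reports the across-tree mean and
empirical 95% interval. On the published coral block means, `on_means`
reproduces the printed slopes to within a fraction of a percent but yields
larger R² values than printed, which is consistent with the published R²
having been averaged over per-tree fits; both modes are exposed and neither
is privileged.

## Problem sizes and limitations

The test suite and the acceptance script run at deliberately modest sizes —
the package's own choices for routine verification: Yule calibrations use
1000 trees of 100 tips (gamma) and 100 trait replicates on 200-tip trees at
1000 null replicates (D); the end-to-end run uses the 400-tip, 10-tree
preset at 200 null replicates across five master seeds. All complete in
about a minute on a single core; full-size runs (838 tips, 1000 trees,
1000 replicates) are linear in each factor.

Known limitations: the D estimator is the package's own daughter-mean rule,
not a re-implementation of any published package, so D values are comparable
within analyses run here but may differ in the third decimal from other
software; %ΔE(PD) magnitudes depend on the normalization choice discussed
above; single-draw threat tables are noisy — the cross-category slope from
one synthetic table has substantial spread, and sign stability should be
judged across master seeds, as the acceptance checks do; and the
random-extinction null treats species as exchangeable, ignoring any
covariance between extinction probability and branch length beyond what the
scenario itself encodes.
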