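---
title: "Methods: event-based and distance-based cophylogenetics in cophyr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-based and distance-based cophylogenetics in cophyr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophyr)
```

# The system and the questions

`cophyr` implements the statistical workflow for asking how a host-specific
parasite fauna diversified on a radiating host clade. The motivating system
is the monogenean gill-parasite genus *Cichlidogyrus* on the tropheine
cichlids of Lake Tanganyika: a host radiation of fewer than twenty nominal
species carrying a considerably richer, strongly host-specific parasite
assemblage. Four questions structure the package:

1. **How many parasite species are in the sample?** Sequence-based
   delimitation with a divergence threshold (`delimit_species()`).
2. **Which speciation mechanisms shaped the parasite tree?** Event-based
   reconciliation of the host and parasite trees under cospeciation /
   sorting (loss) / within-host duplication / host-switch events, with the
   event costs estimated from the data (`reconcile()`,
   `estimate_costs()`).
3. **Are the host and parasite phylogenies congruent at all?** A
   topology-randomization test on cospeciation counts
   (`cospeciation_significance()`) and a distance-based permutation test
   (`parafit_global()`, `parafit_links()`).
4. **Did the parasite speciation rate change through time?**
   Lineages-through-time analysis with a rate-shift test against
   constant-rate trees (`fit_models()`, `rate_shift_test()`).

A fifth, supporting module (`simulate_*()`) generates joint host-parasite
histories with known event tallies, so every inferential step can be
validated against ground truth. The `analysis/` scripts in the repository
run these stages end to end on such a synthetic study.

# Species delimitation

Haplotypes are collapsed case-insensitively (`collapse_haplotypes()`);
pairwise distances are computed under the p, Jukes-Cantor, or
gamma-corrected Jukes-Cantor model with pairwise deletion of gaps and
ambiguities. The defaults used by the analysis scripts are the marker
conventions for this system: a 1% threshold for nuclear ITS rDNA with
gamma shape 0.40, and 2% for mitochondrial COI with shape 0.11.

Two modelling choices deserve comment:

* **Linkage rule.** "Haplotypes displaying at least x% divergence" is read
  as a *separation* criterion: clusters are the connected components of the
  graph joining pairs with `d < threshold` (single linkage), with the
  boundary strict — a pair exactly at the threshold stays separate.
  Complete linkage is available behind `linkage = "complete"`; for the
  published per-host worked examples (at most four haplotypes whose printed
  ranges sit entirely on one side of the threshold) the two rules coincide,
  which is why those counts are usable as exact checks.
* **Distance models.** The original distances were computed under richer
  substitution models (TVM+Γ, TIM2+I+Γ) whose fitted parameters are not
  printed; the package therefore treats published distance ranges as
  classification inputs rather than recomputation targets, and accepts
  externally computed matrices via `read_distance_matrix()`.

Greedy pruning (`prune_similar()`) thins haplotypes below the threshold
before diversification analysis, processing haplotypes by decreasing
multiplicity (ties by label) so the most-sampled variant represents each
cluster; all surviving representatives are pairwise at least the threshold
apart, which is asserted in the tests.

The molecular-rate calibration divides a pairwise divergence range by twice
the clade age (divergence accrues on both lineages); endpoints are rounded
to one decimal to match conventional reporting, so 2–7% over 2.4 My gives
0.4–1.5% per million years per lineage.

# Event-based reconciliation

## Model and algorithm

The parasite tree is embedded into the host tree; each parasite internal
node receives one event:

* *cospeciation* — the parasite node maps onto a host node, its children
  descending into distinct host daughter lineages;
* *duplication* — both children stay in the same host lineage;
* *host-switch* — one child stays, the other jumps to a host edge that is
  not ancestral to the source (no extra duplication is billed unless
  `charge_dup_with_switch` is set);
* *sorting* — each host edge traversed without a parasite event counts one
  loss.

The minimum-total-cost embedding is computed by dynamic programming over
(parasite node, host node) pairs, the standard undated
duplication-transfer-loss recurrence: `C[p, h]` is the cheapest embedding
of the subtree at `p` with `p` mapped at `h`, and `IN[p, h]` additionally
allows sorting down from `h`. Switch targets exclude only `h` and its
ancestors; target contemporaneity is *not* enforced inside the DP (that
problem is NP-hard) but checked afterwards: `check_chronology()` builds the
ordering constraints implied by each switch (the parent of the source must
predate the target, and vice versa) on top of the tree's own ancestor
order, and tests the constraint graph for acyclicity. Tests compare this
against brute-force enumeration of all total orders of host internal
nodes. Note that a minimum-cost reconciliation may legitimately fail the
chronology check — that is a finding about the solution, not an error —
whereas simulated histories pass by construction because simulated switches
target branches alive at the moment of the switch.

Ties are broken deterministically (cospeciation over duplication over
switch, then lexicographic host position by smallest descendant leaf
label), so identical inputs give byte-identical reports. The DP is
validated against an independent exhaustive oracle that enumerates every
assignment of parasite internal nodes to host nodes on tanglegrams of up to
five leaves a side.

Polytomies: a multifurcating parasite node is resolved greedily (children
whose linked hosts are closest on the host tree are joined first) when
`allow_polytomies` is set, mirroring the published parallel analysis with a
basal polytomy. Parasite leaves linked to several hosts are split into one
pseudo-leaf per host with a logged note. Preprocessing follows the
published protocol: nodes under 70% bootstrap support can be collapsed
(`collapse_low_support()`, strict inequality, unlabeled nodes kept), and
terminal monophyletic clades confined to a single host are collapsed to one
leaf (`collapse_terminal_host_clades()`) so that within-host speciation in
terminal taxa does not masquerade as cospeciation.

## Adaptive event costs and their degeneracies

Rather than fixing costs a priori, `estimate_costs()` samples cost vectors
uniformly from the simplex, reconciles under each, and scores each vector
by a quality `q(c)`: the Euclidean distance between the normalized costs
and the normalized inverse event frequencies of the optimal reconciliation
under those costs (frequencies floored at half an event so unused types
stay finite). This operationalizes "costs anti-proportional to event
frequencies", the principle named by the parameter-adaptive reconciliation
literature; the original tool's exact formula is unpublished, so `q` is
documented as an approximation. The best candidates are refined by
Nelder-Mead on the simplex through a softmax parameterization, always
including five deterministic archetype starts (each event type cheap in
turn, plus the uniform scheme) so that every event-dominant basin is
explored regardless of sampling luck.

The anti-proportionality criterion has *exact degenerate fixpoints*: a
scheme that prices one event type out of use entirely can be perfectly
self-consistent (the unused type's inverse frequency is large, matching its
large cost). Two consequences are built into the package:

* among candidates whose qualities tie at the numerical resolution of the
  search, the cheaper (more parsimonious) reconciliation is preferred;
* `flag_implausible()` raises a flag whenever an event type has zero
  inferred occurrences while its normalized cost exceeds 0.9 — the
  signature of the degenerate class, and exactly the pattern on which the
  published analysis rejected its statistically best solutions.

The filter is deliberately narrow: it encodes the published rejection rule,
not a general degeneracy detector. Multi-zero fixpoints (two event types
priced out at ~0.45 each) evade it, which is why the stage-3 analysis
script additionally applies biological context, as the original authors
did: when the randomization test independently demonstrates topological
congruence, ranked solutions that invoke zero cospeciations are rejected
before the filter-passing best is retained. Judging cost schemes on
statistics alone is explicitly insufficient here.

## Topological congruence randomization

`cospeciation_significance()` reconciles under cospeciation-favoring costs
(0 for cospeciation, 1 for everything else), takes the cospeciation count
as the statistic, and compares it with the same statistic on pairs of
topologies drawn uniformly from all labeled rooted binary shapes (the
proportional-to-distinguishable model, implemented by sequential uniform
edge attachment and verified uniform by enumeration for 3 and 4 leaves).
Links are kept fixed; both topologies are randomized; p-values use the
add-one convention. Whether the original randomization also permuted links
is not documented; holding them fixed tests topology, which is the stated
intent.

# Distance-based congruence

`parafit_global()` embeds host and parasite distance matrices by principal
coordinates (axes kept when their eigenvalue exceeds 1e-10 of the largest;
negative eigenvalues dropped by default, Cailliez correction behind a
flag), forms `D4 = t(C) A B`, and uses the sum of squared entries as the
global statistic; the null permutes host identities (rows of B). The
statistic is identical to the classical ParaFit global statistic, which the
tests verify against the independent implementation in `ape`. Per-link
statistics are the drop in the global statistic when one link is removed,
computed by a closed-form rank-1 update and tested against direct
recomputation. 9999 permutations with add-one p-values are the default.
The parasite distance builder accepts a codon-position mask so third
positions of protein-coding markers can be excluded.

# Diversification analysis

Branching times require an ultrametric tree (leaf depths equal to within
1e-6 relative tolerance). Likelihoods use the internode-interval
decomposition: with `k` lineages and per-lineage rate `lambda(k)`, an
interval of length `g_k` ending in a branching event contributes
`ln(k lambda(k)) - k lambda(k) g_k`, the terminal interval only the
exponential term. The model set is the classical five: pure birth and
constant birth-death (rate-constant) versus linear density dependence
`lambda0 (1 - k/K)`, exponential density dependence `lambda0 k^(-x)`, and
two-rate pure birth with the shift searched on the grid of observed
branching times, ties to the earlier time (rate-variable). The pure-birth
rate has the closed form (number of branching events) / (total lineage
time), which the tests confirm equals the numerical optimum; the
birth-death likelihood is checked against `ape::birthdeath`; density
dependence is profiled so only a one-dimensional search remains (K on
`(n, n + e^12]`, x on `[-3, 5]`).

The rate-shift statistic is `AIC(best rate-constant) - AIC(best
rate-variable)`; positive values favor temporal rate variation. Its null
distribution comes from pure-birth trees of the same tip count with the
rate estimated from the data; since the statistic is invariant to time
rescaling (checked by doubling all ages), the estimated rate only sets the
scale and the test is exactly calibrated up to Monte Carlo error — the
acceptance suite verifies a type-I error inside [0.01, 0.10] at the 5%
level and at least 80% power under a strong linear slowdown
(`lambda0 = 1, K = 40, n = 37`), the regime reported for the real parasite
tree. Null trees are simulated as branching-time vectors directly (the
statistic depends on nothing else); complete sampling is assumed
throughout.

# The synthetic-data generator

`simulate_cophylogeny()` grows one parasite lineage down an ultrametric
host tree: at each host node the lineage cospeciates with probability
`p_cosp` or follows a single uniformly chosen daughter (one sorting event);
along branches, duplications, switches and losses are Poisson events;
switch targets are drawn uniformly among host branches alive at that
moment, so simulated histories are chronologically consistent by
construction. The full event log is recorded, and
`replay_cophylogeny()` re-runs the engine with decisions taken from the log
instead of the RNG, reproducing trees, links and tally exactly — the
bookkeeping invariant asserted on every simulation in the tests. True
tallies include events on lineages that later went extinct; inferred counts
from the extant tanglegram are therefore expected to undershoot sortings
and duplications, which is visible in the stage-3 comparison.

Defaults (`p_cosp = 0.9`, `r_dup = 1.5`, `r_switch = 0.3`, `r_loss = 0.5`
per unit host-tree height) were chosen once so that a 16-tip host tree of
height 1 yields a parasite fauna about twice the host richness with only a
handful of true host-switches — the scale and event mix of a host-specific
gill-parasite radiation on a lacustrine host radiation. Sequence evolution
is Jukes-Cantor with optional gamma rate heterogeneity; the two-taxon mean
p-distance is tested against the closed form.
`simulate_clustered_alignment()` builds alignments with a known number of
well-separated clusters (between-cluster model distances about 3.5 times
the threshold, within-cluster at most about 0.4 times), the calibration
under which threshold delimitation is required to recover the true cluster
count in at least 99% of runs.

What the generator does *not* emulate: alignment error and indels,
saturation and among-lineage rate variation beyond the gamma model,
incomplete host sampling, multi-host parasite lineages, and
failure-to-diverge. Passing tests therefore demonstrate correctness of the
inferential machinery under the stated generative model, not robustness to
every artefact of real sequence data.

# Problem sizes, seeds and numerics

The analysis scripts run at desk scale by reducing only Monte Carlo
sampling densities, never the algorithms: 2000 sampled cost sets (the
conventional setting is 1e4), 2000 random tree pairs for the topological
test (1e4), 9999 permutations for the distance-based test, and 5000 null
trees for the rate-shift test, on a 16-host / ~45-parasite simulated
tanglegram. Exhaustive-oracle validation uses tanglegrams of up to five
leaves a side, where enumeration is exact and fast. Every stochastic stage
takes an explicit integer seed; a master seed is fanned out by
`stage_seed()` with fixed offsets, and all tie-breaks are deterministic, so
a full run is reproducible from one integer. Cost comparisons inside the DP
use an absolute tolerance of 1e-9 scaled by the cost magnitude; support
collapse redistributes the removed edge's length onto its children so leaf
depths (and ultrametricity) are preserved; distances carry an explicit
`units` attribute ("fraction" versus "percent") so thresholds cannot be
applied on the wrong scale.

# Known limitations

* The quality function is an approximation to an unpublished criterion;
  only the anti-proportionality principle, not the exact formula, is
  reproduced.
* The reconciliation is undated: chronology is a post-hoc check, and no
  attempt is made to find the cheapest *time-consistent* solution.
* The host tree is taken as given and must be binary or multifurcating
  with meaningful rooting; no rerooting is attempted.
* Diversification fits assume complete sampling; no sampling-fraction
  corrections are implemented.
* The distance-based test inherits ParaFit's behavior of dropping negative
  principal-coordinate eigenvalues unless the Cailliez correction is
  requested.
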