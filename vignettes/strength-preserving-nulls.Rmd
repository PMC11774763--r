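---
title: "Strength sequence-preserving null models for weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strength sequence-preserving null models for weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strengthnulls)
```

## The problem

Weighted network statistics — rich-club coefficients, clustering, path
lengths, hub counts — are only interpretable against a null model that says
what the statistic would look like "by chance" while holding fixed the
features one does *not* want to explain. Degree-preserving rewiring fixes
the binary scaffold but lets node strengths drift freely; because nearly
every weighted statistic is a function of the weight placement, a
degree-only null conflates "this feature is unexpected" with "this feature
follows from the strength sequence". `strengthnulls` builds nulls that fix
the strength sequence too, and ships the machinery to quantify how well
each null family does so.

## The models

All three randomizers operate on a `weighted_network` — a square weight
matrix with directedness/signedness flags, zero diagonal, exact zeros
meaning "no edge". Signed networks therefore cannot carry zero-weight
edges; this is the usual adjacency-matrix convention and a documented
limitation.

**Maslov–Sneppen rewiring.** Two edges `{a,b}`, `{c,d}` with four distinct
endpoints are replaced by one of the two alternative pairings, chosen
uniformly (the choice is not specified by convention; uniformity avoids
bias). Weights travel with their edges, so the weight multiset is conserved
exactly while the strength sequence is destroyed. Proposals that would
create self-loops or multi-edges are rejected; with the connectedness guard
on, a swap is also reverted unless the two severed pairs remain mutually
reachable — for a connected input this is equivalent to the whole graph
staying connected, because any path through a removed edge can be rerouted
through the reconnection, and it is much cheaper than a full component
census. Directed swaps (`a→b, c→d ⇒ a→d, c→b`) keep weights in their
source row and hence preserve the out-strength sequence exactly; the guard
then maintains strong connectivity (no node disconnected under
reachability in either direction — where the convention between weak and
strong is ambiguous we adopt the stricter reading). Signed switching
proposes swaps within a sign class, preserving positive and negative degree
sequences; connectedness is not guaranteed there. The default intensity is
ten swap rounds per edge; each round tries up to ten candidate pairs, and
rejected proposals are counted in `swaps_attempted` but not
`swaps_effected`.

**Rubinov–Sporns rank matching.** On a rewired scaffold, weights are
reassigned iteratively: residual strengths start at the empirical values;
unassigned edges are ranked by expected magnitude
$\hat e_{ij} \propto (s_i - \sum_u \hat A_{iu})(s_j - \sum_u \hat A_{ju})$;
a uniformly random unassigned edge receives the remaining original weight
of matching rank; the two touched residuals are updated and the procedure
repeats. Ties in $\hat e$ are broken by a per-edge random key drawn once
per call (the procedure is only specified up to pseudorandom order); ties
in the weight ranking need no rule because only the rank position in the
sorted multiset matters. The compiled implementation updates residuals
incrementally and recounts ranks in $O(E)$ per step ($O(E^2)$ total); an
independent full-recompute R implementation backs the tests and agrees
bit-for-bit under a shared seed. The unsigned variant places all edges at
once; the signed variant runs the procedure separately on positive and
negative edges with the per-sign strength targets.

**Simulated annealing.** Starting from the scaffold's weight placement,
random weight pairs are swapped; a proposal is kept if it lowers the energy
$E = \frac1n \sum_i (s_i - \hat s_i)^2$ or if $r < \exp(-(E'-E)/T)$ with
$r \sim U(0,1)$. Objectives: undirected — the plain mean squared error;
directed — in-strength and out-strength errors summed; signed — positive
and negative strength errors summed, with swaps restricted to a sign class
(the restriction is implied by requiring both sequences to be preserved
separately, and it keeps per-sign degrees exact); the directed alternative
picks a random node with at least two outgoing edges and swaps two of its
outgoing weights, so out-strengths are conserved exactly and the energy is
the in-strength error alone. The schedule is geometric: temperature starts
at 1,000 and is halved at each stage end, for 100 stages of 10,000
proposals by default. With an energy threshold set (the participant-level
convention: `1e-4`, up to 1,000 stages) the run halts at the first stage
end at or below the threshold — performance is evaluated at stage ends
only. The algorithm returns the *final* configuration, plain-annealing
style; the best-seen energy is recorded in the trace for diagnostics, and
with the default schedule the final stages are effectively greedy so the
two coincide in practice.

Numerical details that matter: energy is updated incrementally per swap
(only up to four node strengths change) and recomputed in full at each
stage end; a drift beyond `1e-9 × n` aborts the run, and the full value
replaces the incremental one so error cannot accumulate across stages.
Swaps of equal weights are ordinary proposals that happen to leave the
configuration unchanged (`ΔE = 0` is accepted); degenerate networks in
which no swap can change any strength (e.g. a perfect matching) simply
return the scaffold weights. One uniform variate is consumed per proposal
from the run's single seeded stream, so runs are exactly reproducible.

**Ensembles.** `generate_ensemble()` first rewires a scaffold for each null
and then applies the strength-preserving step to that scaffold. The
scaffold seed for null *i* is a deterministic hash of the master seed and
*i* alone, so ensembles built with different algorithms under the same
master seed share their binary topologies null-by-null, and results are
independent of generation order — the property that makes parallel
scheduling immaterial. Execution itself is serial.

## Evaluation stack

*Metrics.* Clustering is the mean triangle intensity
$C_u = \frac{2}{k_u(k_u-1)}\sum_{ij}(w_{ui}w_{ij}w_{ju})^{1/3}$ with
weights scaled by the network maximum; nodes of degree < 2 score 0, and the
network average runs over all nodes. Characteristic path length maps
weights to lengths (`1/w` by default; `-log w` for unit-scaled connectome
weights, with explicit domain errors rather than silent rescaling) and
averages Dijkstra shortest paths over unordered pairs, erroring on
disconnected input. Strength assortativity uses the symmetric edge-wise
correlation form, each undirected edge contributing once. Modularity runs
Louvain 250 times by default with a freshly shuffled node order per run and
averages the quality
$Q = \frac{1}{2m}\sum_{ij}(w_{ij} - \frac{s_i s_j}{2m})\,\delta(c_i,c_j)$,
evaluated community-wise so the one-community partition scores exactly
zero. These metrics are defined for undirected positive networks and error
otherwise, matching their standard use.

*Hubs.* Right-tailedness is `p_R = P(X > Q3 + 3·IQR)` with quartiles from
the default linear-interpolation sample-quantile rule (no single estimator
is canonical for this procedure; this is the common default). The
exponential reference `exp(-(ln 4 + 3 ln 3)) = 1/108 ≈ 0.009` is computed
analytically in code, never hard-coded. Outliers use strict inequality.
Hub-partition similarity uses the z-scored Rand pair count under the
fixed-margins hypergeometric model; because the closed-form variance is
easy to mis-transcribe, the implementation is
validated in the tests against a permutation Monte-Carlo oracle (agreement
within 0.1 at 3×10⁴ draws).

*Rich club.* The club at threshold *k* is the set of nodes with degree ≥
*k*; `phi` is either the club weight itself (simplified variant — the
denominator cancels under nulls preserving degrees and the weight multiset,
which the tests assert explicitly) or the club weight over the sum of the
globally top-`E_≥k` weights (top-ranked variant, bounded in [0, 1]).
Normalization divides by the null mean; the one-sided p-value is the
fraction of nulls with a strictly greater coefficient (an exactly tying
null does not count against significance), Bonferroni-corrected over the
defined thresholds by default. Thresholds where the empirical coefficient
is undefined are dropped; nulls undefined at a given threshold are excluded
from that threshold's mean and p-value with the exclusion count reported,
rather than contaminating the average.

*Benchmarking.* Strength recovery is summarized per null by the Spearman
correlation (average ranks for ties) and the two-sample KS statistic
between strength vectors; ensembles are compared by the two-sided
Mann–Whitney U test with `CLES = 100·U/(n_a n_b)`, where U counts
first-group wins plus half-ties. The morphospace embeds each null at
(characteristic path length, mean clustering); ensemble variances use the
unbiased (n−1) convention, a choice the procedure leaves open. Subsample
convergence draws subsamples without replacement (a subsample of distinct
nulls), reports the absolute relative difference to the full-ensemble
statistic — the magnitude reading matches how such trajectories are
plotted; a signed version is available via a flag — and brackets it with a
2.5/97.5 percentile bootstrap band. At the full ensemble size the
difference is exactly zero by construction.

## The synthetic generator

`generate_synthetic()` emulates the inputs these nulls are designed for:
moderately dense graphs with right-skewed weights. Defaults are log-normal
weights (`meanlog = 0, sdlog = 1`), 30% negative edges when signed, and
enforced connectivity for unsigned networks — undirected graphs are seeded
with a uniform random spanning tree (random Prüfer sequence), directed
graphs with a random Hamiltonian cycle (the cheapest certificate of strong
connectivity), before filling the remaining edges uniformly without
replacement so the realized density is exact. What it does *not* emulate:
spatial embedding and distance-dependent weight decay, modular or
hierarchical mesoscale organization, degree–strength coupling beyond what
random placement induces, and measurement noise. Tests passing on these
fixtures therefore certify the algorithms' contracts (conservation,
convergence, ordering of strength recovery across algorithms), not any
claim about a specific empirical connectome.

## Problem sizes and defaults used in the tests

The test suite and the acceptance script exercise the stack at sizes a
desktop analysis would use for a pilot: a 200-node, 20%-density log-normal
benchmark with 50 nulls per algorithm for the strength-recovery ordering;
50 mixed fixtures of 30–200 nodes and 5–50% density for exact-conservation
checks; 100 random ≤ 8-node graphs against brute-force metric oracles; and
morphospace subsampling within a 50-null ensemble. The annealing schedule
in conservation-only checks is shortened to 20 stages (conservation is
schedule-independent); all strength-quality claims use the full default
schedule.

## Known limitations

* Rank matching is specified for undirected networks (plain or signed);
  directed inputs are rejected rather than improvised.
* Graph metrics target undirected positive networks; directed/signed
  metric variants are out of scope.
* The annealing energy is the strength mean squared error only; composite
  objectives (clustering- or geometry-preserving constraint hierarchies)
  and unbiased microcanonical samplers are not implemented.
* `p_R`-based heavy-tail detection needs enough observations for stable
  quartiles; it is a screening heuristic, not a tail-index estimate.
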