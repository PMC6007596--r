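---
title: "Mapping gene-family birth and death on a timetree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-family birth and death on a timetree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dollomap)
```

## The problem

Gene families that originate once and are only ever lost -- microRNA
families scored by presence/absence across animal genomes are the motivating
case -- carry an unusually clean evolutionary signal.  Given a fixed,
time-calibrated phylogeny (branch lengths in Myr) and a binary families x
taxa matrix, dollomap reconstructs where and when each family was gained and
lost, and turns those event maps into per-branch birth/death rates,
per-time-bin rate series with Monte-Carlo confidence intervals, and
root-to-tip lineage summaries.  A two-state maximum-likelihood model, a
consistency-index homoplasy report and a ground-truth simulator complete the
toolkit.

## The Dollo stochastic character map

Under the Dollo assumption each family is gained exactly once and never
regained.  Three observations make the mapping largely deterministic:

* the single gain must sit on the branch subtending the least-inclusive
  clade of taxa possessing the family (the terminal branch for a family
  seen in one taxon only);
* with presence fixed at the gain node and only `1 -> 0` transitions
  allowed, every internal state is forced: a node is present exactly when
  some descendant tip is present;
* each maximal all-absent subtree inside the gain clade therefore
  contributes exactly one loss, on its stem branch.

So the branch assignment of every event -- and hence every count -- is a
deterministic parsimony quantity; the only uncertainty is *when* on its
branch each event happened.  `dollo_map()` samples each event time uniformly
between the two ends of its branch and replicates the draw (1000 times by
default) to produce timing distributions.  This "deterministic placement +
stochastic timing" construction is mathematically equivalent, for counts, to
stochastic character mapping under a losses-only model with a hard presence
prior at the gain-clade root, but it never needs rejection sampling.

Because a loss branch is always a strict descendant of the gain node, its
age interval lies entirely below the gain branch's interval: a family's gain
is older than all of its losses in every replicate without any conditioning.
The code asserts this instead of resampling.

An alternative `loss_timing = "exponential"` draws loss times from a
truncated exponential anchored at the older end of the branch, mirroring the
rate-dependent waiting times a simmap-style sampler would produce; the
choice is recorded in the object and in the pipeline manifest.

### Bounds on loss counts

For every family the minimum number of losses is zero.  The maximum follows
a terminal-loss argument: a least-inclusive clade of N tips needs at least
two present tips to be defined, so at most N - 2 terminal branches can carry
losses; singletons and fully present two-tip clades admit none.
`loss_bounds()` reports the per-family interval and the summed maximum, and
the mapped counts are tested against these bounds.

## Rates, bins and lineage summaries

`branch_rates()` divides the (replicate-invariant) counts by branch duration
-- birth/death per million years; zero-length branches keep their counts but
report `NA` rates rather than infinities.  Changed branches are classified
`gains_only`, `ge75_gains` (>= 75% gains but not pure), `loss_majority`, or
`mixed`.

`rate_series()` bins event times in half-open 10-Myr bins from 720 Ma to the
present, each bin labeled by its older edge and owning events that fall
exactly on that edge.  Means and 2.5/97.5% empirical quantiles are taken
across replicates; per replicate the bin counts sum exactly to the event
total, which is tested.

`lineage_summary()` accumulates counts along each root-to-tip path (the root
stem included when the tree has one), so changes on deep shared branches are
recorded in every descendant taxon.  Two percentage conventions exist in the
literature; the default, `pct_loss = 100 * losses / gains`, is the one that
reproduces published per-lineage tables (301 gains and 22 losses give a
ratio of 13.68 and 7.31% loss), and `pct_loss_of_changes =
100 * losses / (gains + losses)` is reported alongside.  Lineages without
losses report `NA` rather than a division by zero.

`flag_rate_outliers()` implements a documented stand-in for "significantly
high/low rate" calls: branches outside the 2.5--97.5 percentiles of the
per-branch gain-rate distribution, disabled with a warning below five
usable branches.  Published analyses do not state their procedure, so the
rule in force is always recorded in the output.

## The two-state maximum-likelihood model

`fit_gainloss()` estimates a single gain rate g (0 to 1) and loss rate l
(1 to 0), shared by all families, under the continuous-time chain with
generator Q = [[-g, g], [l, -l]] on branch durations in Myr, by Felsenstein
pruning with the state at the root -- at the top of the root stem when one
exists -- fixed to absence.  Optimization is bounded quasi-Newton (L-BFGS-B)
on log-rates from five deterministic starting points, with a 1e-8 tolerance
on the log-likelihood; per-family likelihoods are rescaled during the
postorder pass to avoid underflow.  Rates are reported per Myr and also per
unit of total tree length, since published estimates do not always state
their normalization.

Three properties are worth knowing:

* the observed matrix usually contains only families present somewhere,
  which biases the gain rate upward; no ascertainment correction is applied
  here (by design -- the corresponding published estimate states none), but
  the simulator keeps unobservable families in its truth log so the bias is
  measurable;
* for genuinely loss-free data (families present in every taxon) the profile
  likelihood is maximized at the loss lower bound.  For singleton-heavy
  data it is *not*: a nonzero loss rate also explains the absences at the
  other tips by erasing deeper gains, and the optimum is interior;
* hard ancestral states (threshold 0.5, ties resolved to absence) coincide
  with the Dollo reconstruction only in the rare-gain regime
  (g << l << 1/branch-time).  At moderate rates the reversible model can
  prefer independent recent gains over one deep gain plus long maintenance,
  so likelihood-based event maps legitimately infer more flux deep in the
  tree.

`ancestral_states()` returns marginal presence probabilities from an
up-down pass (tips reproduce the data exactly), and `ml_event_map()` turns
the thresholded states into per-branch gain/loss counts that feed the same
rates and lineage summaries as the Dollo map.

## Consistency index

`fitch_steps()` counts unordered-parsimony changes per family on the fixed
rooted tree (for binary characters the count is independent of root
placement, which is tested).  `ensemble_ci()` reports the classic ratio of
minimum to actual changes summed over variable families; invariant families
are excluded from both sums, the conventional treatment.  The expected CI
for a data set of a given size, `expected_ci()`, uses log-linear curves in
taxon count calibrated to reference levels reported for comparative
compilations of categorical (about 0.50 at 35 taxa) and molecular (about
0.64) matrices; the original regression coefficients behind those reference
levels are unpublished, so the curves here are explicit, documented
anchors, and any other coefficient pair can be supplied and is echoed in
the result.

## The simulator and what passing tests mean

`sim_gainloss_matrix()` realizes the generating process the Dollo map
assumes: family origins are a Poisson process over branch time (optionally
modulated by per-branch burst multipliers and a step function of time),
followed by irreversible exponential losses down-tree.  Families that lose
all descendants are excluded from the emitted matrix -- as in real
annotation data -- but kept in the truth log.  `inject_noise()` adds the
two corruption modes of uncurated archives (per-tip false-negative masking
and spurious singleton false positives) with a complete manifest, and
`recovery_experiment()` runs simulate -> map -> rates -> fit end to end.

Default conditions were chosen once to emulate a curated metazoan-scale
study: a 35-tip, 720-Ma ultrametric fixture tree (Yule topology, root age
700 Ma plus a 20-Myr stem; about 8,600 Myr of total branch time);
`gain_intensity = 0.13` families/Myr, giving roughly 1,100 observable
families; and `loss_rate = 8e-4`/Myr per lineage, which leaves about 90% of
observable families without a single loss -- the low-loss regime reported
for curated miRNA data.  ML recovery checks use 2,000 characters at
g = 0.05, l = 0.01 per Myr.

Two caveats bound what a passing suite shows about real data.  First, Dollo
parsimony is a lower bound on true losses: a clade lost entirely on one
side of the gain leaves no trace, so the mapped count equals the *minimal*
history (verified against an independent dynamic program), not necessarily
the true one; under the default conditions about 93% of families are exact.
Second, the simulator draws loss times exponentially while the mapper's
default timing is uniform, so timing distributions -- not counts -- differ
slightly between generator and mapper by construction.  The generator also
does not emulate correlated annotation error between related taxa, gene
conversion, or family misassignment.

## Numerical choices

* Ages anchor the deepest root-to-tip path's tip at 0 Ma; non-contemporary
  tips are permitted.
* Branch durations must satisfy `start - end` to 1e-9; zero-length branches
  collapse event times to the shared node age.
* Replicate r of a map runs on a stream seed derived deterministically from
  the master seed, so any replicate can be reproduced in isolation.
* Events exactly on a bin edge belong to the younger bin; an event exactly
  at 0 Ma joins the youngest bin.
* Ancestral-state ties at probability 0.5 resolve to absence.
* Unknown matrix cells (`?`) are rejected by default; an explicit
  `unknown = "absent"` policy is available for archival data.

## A worked run

```{r, eval = FALSE}
tree <- read_timetree(system.file("extdata", "timetree35_synthetic.nwk",
                                  package = "dollomap"))
sim <- sim_gainloss_matrix(tree, gain_intensity = 0.13, loss_rate = 8e-4,
                           seed = 1)
res <- run_dollo_pipeline(sim$matrix, tree, out_dir = "run1",
                          n_reps = 1000, seed = 1)
summary(res$dollo)
res$ci
```

The pipeline writes `events.tsv`, `branch_rates.tsv`, `rate_series.tsv`,
`lineage_summaries.tsv`, `loss_histogram.tsv`, `loss_bounds.tsv`,
`ml_rates.json`, `ci_report.json` and a `manifest.json` echoing every
convention in force.

## Limitations

The mapper assumes the input tree and matrix are correct: it has no model
of annotation error (use the noise injector to study that), no per-family
rate variation in the ML stage, and no ascertainment-bias correction.
Bayesian tree inference under stochastic Dollo models, and the curation of
the input matrix itself, are out of scope.
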