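# dollomap

Birth and death of single-origin gene families — microRNA families scored by
presence/absence across animal genomes are the motivating case — mapped onto
a fixed time-calibrated phylogeny.

Many gene families obey a Dollo process: gained once, lost perhaps a few
times, never regained. For such characters, given a rooted timetree (branch
lengths in Myr) and a binary families × taxa matrix, the placement of every
event is a parsimony quantity: the gain sits on the branch subtending the
least-inclusive clade of presence (the terminal branch for singletons), and
each maximal all-absent subtree inside that clade puts one loss on its stem
branch. Only the *timing* of events is uncertain. `dollomap` samples event
times uniformly along their branches, replicates the draw (1,000× by
default), and summarizes:

* **per-branch rates** — gains/losses per Myr, with branches classified
  gains-only, ≥75 % gains, or loss-majority;
* **rate series** — events per 10-Myr bin from 720 Ma to the present, with
  means and 95 % Monte-Carlo intervals across replicates;
* **lineage summaries** — cumulative gains and losses root→tip, with the
  gain:loss ratio and percentage loss (100 × losses/gains);
* **loss bounds** — per family, min 0 and max *N* − 2 for a least-inclusive
  clade of *N* tips;
* **ML rates** — a global gain rate *g* and loss rate *l* under the
  asymmetric two-state chain *Q* = [[−g, g], [l, −l]], root fixed to
  absence, fitted by Felsenstein pruning + bounded quasi-Newton, with
  marginal ancestral states and a likelihood-based event map as a
  robustness check;
* **homoplasy** — Fitch step counts and the ensemble consistency index
  CI = Σmin/Σactual, with expected-CI reference curves by taxon count;
* **a simulator** — Poisson gains over branch time with irreversible
  exponential losses, plus an annotation-noise injector (false-negative
  masking, spurious singletons) with a full corruption manifest, so every
  stage can be validated against known ground truth.

## Worked example

```r
library(dollomap)
tree <- read_timetree(system.file("extdata", "timetree35_synthetic.nwk",
                                  package = "dollomap"))
sim <- sim_gainloss_matrix(tree, gain_intensity = 0.13, loss_rate = 8e-4,
                           seed = 1)
dm <- dollo_map(sim$matrix, tree, n_reps = 200, seed = 1)
summary(dm)
#> Dollo map of 969 families, 200 replicates
#>   total losses: 146 of a possible 1326
#>   families with >=1 loss: 74 (92.4% never lost)
#>   losses per family:
#> losses
#>   0   1   2   3   4   5
#> 895  36  19   8   7   4
```

969 families survived to be observable; the map places 146 losses (the
terminal-loss rule caps the total at 1,326), and 92.4 % of families are
never lost — the low-loss regime typical of curated presence/absence data.
Root-to-tip summaries use the conventions of published lineage tables:

```r
head(lineage_summary(dm), 4)
#>   tip gains losses ratio pct_loss pct_loss_of_changes
#> 1 t31    69      0    NA       NA                  NA
#> 2 t35    74      0    NA       NA                  NA
#> 3 t30    77      1    77 1.298701            1.282051
#> 4 t26    75      3    25 4.000000            3.846154

ensemble_ci(sim$matrix, tree)
#> Consistency index report
#>   ensemble CI: 0.8849 over 969 variable families
#>   expected for 35 taxa: categorical ~0.50, molecular ~0.64
#>   homoplastic families: 74
```

The ensemble CI of 0.88 far exceeds the ~0.50 expected of a comparable
categorical matrix: single-origin characters are weakly homoplastic, which
is what makes them attractive phylogenetic markers.

`run_dollo_pipeline(matrix, tree, out_dir, ...)` runs every stage and
writes TSV tables, JSON reports and a manifest echoing all conventions in
force; identical config + seed gives byte-identical output.

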