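# islandclock

Bayesian node dating with probabilistic island-age calibrations, and a
formal test of whether each calibrated divergence is concomitant with,
older than, or younger than the formation of its island.

## The problem

Phylogeographic studies of hot-spot archipelagos routinely use the
geological age of a volcanic island as a **fixed** calibration on the node
where the island's endemics diverged. That converts relative branch
lengths into absolute time, but it also hard-codes the very hypothesis a
timescale should be able to test — that cladogenesis happened exactly when
the island emerged. `islandclock` is for molecular evolutionists and
island biogeographers who want to re-analyse such datasets with the
calibration treated **probabilistically**, so the sequence data can pull a
divergence away from the island age, and the association between island
formation and speciation becomes a testable null hypothesis instead of an
assumption.

## The method

For a calibrated node with island age $m$ (Ma), two calibration schemes
are built from the same table:

* **probabilistic** — a normal prior $\mathcal{N}(m, s^2)$ with
  $s = \operatorname{round}_{0.1}(m / z_{0.99})$, $z_{0.99} \approx
  2.3263$, so the prior's one-sided 99% lower limit reaches the present
  (for $m = 2.6$ Ma this gives $s = 1.1$ Ma);
* **punctual** — the fixed-age practice emulated as a hard-bounded uniform
  on $[m - 0.01,\, m + 0.01]$ Ma.

Node ages are inferred on a fixed rooted topology under GTR+Γ (6
categories) with a strict or independent-lognormal relaxed clock, by
Metropolis-within-Gibbs MCMC with exact (pruning) likelihoods. Two
replicate chains are run per scheme; every parameter must reach an
effective sample size ≥ 200 and replicate node-age means must agree within
two combined Monte-Carlo standard errors before assessment proceeds.

Each calibrated node is then summarized by

* the posterior mean and 95% HPD interval of its age,
* the Kullback–Leibler divergence
  $\mathrm{KL}(\text{posterior} \,\|\, \text{normal prior})$ in nats —
  near zero when the data add nothing beyond the calibration,
* a classification: `pre_island` if the island age lies below the 95%
  HPD (the split predates the island), `post_island` if above it,
  `concomitant_not_rejected` otherwise,
* the absolute difference between the probabilistic-scheme and
  punctual-scheme posterior means — what fixing the calibration imposed.

A synthetic-data module (Yule time-trees with one node pinned at
`island_age + offset`, GTR+Γ sequences under either clock) generates
datasets with known truth, so the whole pipeline is validated by
parameter-recovery and size/power simulations.

## A worked example

Simulate a 8-taxon radiation (root 8 Ma, 1.5 kb, strict clock) in which
the true divergence of the "island" clade is 4.6 Ma — 2 Ma *older* than
the nominal 2.6 Ma island age — then date it under both schemes with a
tight root anchor:

```r
library(islandclock)

sc  <- simulation_scenario(n_taxa = 8, root_age = 8, island_age = 2.6,
                           divergence_offset = 2, clock_kind = "strict",
                           clock_mean_rate = 0.01, n_sites = 1500, seed = 11)
sim <- simulate_scenario(sc)

calib <- rbind(sim$calibration,
               data.frame(taxonA = "t4", taxonB = "t5",
                          island_name = "root_anchor", island_age_Ma = 8))
schemes <- build_schemes(calib)
schemes$normal$param2[2] <- 0.4             # tight, correct root anchor
schemes$punctual[2, c("prior_kind", "param1", "param2")] <-
  schemes$normal[2, c("prior_kind", "param1", "param2")]

tn <- lapply(c(3201, 3202), function(s)
  mcmc_run(sim$alignment, sim$tree$phy, schemes$normal, clock_kind = "strict",
           settings = mcmc_settings(n_samples = 1000, thin = 10, seed = s)))
tp <- lapply(c(3103, 3104), function(s)
  mcmc_run(sim$alignment, sim$tree$phy, schemes$punctual, clock_kind = "strict",
           settings = mcmc_settings(n_samples = 1000, thin = 10, seed = s)))

check_and_extend(tn, 200)
#> Convergence diagnostics: PASS (min ESS 296, threshold 200)

pool <- function(l) do.call(rbind, lapply(l, as.data.frame))
assess_all(pool(tn), sim$tree$phy, schemes$normal, trace_punctual = pool(tp))
#>   node island_name island_age post_mean hpd_low hpd_high  kl_div
#> 1    9 root_anchor        8.0      7.96    7.23     8.74 0.00901
#> 2   14      island        2.6      3.68    3.07     4.36 1.21801
#>             classification scheme_diff
#> 1 concomitant_not_rejected       0.684
#> 2               pre_island       1.082
```

Reading the output: under the probabilistic calibration the island node is
dated 3.68 Ma with 95% HPD (3.07, 4.36) — the 2.6 Ma island age falls
below the interval, so divergence-at-island-formation is rejected in
favour of an older split (`pre_island`), the correct call: the simulated
truth is 4.6 Ma, and the posterior sits between the truth and the
calibration that pulls it down. The large prior–posterior divergence
(KL ≈ 1.2 nats) says the sequences carry real information beyond the
calibration, and the punctual scheme — which pins the node at 2.6 Ma —
misdates the node by more than 1 Ma (`scheme_diff`). The root anchor, in
contrast, shows KL ≈ 0.01: its posterior is indistinguishable from its
prior.

The same analysis runs end to end from files (FASTA/relaxed-PHYLIP
alignment, newick topology, tab-separated calibration table) through
`pipeline_config()` + `run_pipeline()`, which also applies the
p-distance < 0.003 de-duplication filter, writes both scheme files,
replicate traces, the diagnostics report, per-node density curves and a
manifest of every artifact and seed.

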