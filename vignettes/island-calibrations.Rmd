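---
title: "Testing island-age calibrations with probabilistic node priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing island-age calibrations with probabilistic node priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandclock)
```

## The problem

Molecular dating of island radiations routinely converts a volcanic
island's geological age into a *fixed* ("punctual") calibration on the
node where the island's endemics split from their relatives. That
practice hard-codes the biogeographic hypothesis it should be testing:
it assumes cladogenesis happened exactly when the island emerged, so the
resulting timescale can never reveal a colonization that lagged island
formation, or a divergence that predates it (old taxa on young islands).

`islandclock` implements the alternative workflow: treat the island age
as *probabilistic* calibration information, let the sequence data pull
the node age away from it, and then test formally whether the posterior
age distribution is compatible with divergence at island formation.
The package covers the full path — data preparation, calibration
construction, Bayesian node dating by MCMC, convergence monitoring, and
the prior–posterior conflict assessment — plus a synthetic-data
generator so that every stage can be validated against known truth.

## Calibration construction

Each calibrated node is designated by a pair of taxa (its MRCA) together
with an island age $m$ in Ma. Two parallel schemes are built from the
same table (`build_schemes()`):

* **Probabilistic**: a normal prior $\mathcal{N}(m, s^2)$ whose standard
  deviation is chosen so that the one-sided 99% lower limit of the
  distribution reaches the present:
  $s = \operatorname{round}_{0.1}(m / z_{0.99})$, with
  $z_{0.99} \approx 2.3263$ (`compute_prior_sd()`). The island age stays
  the prior mode while the node is free to explore ages from zero up.
  The rounding to 0.1 Ma matches how such calibrations are reported.
* **Punctual**: a fixed-age calibration emulated as a narrow uniform
  with hard bounds, $[m - 0.01,\, m + 0.01]$ Ma
  (`punctual_interval()`); ages outside carry zero probability.

An ambiguity worth recording: a "99% lower limit reaching zero" could be
read one-sided ($z = 2.3263$) or two-sided ($z = 2.5758$). Only the
one-sided reading, rounded to the nearest 0.1 Ma, reproduces all eight
published island-calibration SDs (2.6→1.1, 3.7→1.6, 1.6→0.7, 0.5→0.2,
5.2→2.2, 4.7→2.0, 3.0→1.3, 0.6→0.3), so that is the rule implemented;
the tests pin all eight cases.

Normal calibration densities are *not* truncated at zero when evaluated
(`prior_log_density()`): the dating model's node-age support (a node is
older than its children, which are no younger than the present) imposes
nonnegativity and implicitly renormalizes. This keeps the reference
density used by the conflict statistic simple.

## The dating model

`mcmc_run()` samples absolute node ages on a **fixed rooted binary
topology** — topology inference is deliberately out of scope; the tree
is an input, as it is when re-analysing a published study.

* **Substitution model**: GTR with empirical base frequencies and
  sampled exchangeabilities (GT ≡ 1), plus discrete-gamma rate variation
  with 6 categories by default ("GTR+G6") and a sampled shape α.
  Likelihoods are exact Felsenstein pruning (site-pattern compressed,
  implemented in C++); gaps and ambiguity codes are partial missing
  data. No approximate-likelihood shortcut is used — at the problem
  sizes this package targets the exact likelihood is affordable.
* **Clock**: strict, or independent lognormal branch rates
  (`independent_lognormal`, the default), i.e. i.i.d. lognormal rates
  with expectation µ and log-sd σ. The uncorrelated-lognormal choice
  mirrors the standard relaxed clock of the mainstream dating programs;
  it is configurable because reported re-analyses rarely state the
  clock form.
* **Node-age prior**: calibration densities at calibrated nodes;
  uncalibrated node ages are uniform order statistics between their
  path constraints given the root age (contributing
  $t_\mathrm{root}^{-k}$ for $k$ free nodes, MCMCTREE-flavored); if the
  root is uncalibrated it gets a vague gamma (shape 2, mean twice the
  oldest calibration mean).
* **Hyperpriors**: µ ~ lognormal(log 0.01, 1²) per Ma; σ ~
  exponential(mean 0.3); α ~ lognormal(0, 0.5²); exchangeabilities
  i.i.d. lognormal(0, 1²). All overridable via `hyper =`.

### Sampler design

One sweep updates: every non-root internal node age by a uniform redraw
inside its instantaneous feasible interval (oldest child, parent),
intersected with any hard calibration bounds — a symmetric proposal that
by construction never violates hard bounds; the root age by a sliding
window reflected at its lower bound; µ, α and one exchangeability per
sweep by multiplicative proposals; under the relaxed clock, every branch
rate and σ likewise. A whole-tree scale move multiplies all ages by $c$
and divides all rates by $c$, leaving the likelihood exactly invariant
(only rate × time products are data-constrained; absolute time comes
from the calibrations) — it decorrelates depth and rate cheaply. The
move is skipped when the scheme contains hard-bounded calibrations,
where any appreciable scaling leaves the bounds and would never accept.

Proposal scales auto-tune toward moderate acceptance **during burn-in
only** (default 25% of cycles), preserving detailed balance afterwards.
Defaults mirror the published sampling regime: record every 100th cycle
until 10,000 samples, two replicate chains. A block with zero accepted
proposals after burn-in raises a diagnostic error recommending window
adjustment rather than returning a silently frozen trace. Chains are
bit-reproducible from their integer seed.

Prior-only sampling (`aln = NULL`) sets the likelihood to 1; with a
single calibrated node, the sampled marginal at that node provably
equals the calibration density truncated to nonnegative ages, which is
what the validation tests assert (Kolmogorov–Smirnov distance < 0.02 at
10,000 thinned samples).

## Convergence

`ess()` implements the truncated-autocorrelation estimator used by
common trace viewers: $n / (1 + 2\sum\hat\rho_k)$, summing to the first
nonpositive autocorrelation. `check_and_extend()` applies the working
rule — every parameter must reach ESS ≥ 200 in *both* replicates — and
checks replicate agreement of each node-age mean to within two combined
Monte-Carlo standard errors — a concrete, scale-free form of the common
practice of comparing replicate chains. Note the 2-SE rule is a ~5%
false-alarm test per node, so occasional failures on perfectly converged
multi-node runs are expected; rerunning longer resolves them. Failing
reports carry an extension factor,
`ceiling(200 / min ESS)`; the pipeline halts before assessment when
diagnostics fail, and the rerun rule extends chains rather than
restarting them.

## The conflict test

For each calibrated node, `assess_all()` reports:

* the posterior mean and 95% HPD of the node age (`hpd_interval()`,
  Chen–Shao shortest-interval estimator);
* the **Kullback–Leibler divergence** between the normal calibration
  prior and the posterior, estimated as the sample average of
  $\log \hat q(x_i) - \log p(x_i)$ with $\hat q$ a Gaussian KDE
  (Silverman bandwidth) over the posterior draws (nats; negative noise
  clamped at zero). KL(posterior‖prior) — the information the data add
  beyond the calibration — is the default direction; the published
  description does not fix the direction, so it is switchable. A value
  near zero means the data are silent about the node's age beyond the
  calibration itself;
* the classification: the concomitant-cladogenesis null is rejected
  only when the island age falls *strictly outside* the 95% HPD —
  `pre_island` when the whole interval is older, `post_island` when it
  is younger, `concomitant_not_rejected` otherwise (ties at an endpoint
  are conservative, by design);
* the absolute difference between the probabilistic-scheme and
  punctual-scheme posterior means (`compare_schemes()`), quantifying
  what the fixed calibration imposed.

A hard-bounded prior cannot serve as the KL reference (it has zero
density almost everywhere the posterior lives), so the divergence is
always taken against the normal calibration; `kl_divergence()` enforces
this with an informative error.

## Synthetic data: what it emulates and what it does not

The generator (`simulation_scenario()` / `simulate_scenario()`) builds
the study conditions end to end: a pure-birth (Yule) time-tree
conditioned on the tip count and rescaled to the root age; one internal
node — the "island node" — pinned exactly at
`island_age + divergence_offset`, so the truth can sit at, before, or
after island formation; strict or independent-lognormal branch rates;
and sequences evolved site-independently under GTR+G6 with the root
drawn from the stationary frequencies.

Defaults describe a plausible single-radiation multilocus dataset: 20
taxa, 2 kb, a 10 Ma radiation, the 2.6 Ma Oahu age as the island
calibration, mean rate 0.005 substitutions/site/Ma with lognormal
spread σ = 0.3, a transition-biased GTR (AG = CT = 4) with unequal
frequencies (0.3, 0.2, 0.2, 0.3) and α = 0.5 over six gamma categories.
Sequence lengths and tip counts bracket the re-analysed empirical
datasets (~10–60 taxa, 1–5 kb).

Not emulated: indels (gaps appear only if present in real input),
codon structure, heterotachy, gene-tree discordance, and topology
error — the generator evolves data on the same fixed topology the
dating engine conditions on. Passing tests therefore validate the
calibration construction, the sampler, and the decision rule under a
correctly specified model; they do not certify robustness to model
misspecification on real data.

## Validation: problem sizes and what the tests show

The test suite works at deliberately desk-sized problems so the whole
suite runs in minutes:

* analytic oracles: JC closed forms, exhaustive-summation likelihoods
  on 4-taxon toys, AR(1) ESS, normal/uniform HPDs, normal–normal KL;
* prior-only MCMC against the truncated calibration density
  (KS < 0.02 at 10,000 samples) and hard-bound containment for the
  punctual scheme;
* parameter recovery: strict-clock data, 7 taxa, 2,000 sites, true
  root 5 Ma, a correct normal root calibration (5 ± 0.5 Ma) — all true
  internal-node ages must fall inside their 95% HPDs in at least 17 of
  20 seeded replicates (a joint coverage requirement across all five
  internal nodes, stricter than per-node 95% coverage);
* operating characteristics of the island test: 7 taxa, 1,500 sites,
  strict clock, island age 2.6 Ma with its rule-derived normal prior
  (± 1.1 Ma), and a tight correct root anchor (root age ± 5%) so
  the timescale is identified; with the true divergence at the island
  age the null must survive in ≥ 18/20 seeds, with the truth at twice
  the island age the test must call `pre_island` in ≥ 16/20 seeds.
  The root anchor's 5% SD is the package's choice of an "informative
  secondary calibration"; with only the tested node calibrated the
  island-node posterior cannot move away from its prior (rate and time
  are confounded) and the test would have no power by construction.

## Numerical choices and edge cases

* Sequence de-duplication (`dedupe_alignment()`) uses the uncorrected
  p-distance on jointly unambiguous columns, greedy in input order,
  threshold 0.003 — at such small distances all common model
  corrections coincide to four decimals, so the uncorrected distance is
  used. A pair with no comparable column is kept as distinct. The
  filter is deterministic and idempotent.
* Pattern-compressed pruning rescales partial likelihoods per node when
  they drop below 1e-80, so long trees do not underflow.
* KDE densities are floored at 1e-300 before logs.
* The discrete-gamma category rates are the exact category means
  (incomplete-gamma formula), not medians.
* Degenerate inputs error early and specifically: ragged alignments,
  duplicate taxa, polytomies (naming the offending node), tip
  "calibrations", infeasible pinned ages, constant series handed to
  `ess()` or `hpd_interval()`, empty calibration tables.

## A worked run

```{r, eval = FALSE}
sc <- simulation_scenario(n_taxa = 12, root_age = 10, island_age = 2.6,
                          divergence_offset = 2, clock_kind = "strict",
                          n_sites = 1500, seed = 7)
cfg <- pipeline_config(out_dir = "island_run", scenario = sc,
                       clock_kind = "strict",
                       settings = mcmc_settings(n_samples = 2000, thin = 10,
                                                seed = 7),
                       ess_threshold = 100, seed = 7)
res <- run_pipeline(cfg)
res$assessment
```

The pipeline writes the deduplicated alignment, both scheme files, two
replicate traces per scheme, the diagnostics report, the per-node
assessment with its density curves, and a manifest of artifacts and
seeds — rerunning with the same configuration and master seed
reproduces every file byte for byte.

## Known limitations

* The punctual scheme's hard bounds make the whole-tree scale move
  useless, so punctual chains mix through single-node and rate moves
  only; deep uncalibrated nodes then need longer chains (the
  diagnostics catch this).
* KL(posterior‖prior) via KDE is biased slightly upward for very narrow
  posteriors relative to the bandwidth; the conflict classification
  never depends on KL alone, only on the HPD test.
* The uniform-order-statistics prior on uncalibrated ages is one of
  several defensible choices; with informative data its influence is
  minor, but prior-only marginals at *uncalibrated* nodes should not be
  over-interpreted.
* Two replicate chains support the 2-SE agreement check; there is no
  multi-chain R-hat machinery here.
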