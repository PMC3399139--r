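test_that("Yule tree simulation respects size, root age and seed", {
  tr <- simulate_time_tree(3, 4.2, seed = 1)
  expect_equal(tr$phy$Nnode, 2L)
  expect_equal(root_age <- tr$ages[4], 4.2)
  expect_true(ape::is.ultrametric(dated_to_phylo(tr)))

  tr2 <- simulate_time_tree(3, 4.2, seed = 1)
  expect_identical(tr, tr2)
  tr3 <- simulate_time_tree(3, 4.2, seed = 2)
  expect_false(identical(tr$ages, tr3$ages))
})

test_that("second-oldest node age matches an independent pure-birth sampler", {
  # independent forward simulator keeping only split times (no tree built)
  indep_second_age <- function(n, root_age) {
    t <- 0; times <- 0
    for (k in 2:(n - 1)) {
      t <- t + rexp(1, k)
      times <- c(times, t)
    }
    present <- t + rexp(1, n)
    ages <- (present - times) * root_age / present
    sort(ages, decreasing = TRUE)[2]
  }
  set.seed(99)
  n_rep <- 600
  oracle <- replicate(n_rep, indep_second_age(10, 10))
  mine <- vapply(seq_len(n_rep), function(i) {
    tr <- simulate_time_tree(10, 10, seed = 5000 + i)
    sort(tr$ages[-(1:10)], decreasing = TRUE)[2]
  }, numeric(1))
  se <- sqrt(var(oracle) / n_rep + var(mine) / n_rep)
  expect_lt(abs(mean(oracle) - mean(mine)), 3 * se)
})

test_that("pin_node_age sets ages exactly within feasibility bounds", {
  tr <- simulate_time_tree(8, 10, seed = 3)
  root <- ape::Ntip(tr$phy) + 1L
  expect_equal(pin_node_age(tr, root, tr$ages[root])$ages, tr$ages)

  nd <- root + 1L
  par <- tr$phy$edge[tr$phy$edge[, 2] == nd, 1]
  expect_error(pin_node_age(tr, nd, tr$ages[par] + 1), "infeasible")

  kids <- tr$phy$edge[tr$phy$edge[, 1] == nd, 2]
  mid <- (max(tr$ages[kids]) + tr$ages[par]) / 2
  expect_equal(pin_node_age(tr, nd, mid)$ages[nd], mid)
})

test_that("branch-rate simulation honours the clock model", {
  tr <- simulate_time_tree(10, 10, seed = 4)
  strict <- simulate_rates(tr, "strict", 0.01)
  expect_true(all(strict == 0.01))

  degen <- simulate_rates(tr, "independent_lognormal", 0.01, 0, seed = 1)
  expect_true(all(abs(degen - 0.01) < 1e-12))

  set.seed(11)
  r <- rlnorm(10000, log(0.02) - 0.6^2 / 2, 0.6)
  expect_lt(abs(mean(r) - 0.02), 3 * sd(r) / sqrt(10000))
})

test_that("sequence simulation collapses to the root draw at rate ~ 0", {
  tr <- simulate_time_tree(5, 10, seed = 6)
  aln <- simulate_alignment(tr, 1e-12, test_model(), 200, seed = 7)
  m <- unclass(aln)
  for (i in 2:nrow(m)) expect_equal(unname(m[i, ]), unname(m[1, ]))
})

test_that("simulated base composition matches the stationary frequencies", {
  freqs <- c(0.1, 0.2, 0.3, 0.4)
  mod <- substitution_model(base_freqs = freqs, gamma_shape = 1)
  tr <- as_dated_tree(read_tree("((a:1,b:1):1,(c:1,d:1):1);"))
  aln <- simulate_alignment(tr, 0.05, mod, 50000, seed = 8)
  counts <- table(factor(unclass(aln), levels = c("A", "C", "G", "T")))
  p_hat <- as.numeric(counts) / sum(counts)
  # 4 correlated sequences; use the per-sequence site count for the SE
  se <- sqrt(freqs * (1 - freqs) / 50000)
  expect_true(all(abs(p_hat - freqs) < 3 * se * 2))
})

test_that("two-taxon JC divergence matches the closed form", {
  tr <- as_dated_tree(read_tree("(a:5,b:5);"))
  mod <- substitution_model(n_categories = 1L)
  aln <- simulate_alignment(tr, 0.01, mod, 50000, seed = 9)  # total path 0.1
  p <- mean(unclass(aln)[1, ] != unclass(aln)[2, ])
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 50000))
})

test_that("scenario generation pins the island node and emits truth files", {
  sc <- simulation_scenario(n_taxa = 8, root_age = 10, island_age = 2.6,
                            divergence_offset = 1, clock_kind = "strict",
                            n_sites = 300, seed = 21)
  sim <- simulate_scenario(sc)
  expect_equal(sim$true_age, 3.6)
  expect_equal(sim$tree$ages[sim$island_node], 3.6)
  expect_equal(resolve_mrca(sim$tree, c(sim$calibration$taxonA,
                                        sim$calibration$taxonB)),
               sim$island_node)
  d <- withr::local_tempdir()
  paths <- write_scenario(sim, d)
  expect_true(all(file.exists(paths)))
  truth <- read.delim(paths["truth"])
  expect_equal(truth$true_age_Ma, 3.6)
  expect_equal(truth$offset, 1)
  back <- read_alignment(paths[["alignment"]])
  expect_identical(unclass(back), unclass(sim$alignment))

  expect_error(simulation_scenario(island_age = 2, divergence_offset = -2),
               "must lie in")
})

test_that("true parameters beat grossly wrong rates under the model's own likelihood", {
  mod <- test_model()
  wins <- 0L
  for (s in 1:20) {
    tr <- simulate_time_tree(6, 8, seed = 300 + s)
    aln <- simulate_alignment(tr, 0.01, mod, 1000, seed = 400 + s)
    ll_true <- pruning_loglik(aln, tr, 0.01, mod)
    ll_bad <- pruning_loglik(aln, tr, 0.1, mod)
    expect_true(is.finite(ll_true))
    if (ll_true > ll_bad) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
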