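test_that("GTR transition matrices are stochastic and hit known limits", {
  mod <- test_model(shape = 1)
  expect_equal(gtr_transition_matrix(mod, 0), diag(4), ignore_attr = TRUE)
  P <- gtr_transition_matrix(mod, 0.37)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P >= -1e-15))

  jc <- substitution_model()
  Pjc <- gtr_transition_matrix(jc, 0.1)
  expect_equal(unname(diag(Pjc)), rep(0.25 + 0.75 * exp(-4 * 0.1 / 3), 4),
               tolerance = 1e-10)
  expect_equal(unname(Pjc[1, 2]), 0.25 - 0.25 * exp(-4 * 0.1 / 3),
               tolerance = 1e-10)

  Pinf <- gtr_transition_matrix(mod, 100)
  for (i in 1:4) expect_equal(unname(Pinf[i, ]), mod$freqs, tolerance = 1e-8)
})

test_that("two-taxon single-site pruning matches the JC closed form", {
  tr <- as_dated_tree(read_tree("(a:5,b:5);"))
  mod <- substitution_model(n_categories = 1L)
  same <- dna_alignment(c(a = "A", b = "A"))
  diffb <- dna_alignment(c(a = "A", b = "C"))
  t <- 0.1  # total path length at rate 0.01
  expect_equal(pruning_loglik(same, tr, 0.01, mod),
               log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))), tolerance = 1e-10)
  expect_equal(pruning_loglik(diffb, tr, 0.01, mod),
               log(0.25 * (0.25 - 0.25 * exp(-4 * t / 3))), tolerance = 1e-10)
})

test_that("pruning equals exhaustive state summation on a 4-taxon toy", {
  tr <- as_dated_tree(read_tree("((a:1,b:1):1.5,(c:2,d:2):0.5);"))
  mod <- substitution_model(exchangeabilities = c(2, 5, 1, 1.5, 6, 1),
                            base_freqs = c(0.35, 0.15, 0.2, 0.3),
                            gamma_shape = 0.7, n_categories = 3L)
  rate <- 0.08
  aln <- dna_alignment(c(a = "AC", b = "AY", c = "G-", d = "TA"))

  brute <- function() {
    masks <- list(A = 1L, C = 2L, G = 4L, T = 8L, Y = 10L, "-" = 15L)
    phy <- tr$phy
    gr <- discrete_gamma_rates(0.7, 3)
    total <- 0
    for (site in 1:2) {
      obs <- lapply(rownames(aln), function(tx) {
        m <- masks[[unclass(aln)[tx, site]]]
        which(bitwAnd(m, 2^(0:3)) > 0)
      })
      names(obs) <- rownames(aln)
      sitelik <- 0
      for (g in seq_along(gr)) {
        Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
          gtr_transition_matrix(mod, rate * gr[g] *
            (tr$ages[phy$edge[e, 1]] - tr$ages[phy$edge[e, 2]])))
        for (s5 in 1:4) for (s6 in 1:4) for (s7 in 1:4) {
          st <- c(rep(NA, 4), s5, s6, s7)
          p <- mod$freqs[s5]
          for (e in seq_len(nrow(phy$edge))) {
            par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
            p <- p * if (ch <= 4)
              sum(Ps[[e]][st[par], obs[[phy$tip.label[ch]]]])
            else Ps[[e]][st[par], st[ch]]
          }
          sitelik <- sitelik + p / length(gr)
        }
      }
      total <- total + log(sitelik)
    }
    total
  }
  expect_equal(pruning_loglik(aln, tr, rate, mod), brute(), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("site independence: duplicating every site doubles the log-likelihood", {
  tr <- simulate_time_tree(5, 6, seed = 31)
  mod <- test_model()
  aln <- simulate_alignment(tr, 0.01, mod, 120, seed = 32)
  m <- unclass(aln)
  dbl <- dna_alignment(cbind(m, m))
  expect_equal(pruning_loglik(dbl, tr, 0.01, mod),
               2 * pruning_loglik(aln, tr, 0.01, mod), tolerance = 1e-9)
})

test_that("pruning agrees with an independent GTR+G implementation", {
  skip_if_not_installed("phangorn")
  tr <- simulate_time_tree(7, 9, seed = 33)
  mod <- substitution_model(exchangeabilities = c(1.3, 3.8, 0.9, 1.1, 4.6, 1),
                            base_freqs = c(0.28, 0.22, 0.24, 0.26),
                            gamma_shape = 0.6, n_categories = 6L)
  aln <- simulate_alignment(tr, 0.012, mod, 600, seed = 34)
  phy <- dated_to_phylo(tr)
  phy$edge.length <- phy$edge.length * 0.012
  pd <- phangorn::phyDat(unclass(aln), type = "DNA")
  fit <- phangorn::pml(phy, pd, model = "GTR", k = 6, shape = 0.6,
                       bf = mod$freqs,
                       Q = mod$exch[c(1, 2, 3, 4, 5, 6)])
  expect_equal(pruning_loglik(aln, tr, 0.012, mod), fit$logLik,
               tolerance = 1e-6)
})

test_that("taxon mismatch between tree and alignment is caught", {
  expect_error(
    pruning_loglik(dna_alignment(c(a = "A", b = "A", c = "A", d = "A")),
                   as_dated_tree(read_tree("((a:1,b:1):1,(c:2,e:2):1);")),
                   0.01, test_model()),
    "absent")
})

test_that("the node-age prior honours hard bounds and unimodality", {
  phy <- read_tree("((a,b),(c,d));")
  pair <- c("a", "b")
  hard <- hard_scheme_row(pair, 2.6)
  out <- mcmc_run(NULL, phy, rbind(hard, normal_scheme_row(c("a", "d"), 8,
                                                           island = "root")),
                  clock_kind = "strict",
                  settings = mcmc_settings(n_samples = 300, thin = 2, seed = 5))
  nd <- resolve_mrca(phy, pair)
  x <- out[[paste0("age_", nd)]]
  expect_true(all(x >= 2.59 & x <= 2.61))

  # unimodality of the normal calibration at the prior level
  no <- prior_normal(2.6, 1.1)
  expect_gt(prior_log_density(no, 2.6), prior_log_density(no, 2.6 + 2.2))
  expect_gt(prior_log_density(no, 2.6), prior_log_density(no, 2.6 - 2.2))
})

test_that("chains are bit-identical under a fixed seed", {
  phy <- read_tree("((a,b),(c,d));")
  sch <- normal_scheme_row(c("a", "d"), 2.6)
  st <- mcmc_settings(n_samples = 50, thin = 2, seed = 17)
  t1 <- mcmc_run(NULL, phy, sch, "strict", st)
  t2 <- mcmc_run(NULL, phy, sch, "strict", st)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("prior-only root marginal matches the truncated calibration normal", {
  phy <- read_tree("((a,b),(c,d));")
  sch <- normal_scheme_row(c("a", "d"), 2.6)
  out <- mcmc_run(NULL, phy, sch, "strict",
                  mcmc_settings(n_samples = 4000, thin = 5, seed = 19))
  x <- out$age_5
  mu_trunc <- 2.6 + 1.1 * dnorm(-2.6 / 1.1) / pnorm(2.6 / 1.1)
  mcse <- sd(x) / sqrt(ess(x))
  expect_lt(abs(mean(x) - mu_trunc), 3 * mcse)
})

test_that("every recorded state respects the node order constraints", {
  tr <- simulate_time_tree(6, 5, seed = 41)
  mod <- test_model()
  aln <- simulate_alignment(tr, 0.01, mod, 300, seed = 42)
  sch <- normal_scheme_row(root_pair(tr), 5, 0.5)
  out <- mcmc_run(aln, tr$phy, sch, "strict",
                  mcmc_settings(n_samples = 150, thin = 2, seed = 43))
  phy <- tr$phy
  ntip <- ape::Ntip(phy)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ch <= ntip) next
    expect_true(all(out[[paste0("age_", p)]] > out[[paste0("age_", ch)]]))
  }
})

test_that("the whole-tree scale move leaves the likelihood invariant", {
  tr <- simulate_time_tree(5, 7, seed = 51)
  mod <- test_model()
  aln <- simulate_alignment(tr, 0.01, mod, 200, seed = 52)
  ll1 <- pruning_loglik(aln, tr, 0.01, mod)
  scaled <- dated_tree(tr$phy, tr$ages * 3)
  ll2 <- pruning_loglik(aln, scaled, 0.01 / 3, mod)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("the relaxed clock recovers a root age from rate-variable data", {
  tr <- simulate_time_tree(6, 5, seed = 61)
  mod <- test_model()
  rates <- simulate_rates(tr, "independent_lognormal", 0.01, 0.3, seed = 62)
  aln <- simulate_alignment(tr, rates, mod, 800, seed = 63)
  out <- mcmc_run(aln, tr$phy, normal_scheme_row(root_pair(tr), 5, 0.5),
                  "independent_lognormal",
                  mcmc_settings(n_samples = 300, thin = 3, seed = 64))
  h <- hpd_interval(out$age_7)
  expect_lt(h[1], 5); expect_gt(h[2], 4)
  expect_true(all(out$sigma > 0))
})

test_that("traces round-trip through the tab-separated log dialect", {
  phy <- read_tree("((a,b),(c,d));")
  out <- mcmc_run(NULL, phy, normal_scheme_row(c("a", "d"), 2.6), "strict",
                  mcmc_settings(n_samples = 20, thin = 1, seed = 3))
  f <- withr::local_tempfile()
  write_trace(out, f)
  back <- read_trace(f)
  expect_equal(names(back), names(as.data.frame(out)))
  expect_equal(back$age_5, out$age_5, tolerance = 1e-9)
  expect_error(read_trace(withr::local_tempfile(lines = "a\tb\n1\t2")), "state")
})
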