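test_that("HPD intervals match normal and uniform references", {
  set.seed(13)
  x <- rnorm(10000)
  h <- hpd_interval(x)
  expect_lt(abs(h[1] + 1.96), 0.08)
  expect_lt(abs(h[2] - 1.96), 0.08)

  u <- runif(10000)
  hu <- hpd_interval(u)
  w <- hu[2] - hu[1]
  expect_gt(w, 0.93); expect_lt(w, 0.97)

  expect_error(hpd_interval(rnorm(50)), "at least 100")
  expect_error(hpd_interval(rep(2, 500)), "constant")
  expect_error(hpd_interval(rnorm(500), mass = 1.2), "mass")
})

test_that("HPD agrees with an independent implementation", {
  skip_if_not_installed("coda")
  set.seed(6)
  x <- rgamma(5000, 2, 1)  # skewed posterior
  h <- hpd_interval(x)
  ref <- coda::HPDinterval(coda::mcmc(x))
  expect_equal(unname(h[1]), ref[1, "lower"], tolerance = 1e-8)
  expect_equal(unname(h[2]), ref[1, "upper"], tolerance = 1e-8)
})

test_that("KL estimator is near zero under the prior and matches the closed form", {
  pr <- prior_normal(2.6, 1.1)
  set.seed(7)
  self <- rnorm(10000, 2.6, 1.1)
  expect_lte(kl_divergence(self, pr), 0.05)

  post <- rnorm(10000, 1.1, 0.3)
  closed <- log(1.1 / 0.3) + (0.3^2 + (1.1 - 2.6)^2) / (2 * 1.1^2) - 0.5
  expect_lt(abs(kl_divergence(post, pr) - closed), 0.1)

  expect_error(kl_divergence(rnorm(2000, 2.6, 0.1),
                             prior_hard_uniform(2.59, 2.61)),
               "normal calibration")
  expect_error(kl_divergence(rnorm(100), pr), "1000")
})

test_that("narrowing the posterior at fixed mean increases the divergence", {
  pr <- prior_normal(2.6, 1.1)
  set.seed(8)
  z <- rnorm(10000)
  kls <- vapply(c(0.8, 0.4, 0.1), function(s)
    kl_divergence(1.1 + s * z, pr), numeric(1))
  expect_true(all(diff(kls) > 0))
  # and the closed form says the same
  closed <- vapply(c(0.8, 0.4, 0.1), function(s)
    log(1.1 / s) + (s^2 + 1.5^2) / (2 * 1.1^2) - 0.5, numeric(1))
  expect_true(all(diff(closed) > 0))
})

test_that("KL estimation error shrinks with the sample size", {
  pr <- prior_normal(2.6, 1.1)
  closed <- log(1.1 / 0.4) + (0.4^2 + 1^2) / (2 * 1.1^2) - 0.5
  errs <- vapply(c(1000, 10000), function(n) {
    e <- numeric(5)
    for (s in 1:5) {
      set.seed(100 + s)
      e[s] <- abs(kl_divergence(rnorm(n, 1.6, 0.4), pr) - closed)
    }
    mean(e)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("island-age classification follows the HPD with conservative ties", {
  expect_equal(classify_node(c(0.6, 1.1), 0.5), "pre_island")
  expect_equal(classify_node(c(0.0, 2.7), 4.7), "post_island")
  expect_equal(classify_node(c(2.0, 3.0), 2.6), "concomitant_not_rejected")
  expect_equal(classify_node(c(2.0, 3.0), 3.0), "concomitant_not_rejected")
  expect_equal(classify_node(c(2.0, 3.0), 2.0), "concomitant_not_rejected")
})

test_that("classification is monotone in the island age", {
  h <- c(1.2, 2.4)
  labels <- vapply(seq(0.1, 4, by = 0.1), function(a) classify_node(h, a),
                   character(1))
  ord <- c(pre_island = 1L, concomitant_not_rejected = 2L, post_island = 3L)
  expect_true(all(diff(ord[labels]) >= 0))
})

test_that("scheme comparison reports per-node posterior-mean differences", {
  set.seed(9)
  tn <- data.frame(state = 1:500, age_7 = rnorm(500, 5, 0.3),
                   age_8 = rnorm(500, 2, 0.2))
  expect_equal(unname(compare_schemes(tn, tn)), c(0, 0), ignore_attr = TRUE)

  tp <- tn; tp$age_8 <- tp$age_8 + 0.5
  d <- compare_schemes(tn, tp)
  expect_equal(unname(d["7"]), 0)
  expect_equal(unname(d["8"]), 0.5)
  expect_equal(unname(attr(d, "range")), c(0, 0.5))

  bad <- tn; names(bad)[3] <- "age_9"
  expect_error(compare_schemes(tn, bad), "schema")
})

test_that("prior-only assessment finds no conflict anywhere", {
  # tight root anchor: keeps the root > island-node order constraint
  # inactive, so each marginal equals its calibration prior
  phy <- read_tree("(((a,b),(c,d)),(e,f));")
  sch <- rbind(normal_scheme_row(c("a", "b"), 2.6, island = "Oahu"),
               normal_scheme_row(c("a", "f"), 8, 0.8, island = "root"))
  out <- mcmc_run(NULL, phy, sch, "strict",
                  mcmc_settings(n_samples = 4000, thin = 4, seed = 101))
  ass <- assess_all(out, phy, sch)
  expect_equal(nrow(ass), 2L)
  expect_true(all(ass$classification == "concomitant_not_rejected"))
  expect_true(all(ass$kl_div <= 0.05))
  expect_true(all(is.na(ass$scheme_diff)))
  cv <- attr(ass, "density_curves")
  expect_equal(length(cv), 2L)
  expect_true(all(c("age", "prior", "posterior") %in% names(cv[[1]])))
})

test_that("assessment output is invariant to calibration-table row order", {
  phy <- read_tree("(((a,b),(c,d)),(e,f));")
  tab <- data.frame(taxonA = c("a", "a", "c"), taxonB = c("b", "f", "d"),
                    island_name = c("Oahu", "root", "Hawaii"),
                    island_age_Ma = c(2.6, 8, 0.6))
  sch <- build_schemes(tab)$normal
  out <- mcmc_run(NULL, phy, sch, "strict",
                  mcmc_settings(n_samples = 1500, thin = 3, seed = 102))
  a1 <- assess_all(out, phy, sch)
  a2 <- assess_all(out, phy, sch[c(3, 1, 2), ])
  expect_equal(as.data.frame(a1), as.data.frame(a2))

  missing <- out; names(missing) <- sub("^age_9$", "age_99", names(missing))
  expect_error(assess_all(missing, phy, sch), "lacks")
})
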