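#' MCMC settings for the dating engine
#'
#' Defaults mirror the sampling regime of the re-analysis workflow: chains
#' thinned every 100th cycle until 10,000 samples are collected, a 25%
#' burn-in, and two independent replicates for convergence checking.
#'
#' @param n_samples posterior samples to collect after burn-in.
#' @param thin record every `thin`-th post-burn-in sweep.
#' @param burnin_fraction fraction of total sweeps discarded as burn-in;
#'   proposal windows are auto-tuned only during burn-in so detailed
#'   balance holds afterwards.
#' @param seed integer seed; the whole trace is reproducible from it.
#' @param n_replicates number of independent chains the pipeline runs.
#' @param tune logical; adapt proposal scales during burn-in.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_samples = 10000L, thin = 100L,
                          burnin_fraction = 0.25, seed = 1L,
                          n_replicates = 2L, tune = TRUE) {
  stopifnot(n_samples >= 1, thin >= 1, burnin_fraction >= 0,
            burnin_fraction < 1)
  structure(list(n_samples = as.integer(n_samples), thin = as.integer(thin),
                 burnin_fraction = burnin_fraction, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates), tune = isTRUE(tune)),
            class = "mcmc_settings")
}

# hyperpriors (all overridable through `hyper` in mcmc_run)
default_hyper <- function() {
  list(mu_meanlog = log(0.01), mu_sdlog = 1,      # clock mean rate, /Ma
       sigma_mean = 0.3,                          # ILN log-sd, exponential
       alpha_meanlog = log(1), alpha_sdlog = 0.5, # gamma shape
       exch_meanlog = 0, exch_sdlog = 1,          # GTR exchangeabilities
       root_shape = 2)                            # vague root gamma shape
}

# Feasible initial ages. A bottom-up pass propagates the hard lower bounds
# of calibrated descendants; a top-down pass then places each node at its
# prior centre (or a height-scaled guess) clamped strictly between that
# minimum and its parent's age (and any hard upper bound).
init_ages <- function(phy, calib, prior_info) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  centre <- target <- rep(NA_real_, nn)
  hard_lo <- rep(0, nn); hard_hi <- rep(Inf, nn)
  for (i in seq_len(nrow(calib))) {
    pr <- calib$prior[[i]]
    centre[calib$node[i]] <- if (pr$kind == "normal") pr$mean else
      (pr$lower + pr$upper) / 2
    if (pr$kind == "hard_uniform") {
      hard_lo[calib$node[i]] <- pr$lower
      hard_hi[calib$node[i]] <- pr$upper
    }
  }
  height <- rep(0L, nn)
  minreq <- rep(0, nn)
  for (nd in postorder_nodes(phy)) {
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    height[nd] <- max(height[kids]) + 1L
    minreq[nd] <- max(hard_lo[nd], minreq[kids])
  }
  t_root <- if (!is.na(centre[root])) centre[root] else
    max(2 * max(centre, na.rm = TRUE), 1e-3)
  t_root <- max(t_root, 1.05 * minreq[root] + 1e-6)
  t_root <- min(t_root, hard_hi[root])
  ages <- rep(0, nn)
  ages[root] <- t_root
  for (nd in rev(postorder_nodes(phy))) {       # preorder, parents first
    for (ch in phy$edge[phy$edge[, 1] == nd, 2]) {
      if (ch <= ntip) next
      upper <- min(ages[nd], hard_hi[ch])
      lower <- minreq[ch]
      if (lower >= upper)
        stop("calibrations are mutually infeasible at node ", ch, call. = FALSE)
      tgt <- if (!is.na(centre[ch])) centre[ch] else
        ages[nd] * height[ch] / height[nd]
      frac <- (tgt - lower) / (upper - lower)
      ages[ch] <- lower + min(max(frac, 0.05), 0.95) * (upper - lower)
    }
  }
  ages
}

# joint log prior of node ages: calibration densities at calibrated nodes,
# uniform order statistics (given the root age) for the rest, root prior
age_log_prior <- function(ages, prior_info) {
  root_age <- ages[prior_info$root]
  lp <- prior_info$n_free * -log(root_age)
  for (i in seq_along(prior_info$cal_nodes)) {
    lp <- lp + prior_log_density(prior_info$cal_priors[[i]],
                                 ages[prior_info$cal_nodes[i]])
    if (!is.finite(lp)) return(-Inf)
  }
  if (!prior_info$root_calibrated)
    lp <- lp + stats::dgamma(root_age, shape = prior_info$root_shape,
                             rate = prior_info$root_rate, log = TRUE)
  lp
}

scale_move <- function(x, lambda) {
  c <- exp(lambda * (stats::runif(1) - 0.5))
  list(value = x * c, log_hastings = log(c))
}

#' Bayesian node-age inference on a fixed topology
#'
#' Metropolis-within-Gibbs sampler over internal node ages, the clock mean
#' rate, the gamma shape, the GTR exchangeabilities and (under the relaxed
#' clock) per-branch rates and their log-scale spread. Node ages move by
#' uniform redraws inside their instantaneous feasible interval (parent /
#' oldest-child bounds intersected with any hard calibration bounds), the
#' root by a reflected sliding window; scalar parameters use multiplicative
#' proposals; a whole-tree scale move (ages x c, rates / c) exploits the
#' rate-time nonidentifiability and is enabled whenever no hard-bounded
#' calibration is present. Base frequencies are fixed at their empirical
#' values. Proposal scales adapt during burn-in only.
#'
#' @param aln a [dna_alignment()], or `NULL` for prior-only sampling
#'   (likelihood identically 1).
#' @param tree rooted binary `phylo` topology (branch lengths ignored).
#' @param scheme calibration scheme table (see [build_schemes()]).
#' @param clock_kind `"strict"` or `"independent_lognormal"`.
#' @param settings an [mcmc_settings()].
#' @param n_categories discrete-gamma categories (6 by default).
#' @param hyper optional list overriding entries of the default hyperpriors.
#' @return `posterior_trace`: a data frame with columns `state`,
#'   `age_<node>` for every internal node, `mu`, `sigma`, `alpha`,
#'   `r_AC..r_CT`, `loglik`, `logprior`, `logpost`.
#' @export
mcmc_run <- function(aln, tree, scheme,
                     clock_kind = c("independent_lognormal", "strict"),
                     settings = mcmc_settings(), n_categories = 6L,
                     hyper = list()) {
  clock_kind <- match.arg(clock_kind)
  validate_tree(tree)
  stopifnot(inherits(settings, "mcmc_settings"))
  hy <- utils::modifyList(default_hyper(), hyper)
  phy <- tree
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  internals <- (ntip + 1L):nn
  calib <- resolve_calibrations(phy, scheme)

  prior_only <- is.null(aln)
  if (!prior_only) {
    ld <- likelihood_data(aln, phy)
    base_counts <- table(factor(unclass(aln)[unclass(aln) %in% UNAMBIGUOUS_BASES],
                                levels = UNAMBIGUOUS_BASES))
    freqs <- as.numeric(base_counts) / sum(base_counts)
    if (any(freqs == 0)) freqs <- (as.numeric(base_counts) + 1) /
        (sum(base_counts) + 4)
  } else {
    ld <- NULL
    freqs <- rep(0.25, 4)
  }

  # structural age-prior bookkeeping
  root_cal_i <- match(root, calib$node)
  cal_means <- vapply(calib$prior, function(p)
    if (p$kind == "normal") p$mean else (p$lower + p$upper) / 2, numeric(1))
  prior_info <- list(
    root = root, cal_nodes = calib$node, cal_priors = calib$prior,
    n_free = length(setdiff(internals, c(calib$node, root))),
    root_calibrated = !is.na(root_cal_i),
    root_shape = hy$root_shape,
    root_rate = hy$root_shape / (2 * max(cal_means)))
  hard_lo <- rep(-Inf, nn); hard_hi <- rep(Inf, nn)
  for (i in seq_len(nrow(calib)))
    if (calib$prior[[i]]$kind == "hard_uniform") {
      hard_lo[calib$node[i]] <- calib$prior[[i]]$lower
      hard_hi[calib$node[i]] <- calib$prior[[i]]$upper
    }
  any_hard <- any(is.finite(hard_hi))
  parent_of <- rep(NA_integer_, nn)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  kids_of <- child_list(phy)

  set.seed(settings$seed)
  ages <- init_ages(phy, calib, prior_info)
  mu <- exp(hy$mu_meanlog)
  sigma <- if (clock_kind == "independent_lognormal") hy$sigma_mean else 0
  alpha <- 1
  exch <- rep(1, 6)           # AC AG AT CG CT GT; GT fixed
  rates <- rep(mu, nn)        # strict: all mu; ILN: per-branch
  if (clock_kind == "independent_lognormal") {
    rates <- stats::rlnorm(nn, log(mu) - sigma^2 / 2, sigma)
    rates[root] <- mu
  }
  grates <- discrete_gamma_rates(alpha, n_categories)

  param_log_prior <- function(mu, sigma, alpha, exch, rates) {
    lp <- stats::dlnorm(mu, hy$mu_meanlog, hy$mu_sdlog, log = TRUE) +
      stats::dlnorm(alpha, hy$alpha_meanlog, hy$alpha_sdlog, log = TRUE) +
      sum(stats::dlnorm(exch[1:5], hy$exch_meanlog, hy$exch_sdlog, log = TRUE))
    if (clock_kind == "independent_lognormal") {
      lp <- lp + stats::dexp(sigma, 1 / hy$sigma_mean, log = TRUE) +
        sum(stats::dlnorm(rates[-root], log(mu) - sigma^2 / 2, sigma,
                          log = TRUE))
    }
    lp
  }
  loglik <- function(ages, rates, exch, alpha_rates) {
    if (prior_only) return(0)
    loglik_from_parts(ld, ages, rates, exch, freqs, alpha_rates)
  }

  cur_ll <- loglik(ages, rates, exch, grates)
  cur_ap <- age_log_prior(ages, prior_info)
  cur_pp <- param_log_prior(mu, sigma, alpha, exch, rates)
  if (!is.finite(cur_ap) || !is.finite(cur_ll))
    stop("could not find a feasible starting state; check calibrations",
         call. = FALSE)

  # tunable proposal scales
  win_root <- 0.1 * ages[root]
  lam <- c(mu = 0.4, alpha = 0.6, exch = 0.6, sigma = 0.8, rate = 0.6,
           tscale = 0.3)
  acc <- att <- c(age = 0, root = 0, mu = 0, alpha = 0, exch = 0, sigma = 0,
                  rate = 0, tscale = 0)

  total_keep <- settings$n_samples * settings$thin
  n_burn <- ceiling(settings$burnin_fraction / (1 - settings$burnin_fraction) *
                      total_keep)
  n_sweeps <- n_burn + total_keep

  ncols_age <- length(internals)
  out_ages <- matrix(NA_real_, settings$n_samples, ncols_age)
  out_par <- matrix(NA_real_, settings$n_samples, 11)
  kept <- 0L
  nonroot <- setdiff(internals, root)

  for (sweep in seq_len(n_sweeps)) {
    ## -- internal node ages: uniform redraw in the feasible interval
    for (nd in nonroot[sample.int(length(nonroot))]) {
      lo <- max(max(ages[kids_of[[nd]]]), hard_lo[nd])
      hi <- min(ages[parent_of[nd]], hard_hi[nd])
      prop <- stats::runif(1, lo, hi)
      new_ages <- ages; new_ages[nd] <- prop
      ap <- age_log_prior(new_ages, prior_info)
      att["age"] <- att["age"] + 1
      if (is.finite(ap)) {
        ll <- loglik(new_ages, rates, exch, grates)
        if (log(stats::runif(1)) < (ll + ap) - (cur_ll + cur_ap)) {
          ages <- new_ages; cur_ll <- ll; cur_ap <- ap
          acc["age"] <- acc["age"] + 1
        }
      }
    }
    ## -- root age: reflected sliding window above the oldest child
    {
      lo <- max(max(ages[kids_of[[root]]]), hard_lo[root])
      hi <- hard_hi[root]
      prop <- ages[root] + stats::runif(1, -win_root, win_root)
      for (rep_i in 1:8) {  # fold back into (lo, hi)
        if (prop < lo) prop <- 2 * lo - prop
        else if (is.finite(hi) && prop > hi) prop <- 2 * hi - prop
        else break
      }
      att["root"] <- att["root"] + 1
      if (prop > lo && (!is.finite(hi) || prop < hi)) {
        new_ages <- ages; new_ages[root] <- prop
        ap <- age_log_prior(new_ages, prior_info)
        if (is.finite(ap)) {
          ll <- loglik(new_ages, rates, exch, grates)
          if (log(stats::runif(1)) < (ll + ap) - (cur_ll + cur_ap)) {
            ages <- new_ages; cur_ll <- ll; cur_ap <- ap
            acc["root"] <- acc["root"] + 1
          }
        }
      }
    }
    ## -- clock mean rate
    {
      mv <- scale_move(mu, lam["mu"])
      att["mu"] <- att["mu"] + 1
      new_rates <- rates
      if (clock_kind == "strict") new_rates[] <- mv$value
      pp <- param_log_prior(mv$value, sigma, alpha, exch, new_rates)
      ll <- if (clock_kind == "strict") loglik(ages, new_rates, exch, grates)
            else cur_ll
      if (log(stats::runif(1)) < (ll + pp + mv$log_hastings) - (cur_ll + cur_pp)) {
        mu <- mv$value; rates <- new_rates; cur_ll <- ll; cur_pp <- pp
        acc["mu"] <- acc["mu"] + 1
      }
    }
    ## -- gamma shape
    {
      mv <- scale_move(alpha, lam["alpha"])
      att["alpha"] <- att["alpha"] + 1
      gr <- discrete_gamma_rates(mv$value, n_categories)
      pp <- param_log_prior(mu, sigma, mv$value, exch, rates)
      ll <- loglik(ages, rates, exch, gr)
      if (log(stats::runif(1)) < (ll + pp + mv$log_hastings) - (cur_ll + cur_pp)) {
        alpha <- mv$value; grates <- gr; cur_ll <- ll; cur_pp <- pp
        acc["alpha"] <- acc["alpha"] + 1
      }
    }
    ## -- exchangeabilities, one at a time (GT stays 1)
    for (exch_idx in 1:5) {
      mv <- scale_move(exch[exch_idx], lam["exch"])
      att["exch"] <- att["exch"] + 1
      new_exch <- exch; new_exch[exch_idx] <- mv$value
      pp <- param_log_prior(mu, sigma, alpha, new_exch, rates)
      ll <- loglik(ages, rates, new_exch, grates)
      if (log(stats::runif(1)) < (ll + pp + mv$log_hastings) - (cur_ll + cur_pp)) {
        exch <- new_exch; cur_ll <- ll; cur_pp <- pp
        acc["exch"] <- acc["exch"] + 1
      }
    }
    ## -- relaxed clock: branch rates and sigma
    if (clock_kind == "independent_lognormal") {
      for (nd in setdiff(seq_len(nn), root)) {
        mv <- scale_move(rates[nd], lam["rate"])
        att["rate"] <- att["rate"] + 1
        new_rates <- rates; new_rates[nd] <- mv$value
        pp <- param_log_prior(mu, sigma, alpha, exch, new_rates)
        ll <- loglik(ages, new_rates, exch, grates)
        if (log(stats::runif(1)) < (ll + pp + mv$log_hastings) -
              (cur_ll + cur_pp)) {
          rates <- new_rates; cur_ll <- ll; cur_pp <- pp
          acc["rate"] <- acc["rate"] + 1
        }
      }
      mv <- scale_move(sigma, lam["sigma"])
      att["sigma"] <- att["sigma"] + 1
      pp <- param_log_prior(mu, mv$value, alpha, exch, rates)
      if (log(stats::runif(1)) < (pp + mv$log_hastings) - cur_pp) {
        sigma <- mv$value; cur_pp <- pp
        acc["sigma"] <- acc["sigma"] + 1
      }
    }
    ## -- whole-tree scale: ages x c, rates / c (likelihood invariant);
    ##    pointless against hard-bounded calibrations, so skipped there
    if (!any_hard) {
      c_ <- exp(lam["tscale"] * (stats::runif(1) - 0.5))
      att["tscale"] <- att["tscale"] + 1
      new_ages <- ages; new_ages[internals] <- ages[internals] * c_
      new_mu <- mu / c_
      new_rates <- rates / c_
      n_down <- if (clock_kind == "independent_lognormal") nn else 1L
      log_h <- (length(internals) - n_down) * log(c_)
      ap <- age_log_prior(new_ages, prior_info)
      pp <- param_log_prior(new_mu, sigma, alpha, exch, new_rates)
      if (is.finite(ap) &&
          log(stats::runif(1)) < (ap + pp + log_h) - (cur_ap + cur_pp)) {
        ages <- new_ages; mu <- new_mu; rates <- new_rates
        cur_ap <- ap; cur_pp <- pp
        acc["tscale"] <- acc["tscale"] + 1
      }
    }
    ## -- burn-in auto-tuning
    if (settings$tune && sweep <= n_burn && sweep %% 50L == 0L) {
      rt <- acc / pmax(att, 1)
      for (nm in c("mu", "alpha", "exch", "sigma", "rate", "tscale")) {
        if (att[nm] == 0) next
        if (rt[nm] > 0.45) lam[nm] <- lam[nm] * 1.3
        if (rt[nm] < 0.15) lam[nm] <- lam[nm] / 1.3
      }
      if (att["root"] > 0) {
        if (rt["root"] > 0.45) win_root <- win_root * 1.3
        if (rt["root"] < 0.15) win_root <- win_root / 1.3
      }
      acc[] <- 0; att[] <- 0
    }
    if (sweep == n_burn) { acc[] <- 0; att[] <- 0 }
    ## -- record
    if (sweep > n_burn && (sweep - n_burn) %% settings$thin == 0L) {
      kept <- kept + 1L
      out_ages[kept, ] <- ages[internals]
      out_par[kept, ] <- c(mu, sigma, alpha, exch[1:5], cur_ll,
                           cur_ap + cur_pp, cur_ll + cur_ap + cur_pp)
    }
  }

  dead <- names(which(att > 0 & acc == 0))
  if (length(dead))
    stop("no accepted proposal after burn-in in block(s): ",
         paste(dead, collapse = ", "),
         "; adjust the proposal windows or extend the chain", call. = FALSE)

  tr <- data.frame(state = seq_len(settings$n_samples) * settings$thin,
                   out_ages, out_par)
  names(tr) <- c("state", paste0("age_", internals),
                 "mu", "sigma", "alpha",
                 paste0("r_", c("AC", "AG", "AT", "CG", "CT")),
                 "loglik", "logprior", "logpost")
  structure(tr, class = c("posterior_trace", "data.frame"),
            internals = internals, calibration = calib,
            clock_kind = clock_kind, seed = settings$seed,
            acceptance = acc / pmax(att, 1))
}

#' Read / write posterior traces
#'
#' Tab-separated, one row per sample, `state` column first — the common
#' trace-log dialect readable by external trace viewers.
#'
#' @param trace a `posterior_trace` (any data frame with a `state` column).
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(tr)[1] != "state") stop("not a trace file: no 'state' column",
                                    call. = FALSE)
  class(tr) <- c("posterior_trace", "data.frame")
  tr
}
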