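#' Derive a stream seed from a master seed
#'
#' Modules draw their randomness from seeds fanned out of one master seed
#' with a counter, so each stage is independently reproducible.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer stream index.
#' @return integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(master, counter) {
  as.integer(((master %% 2147483647) * 16807 + counter * 2654435) %%
               2147483629) + 1L
}

#' Simulate a pure-birth (Yule) time-tree
#'
#' Forward simulation: the root splits at time zero into two lineages; each
#' lineage splits at rate `birth_rate` until `n_taxa` lineages exist, after
#' which one further exponential waiting time sets the present. Node ages
#' are then rescaled so the root sits exactly at `root_age`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param root_age root age in Ma.
#' @param birth_rate per-lineage speciation rate (only shapes relative node
#'   depths; the rescaling fixes the absolute scale).
#' @param seed integer seed.
#' @return a [dated_tree()] with tips `t1..tn`.
#' @export
simulate_time_tree <- function(n_taxa, root_age, birth_rate = 1, seed = 1L) {
  stopifnot(n_taxa >= 3, root_age > 0, birth_rate > 0)
  set.seed(seed)
  max_lin <- 2L * n_taxa - 1L
  birth <- death <- rep(NA_real_, max_lin)
  parent <- rep(0L, max_lin)
  birth[1:2] <- 0
  active <- c(1L, 2L)
  nxt <- 3L
  t <- 0
  while (length(active) < n_taxa) {
    k <- length(active)
    t <- t + stats::rexp(1, k * birth_rate)
    i <- active[sample.int(k, 1L)]
    death[i] <- t
    parent[c(nxt, nxt + 1L)] <- i
    birth[c(nxt, nxt + 1L)] <- t
    active <- c(setdiff(active, i), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  present <- t + stats::rexp(1, n_taxa * birth_rate)
  scale <- root_age / present
  tip_no <- integer(max_lin)
  tip_no[active] <- seq_len(n_taxa)
  kids <- split(which(parent > 0), parent[parent > 0])
  sub <- function(lin) {
    if (lin %in% active)
      return(sprintf("t%d:%.10g", tip_no[lin], (present - birth[lin]) * scale))
    ch <- kids[[as.character(lin)]]
    len <- (death[lin] - birth[lin]) * scale
    sprintf("(%s,%s):%.10g", sub(ch[1]), sub(ch[2]), len)
  }
  nwk <- sprintf("(%s,%s);", sub(1L), sub(2L))
  as_dated_tree(read_tree(nwk))
}

#' Pin an internal node to an exact age
#'
#' Sets one node's age, leaving all others untouched. The target must lie
#' strictly between the node's oldest child and its parent (any age above
#' the oldest child for the root).
#'
#' @param tree a [dated_tree()].
#' @param node internal node number, or a taxon pair resolved via
#'   [resolve_mrca()].
#' @param target_age new age in Ma.
#' @return the adjusted [dated_tree()].
#' @export
pin_node_age <- function(tree, node, target_age) {
  stopifnot(inherits(tree, "dated_tree"))
  if (is.character(node)) node <- resolve_mrca(tree, node)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  if (node <= ntip) stop("cannot pin a tip age", call. = FALSE)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  lo <- max(tree$ages[kids])
  hi <- if (node == ntip + 1L) Inf else tree$ages[phy$edge[phy$edge[, 2] == node, 1]]
  if (target_age <= lo || target_age >= hi)
    stop(sprintf("target age %.4g infeasible for node %d: must be in (%.4g, %.4g)",
                 target_age, node, lo, hi), call. = FALSE)
  ages <- tree$ages
  ages[node] <- target_age
  dated_tree(phy, ages)
}

#' Simulate per-branch clock rates
#'
#' Strict clock: every branch gets `mean_rate`. Independent lognormal:
#' i.i.d. lognormal rates with expectation `mean_rate` and log-scale
#' standard deviation `log_sd`.
#'
#' @param tree a [dated_tree()].
#' @param clock_kind `"strict"` or `"independent_lognormal"`.
#' @param mean_rate expected rate in substitutions/site/Ma.
#' @param log_sd lognormal sigma (dimensionless); ignored for strict.
#' @param seed integer seed.
#' @return numeric vector of rates indexed by child node number (root entry
#'   present but unused).
#' @export
simulate_rates <- function(tree, clock_kind = c("strict", "independent_lognormal"),
                           mean_rate, log_sd = 0, seed = 1L) {
  clock_kind <- match.arg(clock_kind)
  stopifnot(mean_rate > 0, log_sd >= 0)
  nn <- ape::Ntip(tree$phy) + tree$phy$Nnode
  if (clock_kind == "strict") return(rep(mean_rate, nn))
  set.seed(seed)
  r <- stats::rlnorm(nn, meanlog = log(mean_rate) - log_sd^2 / 2, sdlog = log_sd)
  r[ape::Ntip(tree$phy) + 1L] <- mean_rate  # root entry unused
  r
}

#' Simulate a nucleotide alignment on a dated tree
#'
#' Sites evolve independently under GTR with a per-site discrete-gamma rate
#' multiplier. The root sequence is drawn from the stationary frequencies;
#' each branch applies `P(rate * duration * site_multiplier)`.
#'
#' @param tree a [dated_tree()].
#' @param rates per-branch rates as from [simulate_rates()] (scalar recycled).
#' @param model a [substitution_model()].
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return a [dna_alignment()] over the tree tips.
#' @export
simulate_alignment <- function(tree, rates, model, n_sites, seed = 1L) {
  stopifnot(inherits(tree, "dated_tree"), inherits(model, "subst_model"),
            n_sites >= 1)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  if (length(rates) == 1L) rates <- rep(rates, nn)
  set.seed(seed)
  grates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  cat_of_site <- sample.int(model$n_categories, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, nn, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(4, n_sites, replace = TRUE, prob = model$freqs)
  # preorder: parents before children
  ord <- rev(ape::postorder(phy))
  for (e in ord) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    dur <- tree$ages[p] - tree$ages[ch]
    for (k in seq_len(model$n_categories)) {
      idx <- which(cat_of_site == k)
      if (!length(idx)) next
      P <- gtr_transition_matrix(model, rates[ch] * dur * grates[k])
      P <- pmax(P, 0)
      for (a in 1:4) {
        sel <- idx[states[p, idx] == a]
        if (length(sel))
          states[ch, sel] <- sample.int(4, length(sel), replace = TRUE,
                                        prob = P[a, ])
      }
    }
  }
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE]],
              nrow = ntip, dimnames = list(phy$tip.label, NULL))
  dna_alignment(m)
}

#' Define an island-divergence simulation scenario
#'
#' A scenario fixes everything needed to generate data with known truth:
#' tree size and depth, a nominal island age, the signed offset of the true
#' divergence from that island age (0 = concomitant, positive = divergence
#' predates the island, negative = postdates it), the clock, the
#' substitution model, and the sequence length.
#'
#' Defaults emulate a single-radiation multilocus dataset: 20 taxa, 2 kb,
#' a 10 Ma radiation, the 2.6 Ma Oahu age as the island calibration, an
#' independent-lognormal clock around 0.005 substitutions/site/Ma, and a
#' transition-biased GTR+G6 model.
#'
#' @param n_taxa,root_age,island_age,divergence_offset scenario geometry (Ma).
#' @param clock_kind,clock_mean_rate,clock_log_sd clock settings.
#' @param subst_model a [substitution_model()].
#' @param n_sites alignment length.
#' @param seed master seed; stage seeds are fanned out via [derive_seed()].
#' @return object of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_taxa = 20L, root_age = 10, island_age = 2.6,
                                divergence_offset = 0,
                                clock_kind = "independent_lognormal",
                                clock_mean_rate = 0.005, clock_log_sd = 0.3,
                                subst_model = substitution_model(
                                  exchangeabilities = c(1, 4, 1, 1, 4, 1),
                                  base_freqs = c(0.3, 0.2, 0.2, 0.3),
                                  gamma_shape = 0.5, n_categories = 6L),
                                n_sites = 2000L, seed = 1L) {
  target <- island_age + divergence_offset
  if (target <= 0 || target >= root_age)
    stop("island_age + divergence_offset must lie in (0, root_age)",
         call. = FALSE)
  stopifnot(clock_mean_rate > 0, n_sites >= 1)
  structure(list(n_taxa = n_taxa, root_age = root_age, island_age = island_age,
                 divergence_offset = divergence_offset,
                 clock_kind = clock_kind, clock_mean_rate = clock_mean_rate,
                 clock_log_sd = clock_log_sd, subst_model = subst_model,
                 n_sites = n_sites, seed = seed),
            class = "sim_scenario")
}

# pick a taxon pair whose MRCA is `node`: one tip from each child subtree
mrca_defining_pair <- function(tree, node) {
  phy <- tree$phy
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  pick <- function(v) {
    while (v > ape::Ntip(phy)) v <- phy$edge[phy$edge[, 1] == v, 2][1]
    phy$tip.label[v]
  }
  c(pick(kids[1]), pick(kids[2]))
}

#' Generate a full synthetic dataset with known truth
#'
#' Simulates a Yule time-tree, pins one internal node (the "island node")
#' to `island_age + divergence_offset`, draws branch rates and sequences,
#' and returns everything downstream stages need, including the
#' calibration-table row designating the island node by a taxon pair.
#'
#' @param scenario a [simulation_scenario()].
#' @return list of class `sim_truth`: `tree` (true [dated_tree()]), `rates`,
#'   `alignment`, `island_node`, `true_age`, `calibration` (one-row table),
#'   `scenario`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  target <- scenario$island_age + scenario$divergence_offset
  tree <- NULL
  for (try in 0:49) {
    cand <- simulate_time_tree(scenario$n_taxa, scenario$root_age,
                               seed = derive_seed(scenario$seed, 10L + try))
    phy <- cand$phy
    ntip <- ape::Ntip(phy)
    internals <- setdiff(seq_len(ntip + phy$Nnode)[-seq_len(ntip)], ntip + 1L)
    feas <- Filter(function(nd) {
      kids <- phy$edge[phy$edge[, 1] == nd, 2]
      par <- phy$edge[phy$edge[, 2] == nd, 1]
      max(cand$ages[kids]) < target && target < cand$ages[par]
    }, internals)
    if (length(feas)) {
      node <- feas[which.min(abs(cand$ages[feas] - target))]
      tree <- pin_node_age(cand, node, target)
      break
    }
  }
  if (is.null(tree))
    stop("no simulated tree admitted the target node age; adjust the scenario",
         call. = FALSE)
  rates <- simulate_rates(tree, scenario$clock_kind, scenario$clock_mean_rate,
                          scenario$clock_log_sd,
                          seed = derive_seed(scenario$seed, 2L))
  aln <- simulate_alignment(tree, rates, scenario$subst_model,
                            scenario$n_sites,
                            seed = derive_seed(scenario$seed, 3L))
  pair <- mrca_defining_pair(tree, node)
  calib <- data.frame(taxonA = pair[1], taxonB = pair[2],
                      island_name = "island", island_age_Ma = scenario$island_age)
  structure(list(tree = tree, rates = rates, alignment = aln,
                 island_node = node, true_age = target,
                 calibration = calib, scenario = scenario),
            class = "sim_truth")
}

#' Write a simulated dataset to disk
#'
#' Emits the alignment (FASTA), the true dated tree (newick) and a
#' tab-separated truth table (`node`, `true_age_Ma`, `island_age_Ma`,
#' `offset`) so downstream assessments can be checked against known ages.
#'
#' @param sim a `sim_truth` from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_scenario <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.fasta"),
             tree = file.path(dir, "true_tree.nwk"),
             truth = file.path(dir, "truth.tsv"),
             calibration = file.path(dir, "calibration.tsv"))
  write_alignment(sim$alignment, paths["alignment"])
  write_tree(sim$tree, paths["tree"])
  utils::write.table(
    data.frame(node = sim$island_node, true_age_Ma = sim$true_age,
               island_age_Ma = sim$scenario$island_age,
               offset = sim$scenario$divergence_offset),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_calibration_table(sim$calibration, paths["calibration"])
  invisible(paths)
}
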