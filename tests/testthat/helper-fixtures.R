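# shared fixtures built in code

# modest GTR+G6 model used by most simulation tests
test_model <- function(shape = 0.5, k = 6L) {
  substitution_model(exchangeabilities = c(1, 4, 1, 1, 4, 1),
                     base_freqs = c(0.3, 0.2, 0.2, 0.3),
                     gamma_shape = shape, n_categories = k)
}

# one-row normal calibration scheme on the MRCA of a taxon pair
normal_scheme_row <- function(pair, mean, sd = compute_prior_sd(mean),
                              island = "island") {
  data.frame(taxonA = pair[1], taxonB = pair[2], island_name = island,
             island_age_Ma = mean, prior_kind = "normal",
             param1 = mean, param2 = sd)
}

hard_scheme_row <- function(pair, mean, island = "island") {
  iv <- punctual_interval(mean)
  data.frame(taxonA = pair[1], taxonB = pair[2], island_name = island,
             island_age_Ma = mean, prior_kind = "hard_uniform",
             param1 = iv[1], param2 = iv[2])
}

# taxon pair whose MRCA is the root
root_pair <- function(tree) {
  phy <- if (inherits(tree, "dated_tree")) tree$phy else tree
  islandclock:::mrca_defining_pair(
    if (inherits(tree, "dated_tree")) tree else as_dated_tree(phy),
    ape::Ntip(phy) + 1L)
}

# Ma-truncated (age > 0) normal CDF: the calibration density on the dating
# model's support
truncnorm_cdf <- function(mean, sd) {
  function(q) pmax(0, (stats::pnorm(q, mean, sd) - stats::pnorm(0, mean, sd))) /
    stats::pnorm(mean / sd)
}

# alignment from named sequence strings
aln_from_strings <- function(...) dna_alignment(c(...))
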