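# Pre-digest an alignment for repeated likelihood evaluation: encode to
# IUPAC bit masks, collapse identical site patterns, and fix the postorder
# edge traversal. Gaps and ambiguity codes become partial missing data
# (all compatible states allowed).
likelihood_data <- function(aln, phy) {
  stopifnot(inherits(aln, "dna_alignment"))
  validate_tree(phy)
  missing <- setdiff(phy$tip.label, rownames(aln))
  if (length(missing))
    stop("tree tips absent from alignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- unclass(aln)[phy$tip.label, , drop = FALSE]
  masks <- matrix(iupac_mask(m), nrow = nrow(m))
  key <- apply(masks, 2, paste, collapse = ".")
  f <- factor(key, levels = unique(key))
  weights <- as.numeric(table(f))
  masks <- masks[, !duplicated(key), drop = FALSE]
  ord <- ape::postorder(phy)
  list(masks = masks, weights = weights,
       edge = phy$edge[ord, , drop = FALSE], edge_order = ord)
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Exact site-wise pruning likelihood under GTR + discrete gamma on a dated
#' tree. The length of the branch above node `v` is
#' `rate[v] * (age[parent(v)] - age[v])` expected substitutions per site,
#' further scaled per site class by the discrete-gamma multipliers; the
#' site likelihood averages the classes. Gaps and ambiguity codes are
#' treated as partially missing data.
#'
#' @param aln a [dna_alignment()] whose taxa cover the tree tips.
#' @param tree a [dated_tree()].
#' @param rates per-branch clock rates in substitutions/site/Ma, indexed by
#'   child node number (length `Ntip + Nnode`; the root entry is unused).
#'   A single value is recycled (strict clock).
#' @param model a [substitution_model()].
#' @return total log-likelihood.
#' @export
pruning_loglik <- function(aln, tree, rates, model) {
  stopifnot(inherits(tree, "dated_tree"), inherits(model, "subst_model"))
  phy <- tree$phy
  nn <- ape::Ntip(phy) + phy$Nnode
  if (length(rates) == 1L) rates <- rep(rates, nn)
  if (length(rates) != nn)
    stop("rates must have one entry per node (or length 1)", call. = FALSE)
  if (any(rates[-(ape::Ntip(phy) + 1L)] <= 0))
    stop("branch rates must be strictly positive", call. = FALSE)
  ld <- likelihood_data(aln, phy)
  durations <- tree$ages[ld$edge[, 1]] - tree$ages[ld$edge[, 2]]
  blen <- rates[ld$edge[, 2]] * durations
  grates <- discrete_gamma_rates(model$gamma_shape, model$n_categories)
  pruning_loglik_cpp(ld$masks, ld$weights, ld$edge, blen,
                     model$exch, model$freqs, grates)
}

# fast path used inside the MCMC: everything pre-digested
loglik_from_parts <- function(ld, ages, rates, exch, freqs, grates) {
  blen <- rates[ld$edge[, 2]] * (ages[ld$edge[, 1]] - ages[ld$edge[, 2]])
  pruning_loglik_cpp(ld$masks, ld$weights, ld$edge, blen, exch, freqs, grates)
}
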